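test_that("generators are deterministic given a seed and vary across seeds", {
  a <- sim_binding_curve(noise_cv = 0.05, seed = 3)
  b <- sim_binding_curve(noise_cv = 0.05, seed = 3)
  c <- sim_binding_curve(noise_cv = 0.05, seed = 4)
  expect_identical(a$bound_fraction, b$bound_fraction)
  expect_false(identical(a$bound_fraction, c$bound_fraction))

  r1 <- sim_rit_cohort(data.frame(arm = "x", dose_Gy = 10), seed = 9,
                       noise_cv = 0.1)
  r2 <- sim_rit_cohort(data.frame(arm = "x", dose_Gy = 10), seed = 9,
                       noise_cv = 0.1)
  expect_identical(r1$records$volume_mm3, r2$records$volume_mm3)
  expect_identical(r1$truth$response, r2$truth$response)
})

test_that("binding generator saturates to r and closes the Lindmo loop", {
  curve <- sim_binding_curve(r_true = 0.83, cells = c(1e8, 1e9, 1e10),
                             half_sat_cells = 5e6, noise_cv = 0)
  expect_equal(curve$bound_fraction[3], 0.83, tolerance = 1e-2)
  expect_equal(lindmo_fit(sim_binding_curve(r_true = 0.88,
                                            noise_cv = 0))$immunoreactive_fraction,
               0.88, tolerance = 1e-6)
  expect_error(sim_binding_curve(noise_cv = 1), "noise_cv")
})

test_that("competition generator is half-maximal at Kd + hot and maximal at zero", {
  curve <- sim_competition_curve(kd_true_nM = 1.9, labeled_conc_nM = 0.1,
                                 conc_nM = c(0, 0.01, 2.0, 100, 1e4),
                                 b0 = 1000, ns = 0, noise_cv = 0)
  expect_equal(curve$bound_signal[1], 1000)
  expect_equal(curve$bound_signal[3], 500)  # at c = IC50 = 2.0 nM
  expect_true(all(diff(curve$bound_signal) <= 0))
})

test_that("internalization kinetics conserve mass and match label biology", {
  for (lab in c("residualizing", "non_residualizing")) {
    tc <- sim_internalization(lab, noise = FALSE)
    fr <- attr(tc, "truth")$fractions
    expect_equal(unname(rowSums(fr)), rep(1, nrow(fr)), tolerance = 1e-9)
  }
  # residualizing: internalized approaches k_int/(k_int + k_off) as t -> Inf
  sol <- internalization_solution(c(20, 200, 2000), 0.25, 0.18, 0)
  expect_equal(unname(sol[3, "internalized"]), 0.25 / 0.43, tolerance = 1e-9)
  # calibration band: ~55% internalized at 20 h for the residualizing label
  fr20 <- internalization_solution(20, 0.25, 0.18, 0)
  expect_gt(fr20[, "internalized"], 0.45)
  expect_lt(fr20[, "internalized"], 0.65)
  # non-residualizing label peaks near 3 h then declines
  t <- seq(0.25, 24, by = 0.25)
  i_frac <- internalization_solution(t, 0.65, 0.15, 0.09)[, "internalized"]
  t_max <- t[which.max(i_frac)]
  expect_gt(t_max, 1.5)
  expect_lt(t_max, 5)
  expect_lt(i_frac[length(i_frac)], max(i_frac))
  expect_error(internalization_solution(1, -0.1, 0.1, 0), ">= 0")
})

test_that("noise-free biodistribution cohorts reproduce the biexponential", {
  sc <- biodist_scenario("12A8")
  bio <- sim_biodistribution(sc, noise_cv = 0, seed = 2)
  tab <- build_biodist_table(bio$samples, bio$standard_cpm,
                             get_nuclide("111In"), antibody = "12A8")
  tum <- tab[tab$tissue == "Tumor", ]
  expect_equal(tum$mean_pid_g, biexp_value(sc$tissues$Tumor, tum$day),
               tolerance = 1e-9)
  expect_equal(tum$sd_pid_g, rep(0, 5), tolerance = 1e-9)
  expect_error(sim_biodistribution(sc, n = 0), "n")
})

test_that("analytic biexponential AUC agrees with a dense trapezoid", {
  sc <- biodist_scenario("12A8")
  t <- seq(0, 10, by = 0.05)
  for (tissue in names(sc$tissues)) {
    p <- sc$tissues[[tissue]]
    expect_equal(oracle_trapz(t, biexp_value(p, t)), biexp_auc(p, 10),
                 tolerance = 1e-2)
  }
  # scenario calibration: tumor uptake peaks at day 4 on the study grid
  vals <- biexp_value(sc$tissues$Tumor, study_days)
  expect_equal(study_days[which.max(vals)], 4)
})

test_that("RIT generator truth labels and kill behavior are coherent", {
  arms <- data.frame(arm = c("untreated", "low", "high"),
                     dose_Gy = c(0, 4.2, 21))
  sim <- sim_rit_cohort(arms, seed = 17, noise_cv = 0)
  tr <- sim$truth
  expect_true(all(tr$response[tr$arm == "untreated"] == "progression"))
  expect_true(all(tr$response[tr$arm == "high"] == "complete_regression"))
  # untreated volumes increase monotonically in noise-free mode
  un <- sim$records[sim$records$arm == "untreated", ]
  for (id in unique(un$animal_id)) {
    expect_true(all(diff(un$volume_mm3[un$animal_id == id]) > 0))
  }
  expect_error(sim_rit_cohort(data.frame()), "non-empty")
})
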