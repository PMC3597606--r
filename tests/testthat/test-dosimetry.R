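test_that("de-decay-correction multiplies by the 90Y decay factor", {
  tac <- time_activity_curve(study_days, tumor_row_12A8)
  phys <- to_physical_curve(tac, y90)
  expect_false(attr(phys, "decay_corrected"))
  expect_equal(phys$conc_pid_g[1], 7.3 * ORACLE$df_24h, tolerance = 1e-6)
  expect_equal(round(phys$conc_pid_g[1], 2), 5.63)

  tac2 <- time_activity_curve(study_days, tumor_row_67A2)
  phys2 <- to_physical_curve(tac2, y90)
  expect_equal(phys2$conc_pid_g[5], 16.7 * exp(-log(2) * 240 / 64.1),
               tolerance = 1e-9)
  expect_equal(phys2$conc_pid_g[5], 1.246, tolerance = 1e-3)

  # a t = 0 value is unchanged
  tac0 <- time_activity_curve(c(0, 1), c(5, 5))
  expect_equal(to_physical_curve(tac0, y90)$conc_pid_g[1], 5)
  # double-decay guard
  expect_error(to_physical_curve(phys, y90), "already physical")
})

test_that("trapezoid AUC: rectangle, unit chain, anchoring, linearity", {
  flat <- time_activity_curve(c(0, 1), c(10, 10), decay_corrected = FALSE)
  auc <- trapezoid_auc(flat, anchor_zero_at_origin = FALSE)
  expect_equal(auc$auc_pidg_day, 10)
  expect_equal(auc$auc_s_per_kg, 8.64e6)
  expect_identical(PIDG_DAY_TO_S_PER_KG, 864000)

  one <- time_activity_curve(1, 10, decay_corrected = FALSE)
  expect_error(trapezoid_auc(one, anchor_zero_at_origin = FALSE),
               "at least two points")
  expect_equal(trapezoid_auc(one)$auc_pidg_day, 5)  # triangle with anchor

  # refuse decay-corrected input
  expect_error(trapezoid_auc(time_activity_curve(c(1, 2), c(1, 1))),
               "physical curve")

  # doubling every concentration doubles the AUC
  tac <- time_activity_curve(study_days, tumor_row_12A8)
  a1 <- trapezoid_auc(to_physical_curve(tac, y90))$auc_pidg_day
  tac2 <- time_activity_curve(study_days, 2 * tumor_row_12A8)
  a2 <- trapezoid_auc(to_physical_curve(tac2, y90))$auc_pidg_day
  expect_equal(a2, 2 * a1, tolerance = 1e-12)
})

test_that("trapezoid equals the closed form for piecewise-linear curves", {
  set.seed(7)
  for (i in 1:20) {
    t <- sort(c(0, runif(6, 0.1, 10)))
    y <- runif(7, 0, 30)
    tac <- time_activity_curve(t, y, decay_corrected = FALSE)
    expect_equal(trapezoid_auc(tac)$auc_pidg_day, oracle_trapz(t, y),
                 tolerance = 1e-12)
  }
})

test_that("study-table AUCs match the hand-trapezoid oracle", {
  p1 <- to_physical_curve(time_activity_curve(study_days, tumor_row_12A8), y90)
  expect_equal(trapezoid_auc(p1)$auc_pidg_day, ORACLE$auc1_pidg_day,
               tolerance = 1e-9)
  p2 <- to_physical_curve(time_activity_curve(study_days, tumor_row_67A2), y90)
  expect_equal(trapezoid_auc(p2)$auc_pidg_day, ORACLE$auc2_pidg_day,
               tolerance = 1e-9)
})

test_that("absorbed dose composes AUC, activity and Delta; linear in both", {
  auc <- ORACLE$auc1_pidg_day * PIDG_DAY_TO_S_PER_KG
  d <- absorbed_dose(auc, 3.7, y90)
  expect_equal(d$dose_Gy, ORACLE$dose1_3p7_Gy, tolerance = 1e-9)
  expect_equal(d$dose_Gy,
               d$injected_MBq * 1e6 * d$auc_s_per_kg * d$delta,
               tolerance = 1e-12)
  expect_equal(absorbed_dose(auc, 1.85, y90)$dose_Gy, d$dose_Gy / 2,
               tolerance = 1e-12)
  expect_error(absorbed_dose(auc, 3.7, get_nuclide("111In")),
               "mean beta energy")
  expect_error(absorbed_dose(auc, 0, y90), "> 0")
})

test_that("dose_table runs the chain end-to-end on the packaged tables", {
  t1 <- packaged_biodist("12A8")
  dt <- dose_table(t1, c(0.74, 1.85, 3.7))
  expect_equal(dt$dose_Gy, ORACLE$dose1_3p7_Gy * c(0.2, 0.5, 1),
               tolerance = 1e-9)
  expect_match(paste(attr(dt, "assumptions"), collapse = " "), "surrogate")
  expect_equal(nrow(dose_table(t1, numeric(0))), 0L)
  # missing tumor row propagates a named stage error
  blood_only <- biodist_table(t1[t1$tissue == "Blood", ], antibody = "x")
  expect_error(dose_table(blood_only, 3.7), "Tumor")
})
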