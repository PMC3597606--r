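test_that("percent_id_per_gram arithmetic, normalization and linearity", {
  # counts = 1% of standard, 0.05 g tissue, 20 g mouse -> 20 %ID/g
  expect_equal(percent_id_per_gram(1e4, 0.05, 1e6, body_weight_g = 20), 20)
  expect_equal(percent_id_per_gram(1e4, 0.05, 1e6, body_weight_g = 22), 22)
  expect_equal(percent_id_per_gram(0, 0.05, 1e6), 0)
  # linear in counts, inverse-linear in weight
  base <- percent_id_per_gram(500, 0.1, 1e6)
  expect_equal(percent_id_per_gram(1500, 0.1, 1e6), 3 * base)
  expect_equal(percent_id_per_gram(500, 0.3, 1e6), base / 3)
  # decay correction divides by the decay factor
  expect_equal(percent_id_per_gram(1e4, 0.05, 1e6, counting_offset_h = 64.1,
                                   nuclide = y90), 40, tolerance = 1e-9)
  expect_error(percent_id_per_gram(1, 0.1, 0), "> 0")
  expect_warning(percent_id_per_gram(1, 0.1, 1e6, body_weight_g = 45),
                 "rodent range")
})

test_that("build_biodist_table aggregates with mean and n-1 SD", {
  samples <- data.frame(
    animal_id = paste0("m", 1:7),
    tissue = c(rep("Tumor", 5), "Blood", "Blood"),
    day = 1,
    counts = c(rep(7.3 * 1e6 * 0.1 / 100, 5),
               6 * 1e6 * 0.5 / 100, 8 * 1e6 * 0.5 / 100),
    weight_g = c(rep(0.1, 5), 0.5, 0.5),
    body_weight_g = 20)
  tab <- build_biodist_table(samples, 1e6, get_nuclide("111In"), "test")
  tum <- tab[tab$tissue == "Tumor", ]
  expect_equal(tum$mean_pid_g, 7.3)
  expect_equal(tum$sd_pid_g, 0)
  expect_equal(tum$n, 5L)
  bl <- tab[tab$tissue == "Blood", ]
  expect_equal(bl$mean_pid_g, 7)
  expect_equal(bl$sd_pid_g, sqrt(2))
  expect_equal(bl$n, 2L)
})

test_that("cohort table means land within 2 SE of generator truth", {
  # one scenario cell checked over replicates: the aggregated mean is an
  # unbiased estimate of the biexponential truth
  sc <- biodist_scenario("12A8")
  truth4 <- biexp_value(sc$tissues$Tumor, 4)
  se_truth <- truth4 * 0.1 / sqrt(5)  # lognormal mean-1 noise: sd = cv x mean
  set.seed(42)
  hits <- 0L; reps <- 500L
  for (i in seq_len(reps)) {
    bio <- sim_biodistribution(sc, days = 4, n = 5, noise_cv = 0.1)
    tab <- build_biodist_table(bio$samples, bio$standard_cpm,
                               get_nuclide("111In"))
    row <- tab[tab$tissue == "Tumor", ]
    if (abs(row$mean_pid_g - truth4) <= 2 * se_truth) hits <- hits + 1L
  }
  expect_gte(hits / reps, 0.93)
})

test_that("tumor-to-blood ratios match the packaged study tables", {
  t1 <- packaged_biodist("12A8")
  t2 <- packaged_biodist("67A2")
  expect_equal(round(tumor_to_blood_ratio(t1, 1), 1), 0.6)
  expect_equal(round(tumor_to_blood_ratio(t2, 1), 1), 0.9)
  expect_equal(round(tumor_to_blood_ratio(t1, 10), 1), 3.6)
  expect_equal(tumor_to_blood_ratio(t1, 1), 7.3 / 12.5, tolerance = 1e-12)
  expect_error(tumor_to_blood_ratio(t1, 3), "unique")
})

test_that("ratios are invariant to the normalization body weight", {
  mk <- function(bw) {
    samples <- data.frame(animal_id = c("a", "a"),
                          tissue = c("Tumor", "Blood"), day = 1,
                          counts = c(100, 400), weight_g = c(0.1, 0.5),
                          body_weight_g = bw)
    build_biodist_table(samples, 1e6, get_nuclide("111In"))
  }
  expect_equal(tumor_to_blood_ratio(mk(19), 1), tumor_to_blood_ratio(mk(23), 1),
               tolerance = 1e-12)
})

test_that("biodistribution CSV round-trips bit-exactly", {
  t1 <- packaged_biodist("12A8")
  tmp <- tempfile(fileext = ".csv")
  write_biodist_csv(t1, tmp)
  back <- read_biodist_csv(tmp, nuclide = get_nuclide("111In"))
  expect_identical(back$mean_pid_g, t1$mean_pid_g)
  expect_identical(back$sd_pid_g, t1$sd_pid_g)
  expect_identical(back$tissue, t1$tissue)
  expect_identical(attr(back, "antibody"), "12A8")
})
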