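test_that("tumor volume is half the dimension product and symmetric", {
  expect_equal(tumor_volume(2, 2, 2), 4)
  expect_equal(tumor_volume(1, 1, 1), 0.5)
  expect_equal(tumor_volume(3, 2, 4), 12)
  expect_equal(tumor_volume(3, 2, 4), tumor_volume(4, 3, 2))
  expect_equal(tumor_volume(0, 5, 5), 0)
  expect_error(tumor_volume(-1, 1, 1), ">= 0")
})

test_that("response classification covers the four outcome patterns", {
  days <- c(0, 3, 7, 10, 14, 17, 21, 24, 28)
  expect_equal(classify_response(days, 2^(seq_along(days))), "progression")
  expect_equal(classify_response(c(0, 7, 14, 21, 28), c(5, 8, 0, 0, 0)),
               "complete_regression")
  expect_equal(classify_response(c(0, 7, 14, 21, 28), c(5, 8, 0, 10, 50)),
               "regression_with_regrowth")
  # deep but incomplete regression
  expect_equal(classify_response(c(0, 7, 14, 21, 28), c(5, 9, 2, 3, 6)),
               "growth_delay")
  expect_error(classify_response(c(0, 7), c(1, 2)), "at least 3")
})

test_that("classification is invariant to joint volume/threshold rescaling", {
  days <- c(0, 7, 14, 21, 28)
  vols <- c(5, 9, 0.8, 1.5, 40)
  for (s in c(0.1, 1, 25)) {
    expect_equal(
      classify_response(days, s * vols, disappearance_threshold_mm3 = s),
      classify_response(days, vols, disappearance_threshold_mm3 = 1))
  }
})

test_that("censoring truncates at the first volume above the endpoint", {
  out <- censor_at_endpoint(c(0, 3, 7, 10, 14), c(4, 20, 150, 230, 400))
  expect_equal(out$censored_day, 10)
  expect_equal(out$volumes, c(4, 20, 150, 230))
  none <- censor_at_endpoint(c(0, 3), c(4, 20))
  expect_true(is.na(none$censored_day))
})

test_that("arm_summary reports relative volumes and excludes censored days", {
  rec <- growth_records(data.frame(
    animal_id = c(rep("a", 3), rep("b", 3)),
    arm = "x",
    day = rep(c(0, 7, 14), 2),
    volume_mm3 = c(4, 8, 300, 4, 8, 16)))
  s <- arm_summary(rec)
  d14 <- s$per_day[s$per_day$day == 14, ]
  expect_equal(d14$n, 2L)  # censored animal contributes its endpoint day
  d7 <- s$per_day[s$per_day$day == 7, ]
  expect_equal(d7$mean_relative_volume, 2)
  expect_equal(d7$sd_relative_volume, 0)
  expect_equal(s$per_arm$censored, 1L)
  # a volume measured after crossing the endpoint no longer contributes
  rec2 <- growth_records(data.frame(
    animal_id = "a", arm = "x", day = c(0, 7, 14, 21),
    volume_mm3 = c(4, 8, 300, 600)))
  s2 <- arm_summary(rec2)
  expect_false(21 %in% s2$per_day$day)
  # missing day-0 volume is an error
  bad <- growth_records(data.frame(animal_id = "a", arm = "x",
                                   day = c(1, 2, 3), volume_mm3 = 1:3))
  expect_error(arm_summary(bad), "day-0")
})

test_that("dose-response threshold honors the exception allowance", {
  doses <- c(4.2, 10.5, 18.0, 21.0, 35.9)
  cr <- c(0, 0, 4, 5, 5)
  res <- dose_response_threshold(doses, cr, rep(5, 5), allowed_exceptions = 1)
  expect_equal(res$threshold_Gy, 18.0)
  expect_length(res$violations_dose_Gy, 0)
  strict <- dose_response_threshold(doses, cr, rep(5, 5),
                                    allowed_exceptions = 0)
  expect_equal(strict$threshold_Gy, 21.0)
  none <- dose_response_threshold(doses, rep(0, 5), rep(5, 5))
  expect_false(none$qualified)
  all_cr <- dose_response_threshold(doses, rep(5, 5), rep(5, 5))
  expect_equal(all_cr$threshold_Gy, 4.2)
})

test_that("apoptosis density summarizes per-field fractions", {
  a <- apoptosis_density(rep(10, 5), rep(100, 5))
  expect_equal(a$mean, 0.1)
  expect_equal(a$sd, 0)
  expect_equal(apoptosis_density(rep(0, 5), rep(100, 5))$mean, 0)
  expect_error(apoptosis_density(rep(1, 4), rep(10, 4)), "at least 5")
  expect_error(apoptosis_density(rep(1, 5), c(10, 10, 0, 10, 10)), "> 0")
  expect_error(apoptosis_density(rep(11, 5), rep(10, 5)), "total_cells")
  b <- apoptosis_density(c(28, 30, 32, 29, 31), rep(100, 5))
  cmp <- compare_apoptosis(b, apoptosis_density(c(9, 10, 11, 10, 10),
                                                rep(100, 5)))
  expect_equal(cmp$difference, 0.2)
  expect_true(is.numeric(cmp$p_value))
})

test_that("dose-ordered apoptosis generator yields dose-ordered estimates", {
  doses <- c(untreated = 0, low = 4.2, mid = 10.5, high = 21)
  df <- sim_apoptosis(doses, pattern = "dose_dependent", n_fields = 25,
                      seed = 5)
  means <- vapply(split(df, df$arm)[unique(df$arm)], function(d) {
    apoptosis_density(d$tunel_positive, d$total_cells)$mean
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})
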