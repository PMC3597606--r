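# Radioimmunotherapy outcomes: caliper tumor volumes, per-animal growth
# response classification, arm summaries, dose-response threshold, and
# TUNEL apoptotic-cell densities.

#' Caliper tumor volume
#'
#' V (mm^3) = width x height x depth / 2; symmetric in the three dimensions.
#'
#' @param width_mm,height_mm,depth_mm Caliper dimensions in mm (>= 0);
#'   vectorized.
#' @return Volume(s) in mm^3.
#' @export
tumor_volume <- function(width_mm, height_mm, depth_mm) {
  dims <- cbind(width_mm, height_mm, depth_mm)
  if (any(!is.finite(dims)) || any(dims < 0)) {
    stop("caliper dimensions must be finite and >= 0", call. = FALSE)
  }
  width_mm * height_mm * depth_mm / 2
}

#' Apply the humane-endpoint censoring rule
#'
#' Truncates a volume series at the first measurement exceeding the endpoint
#' volume (default 200 mm^3): that measurement is kept (the animal is
#' euthanized on that day) and later days are dropped.
#'
#' @param days,volumes Measurement series (days increasing).
#' @param endpoint_mm3 Euthanasia threshold (default 200 mm^3).
#' @return List with truncated `days`, `volumes`, and `censored_day`
#'   (`NA` if the endpoint was never reached).
#' @export
censor_at_endpoint <- function(days, volumes, endpoint_mm3 = 200) {
  stopifnot(length(days) == length(volumes), all(diff(days) > 0))
  hit <- which(volumes > endpoint_mm3)
  if (length(hit) == 0L) {
    return(list(days = days, volumes = volumes, censored_day = NA_real_))
  }
  k <- hit[1L]
  list(days = days[seq_len(k)], volumes = volumes[seq_len(k)],
       censored_day = days[k])
}

#' Classify a tumor growth response
#'
#' Labels a per-animal volume series as one of `"complete_regression"`,
#' `"regression_with_regrowth"`, `"growth_delay"` or `"progression"`:
#' \itemize{
#' \item complete_regression: the volume falls to or below the disappearance
#'   threshold at some day >= 7 and stays there through the end of
#'   observation;
#' \item regression_with_regrowth: the volume falls to or below the
#'   threshold but later exceeds `regrowth_factor` x threshold;
#' \item progression: the final volume exceeds the first and no sustained
#'   decrease occurred (a sustained decrease meaning a drop to half or less
#'   of the running maximum);
#' \item growth_delay: anything else.
#' }
#'
#' @param days,volumes Measurement series, >= 3 points, days increasing.
#' @param disappearance_threshold_mm3 Volume at or below which a tumor
#'   counts as disappeared (default 1 mm^3).
#' @param regrowth_factor Multiple of the threshold that counts as regrowth
#'   (default 2).
#' @param observation_end_day Last day of the observation window; days
#'   beyond it are ignored (default: last measured day).
#' @return A single response label (character).
#' @export
classify_response <- function(days, volumes, disappearance_threshold_mm3 = 1,
                              regrowth_factor = 2,
                              observation_end_day = max(days)) {
  stopifnot(length(days) == length(volumes))
  if (length(days) < 3L) {
    stop("response classification needs at least 3 time points", call. = FALSE)
  }
  if (any(diff(days) <= 0)) stop("`days` must be increasing", call. = FALSE)
  keep <- days <= observation_end_day
  days <- days[keep]; volumes <- volumes[keep]
  thr <- disappearance_threshold_mm3

  below <- which(volumes <= thr & days >= 7)
  if (length(below)) {
    first_below <- below[1L]
    later <- volumes[seq_along(volumes) > first_below]
    if (all(later <= thr)) return("complete_regression")
  }
  any_below <- which(volumes <= thr)
  if (length(any_below)) {
    later <- volumes[seq_along(volumes) > any_below[1L]]
    if (any(later > regrowth_factor * thr)) return("regression_with_regrowth")
  }
  running_max <- cummax(volumes)
  sustained_decrease <- any(volumes <= 0.5 * running_max & running_max > 0)
  if (volumes[length(volumes)] > volumes[1L] && !sustained_decrease) {
    return("progression")
  }
  "growth_delay"
}

#' Validate a growth-record table
#'
#' @param df Long data frame with columns `animal_id`, `arm`, `day`,
#'   `volume_mm3` and optionally `body_weight_g`.
#' @return The data frame with class `"growth_records"`.
#' @export
growth_records <- function(df) {
  need <- c("animal_id", "arm", "day", "volume_mm3")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("growth-record table is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (any(df$day < 0) || any(df$volume_mm3 < 0)) {
    stop("days and volumes must be >= 0", call. = FALSE)
  }
  df <- df[order(df$arm, df$animal_id, df$day), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("growth_records", "data.frame")
  df
}

#' Per-arm growth summary
#'
#' For each arm and measurement day: mean and SD of the relative tumor
#' volume (volume / the animal's day-0 volume) and the number of animals
#' still under observation (censored animals stop contributing after their
#' censoring day). Also reports, per arm, the complete-regression count
#' (via [classify_response()]) and the censored count.
#'
#' @param records A [growth_records()] table (pre-censoring volumes).
#' @param endpoint_mm3 Humane-endpoint volume for [censor_at_endpoint()].
#' @param ... Passed to [classify_response()].
#' @return List with `per_day` (arm, day, mean_relative_volume,
#'   sd_relative_volume, n) and `per_arm` (arm, n_animals,
#'   complete_regression, censored) data frames.
#' @export
arm_summary <- function(records, endpoint_mm3 = 200, ...) {
  records <- growth_records(as.data.frame(records))
  per_day <- list(); per_arm <- list()
  for (arm in unique(records$arm)) {
    sub <- records[records$arm == arm, , drop = FALSE]
    rel_rows <- list(); n_cr <- 0L; n_cens <- 0L; n_animals <- 0L
    for (id in unique(sub$animal_id)) {
      s <- sub[sub$animal_id == id, , drop = FALSE]
      if (!any(s$day == 0) || s$volume_mm3[s$day == 0] <= 0) {
        stop("animal '", id, "' in arm '", arm,
             "' has no positive day-0 volume", call. = FALSE)
      }
      n_animals <- n_animals + 1L
      cens <- censor_at_endpoint(s$day, s$volume_mm3,
                                 endpoint_mm3 = endpoint_mm3)
      if (!is.na(cens$censored_day)) n_cens <- n_cens + 1L
      if (classify_response(cens$days, cens$volumes, ...) ==
          "complete_regression") n_cr <- n_cr + 1L
      rel_rows[[id]] <- data.frame(
        day = cens$days,
        rel = cens$volumes / cens$volumes[cens$days == 0])
    }
    rel <- do.call(rbind, rel_rows)
    agg <- stats::aggregate(rel$rel, by = list(day = rel$day),
                            FUN = function(v) c(mean = mean(v),
                                                sd = if (length(v) > 1) stats::sd(v) else 0,
                                                n = length(v)))
    per_day[[as.character(arm)]] <- data.frame(
      arm = arm, day = agg$day,
      mean_relative_volume = agg$x[, "mean"],
      sd_relative_volume = agg$x[, "sd"],
      n = as.integer(agg$x[, "n"]))
    per_arm[[as.character(arm)]] <- data.frame(
      arm = arm, n_animals = n_animals, complete_regression = n_cr,
      censored = n_cens)
  }
  list(per_day = do.call(rbind, c(per_day, make.row.names = FALSE)),
       per_arm = do.call(rbind, c(per_arm, make.row.names = FALSE)))
}

#' Minimal absorbed dose achieving complete regression
#'
#' An arm "qualifies" when at least `n_total - allowed_exceptions` of its
#' animals achieved complete regression. Returns the minimum dose among
#' qualifying arms together with any higher-dose arms that failed to
#' qualify (which should be empty for a monotone dose-response).
#'
#' @param dose_Gy Absorbed dose per arm (Gy).
#' @param n_complete Complete-regression count per arm.
#' @param n_total Animals per arm.
#' @param allowed_exceptions Number of non-responding animals an arm may
#'   contain and still qualify (default 1).
#' @return List with `threshold_Gy` (`NA` and `qualified = FALSE` when no
#'   arm qualifies), `qualifying_dose_Gy`, and `violations_dose_Gy`
#'   (non-qualifying arms above the threshold).
#' @export
dose_response_threshold <- function(dose_Gy, n_complete, n_total,
                                    allowed_exceptions = 1) {
  stopifnot(length(dose_Gy) == length(n_complete),
            length(dose_Gy) == length(n_total))
  if (any(n_complete > n_total)) {
    stop("`n_complete` cannot exceed `n_total`", call. = FALSE)
  }
  ok <- n_complete >= (n_total - allowed_exceptions)
  if (!any(ok)) {
    return(list(threshold_Gy = NA_real_, qualified = FALSE,
                qualifying_dose_Gy = numeric(0),
                violations_dose_Gy = numeric(0)))
  }
  thr <- min(dose_Gy[ok])
  list(threshold_Gy = thr, qualified = TRUE,
       qualifying_dose_Gy = sort(dose_Gy[ok]),
       violations_dose_Gy = sort(dose_Gy[!ok & dose_Gy > thr]))
}

#' Apoptotic-cell density from TUNEL field counts
#'
#' Per-field fraction of TUNEL-positive cells, summarized as mean and sample
#' SD over at least five randomly selected fields.
#'
#' @param tunel_positive Positive-cell counts per field (>= 0).
#' @param total_cells Total cells per field (> 0), same length.
#' @return List with `mean`, `sd`, `n_fields`, `fractions`.
#' @export
apoptosis_density <- function(tunel_positive, total_cells) {
  stopifnot(length(tunel_positive) == length(total_cells))
  if (length(tunel_positive) < 5L) {
    stop("apoptosis quantification needs at least 5 fields", call. = FALSE)
  }
  if (any(total_cells <= 0)) {
    stop("`total_cells` must be > 0 in every field", call. = FALSE)
  }
  if (any(tunel_positive < 0) || any(tunel_positive > total_cells)) {
    stop("`tunel_positive` must lie in [0, total_cells]", call. = FALSE)
  }
  frac <- tunel_positive / total_cells
  list(mean = mean(frac), sd = stats::sd(frac), n_fields = length(frac),
       fractions = frac)
}

#' Descriptive two-arm comparison of apoptotic densities
#'
#' Delegates to a Welch two-sample t-test on the per-field fractions and
#' reports the result descriptively.
#'
#' @param a,b Results of [apoptosis_density()] for two arms.
#' @return List with the two means, their difference, and the t-test
#'   `p_value`.
#' @export
compare_apoptosis <- function(a, b) {
  tt <- stats::t.test(a$fractions, b$fractions)
  list(mean_a = a$mean, mean_b = b$mean, difference = a$mean - b$mean,
       p_value = tt$p.value)
}
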