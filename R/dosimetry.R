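# MIRD-style tumor absorbed dose from a surrogate-nuclide biodistribution:
# remove the decay correction with the therapeutic nuclide's half-life,
# integrate the physical time-activity curve, convert units, multiply by
# injected activity and the mean energy per transition.

#' Unit conversion: (%ID/g) x day to s/kg
#'
#' One (%ID/g).day of a time-activity curve per unit injected activity equals
#' 86400 s/day x (1/100 per percent) x (1000 g/kg) = 864000 s/kg. The whole
#' unit chain of the dose computation is concentrated in this one constant.
#' @export
PIDG_DAY_TO_S_PER_KG <- 86400 * 10

#' Time-activity curve
#'
#' Tissue activity concentration (%ID/g) per unit injected activity versus
#' time after injection, flagged as decay-corrected (biological kinetics
#' only) or physical (decay included).
#'
#' @param times_day Strictly increasing times in days (>= 0).
#' @param conc_pid_g Concentrations (%ID/g, >= 0), same length.
#' @param decay_corrected Logical flag.
#' @param nuclide Optional [nuclide()] annotation (the nuclide whose decay
#'   the physical curve includes, or the counting surrogate for a
#'   decay-corrected curve).
#' @return A data frame of class `"time_activity_curve"`.
#' @export
time_activity_curve <- function(times_day, conc_pid_g, decay_corrected = TRUE,
                                nuclide = NULL) {
  stopifnot(length(times_day) == length(conc_pid_g))
  if (any(!is.finite(times_day)) || any(times_day < 0) ||
      any(diff(times_day) <= 0)) {
    stop("`times_day` must be >= 0 and strictly increasing", call. = FALSE)
  }
  if (any(!is.finite(conc_pid_g)) || any(conc_pid_g < 0)) {
    stop("`conc_pid_g` must be finite and >= 0", call. = FALSE)
  }
  structure(
    data.frame(times_day = as.numeric(times_day),
               conc_pid_g = as.numeric(conc_pid_g)),
    decay_corrected = isTRUE(decay_corrected),
    nuclide = nuclide,
    class = c("time_activity_curve", "data.frame")
  )
}

#' Extract a tissue time-activity curve from a biodistribution table
#'
#' @param table A [biodist_table()] (decay-corrected by convention).
#' @param tissue Row label, default `"Tumor"`.
#' @return A decay-corrected [time_activity_curve()].
#' @export
biodist_tac <- function(table, tissue = "Tumor") {
  stopifnot(inherits(table, "biodist_table"))
  rows <- table[table$tissue == tissue, , drop = FALSE]
  if (nrow(rows) == 0L) {
    stop("no '", tissue, "' row in the biodistribution table", call. = FALSE)
  }
  rows <- rows[order(rows$day), , drop = FALSE]
  time_activity_curve(rows$day, rows$mean_pid_g, decay_corrected = TRUE,
                      nuclide = attr(table, "nuclide"))
}

#' Convert a decay-corrected curve to the physical curve of a therapeutic
#' nuclide
#'
#' Multiplies each decay-corrected value by the therapeutic nuclide's decay
#' factor at that time (days converted to hours as day x 24), under the
#' standard surrogate assumption that the biological kinetics of the
#' surrogate-labeled and therapeutic-labeled conjugates are identical.
#'
#' @param tac A decay-corrected [time_activity_curve()].
#' @param therapeutic The therapeutic [nuclide()] (e.g. 90Y).
#' @return A physical [time_activity_curve()] (`decay_corrected = FALSE`).
#' @export
to_physical_curve <- function(tac, therapeutic) {
  stopifnot(inherits(tac, "time_activity_curve"),
            inherits(therapeutic, "nuclide"))
  if (!attr(tac, "decay_corrected")) {
    stop("curve is already physical; refusing to apply decay twice",
         call. = FALSE)
  }
  time_activity_curve(
    tac$times_day,
    tac$conc_pid_g * decay_factor(therapeutic, 24 * tac$times_day),
    decay_corrected = FALSE,
    nuclide = therapeutic
  )
}

#' Trapezoidal AUC of a physical time-activity curve
#'
#' Piecewise-linear integration over \[0, t_last\]. With
#' `anchor_zero_at_origin` (the default) a (0, 0) point is prepended when the
#' curve does not start at t = 0, reflecting zero tumor activity at the
#' moment of injection. The raw area in (%ID/g).day is also returned in
#' s/kg per unit injected activity via [PIDG_DAY_TO_S_PER_KG].
#'
#' @param tac A physical [time_activity_curve()].
#' @param anchor_zero_at_origin Prepend (0, 0) when absent.
#' @return List with `auc_pidg_day`, `auc_s_per_kg`, and the integration
#'   window `window_day`.
#' @export
trapezoid_auc <- function(tac, anchor_zero_at_origin = TRUE) {
  stopifnot(inherits(tac, "time_activity_curve"))
  if (attr(tac, "decay_corrected")) {
    stop("AUC must be computed on a physical curve; call to_physical_curve() first",
         call. = FALSE)
  }
  t <- tac$times_day
  y <- tac$conc_pid_g
  if (anchor_zero_at_origin && t[1L] > 0) {
    t <- c(0, t)
    y <- c(0, y)
  }
  if (length(t) < 2L) {
    stop("need at least two points (or a zero anchor) to integrate",
         call. = FALSE)
  }
  auc <- pracma::trapz(t, y)
  list(auc_pidg_day = auc,
       auc_s_per_kg = auc * PIDG_DAY_TO_S_PER_KG,
       window_day = c(t[1L], t[length(t)]))
}

#' Tumor absorbed dose from AUC and injected activity
#'
#' Self-dose approximation for a beta emitter fully absorbed in the tumor:
#' D (Gy) = A0 (Bq) x AUC (s/kg) x Delta (Gy kg / (Bq s)), with
#' Delta = [mean_energy_per_transition()] of the nuclide's mean beta energy.
#'
#' @param auc_s_per_kg AUC per unit injected activity, s/kg (> 0).
#' @param injected_MBq Injected activity in MBq (> 0).
#' @param nuclide Therapeutic [nuclide()]; must carry a mean beta energy.
#' @param antibody Optional label carried into the result.
#' @param window_day Optional integration window annotation.
#' @return A list of class `"absorbed_dose_result"` with `dose_Gy`, `delta`,
#'   `auc_s_per_kg`, `injected_MBq`.
#' @export
absorbed_dose <- function(auc_s_per_kg, injected_MBq, nuclide,
                          antibody = "", window_day = c(0, NA_real_)) {
  stopifnot(inherits(nuclide, "nuclide"))
  if (is.na(nuclide$mean_beta_energy_MeV)) {
    stop("nuclide '", nuclide$name,
         "' has no mean beta energy; cannot compute an absorbed dose",
         call. = FALSE)
  }
  if (!is.numeric(auc_s_per_kg) || auc_s_per_kg < 0) {
    stop("`auc_s_per_kg` must be >= 0", call. = FALSE)
  }
  if (!is.numeric(injected_MBq) || injected_MBq <= 0) {
    stop("`injected_MBq` must be > 0", call. = FALSE)
  }
  delta <- mean_energy_per_transition(nuclide$mean_beta_energy_MeV)
  structure(
    list(antibody = antibody,
         nuclide = nuclide$name,
         injected_MBq = injected_MBq,
         auc_s_per_kg = auc_s_per_kg,
         delta = delta,
         dose_Gy = injected_MBq * 1e6 * auc_s_per_kg * delta,
         integration_window_day = window_day),
    class = "absorbed_dose_result"
  )
}

#' @export
print.absorbed_dose_result <- function(x, ...) {
  cat(sprintf("<absorbed_dose> %s%s: %.3g MBq -> %.3f Gy (AUC %.4g s/kg, Delta %.4g Gy kg/(Bq s))\n",
              if (nzchar(x$antibody)) paste0(x$antibody, " ") else "",
              x$nuclide, x$injected_MBq, x$dose_Gy, x$auc_s_per_kg, x$delta))
  invisible(x)
}

#' End-to-end tumor dose table from a biodistribution table
#'
#' Composes the full chain for one treatment arm list: extract the tumor
#' time-activity curve, remove the decay correction for the therapeutic
#' nuclide, integrate with a zero-anchored trapezoid, and convert to
#' absorbed dose for each injected activity.
#'
#' @param table A [biodist_table()] with a tumor row at >= 2 days.
#' @param activities_MBq Numeric vector of injected activities (MBq).
#' @param therapeutic Therapeutic [nuclide()], default 90Y.
#' @param tissue Tumor row label.
#' @param anchor_zero_at_origin Passed to [trapezoid_auc()].
#' @return Data frame with columns `injected_MBq`, `dose_Gy`; attributes
#'   `auc_pidg_day`, `auc_s_per_kg`, `antibody`, `assumptions`.
#' @export
dose_table <- function(table, activities_MBq,
                       therapeutic = get_nuclide("90Y"), tissue = "Tumor",
                       anchor_zero_at_origin = TRUE) {
  stopifnot(inherits(table, "biodist_table"))
  tac <- biodist_tac(table, tissue = tissue)
  if (nrow(tac) < 2L) {
    stop("dose_table needs the '", tissue, "' row at >= 2 days", call. = FALSE)
  }
  phys <- to_physical_curve(tac, therapeutic)
  auc <- trapezoid_auc(phys, anchor_zero_at_origin = anchor_zero_at_origin)
  doses <- vapply(activities_MBq, function(a) {
    absorbed_dose(auc$auc_s_per_kg, a, therapeutic,
                  antibody = attr(table, "antibody"),
                  window_day = auc$window_day)$dose_Gy
  }, numeric(1))
  structure(
    data.frame(injected_MBq = as.numeric(activities_MBq), dose_Gy = doses),
    auc_pidg_day = auc$auc_pidg_day,
    auc_s_per_kg = auc$auc_s_per_kg,
    window_day = auc$window_day,
    antibody = attr(table, "antibody"),
    nuclide = therapeutic$name,
    assumptions = c(
      "surrogate biological kinetics assumed identical for the therapeutic conjugate",
      "complete local absorption of beta energy within the tumor",
      sprintf("zero-anchored trapezoidal integration over [%g, %g] days",
              auc$window_day[1], auc$window_day[2])),
    class = c("dose_table", "data.frame")
  )
}
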