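# Radioligand binding assays: Lindmo immunoreactive fraction, homologous
# competition affinity, and internalization compartment fractions.

#' Cell-binding curve
#'
#' Serially diluted cells incubated with a fixed trace amount of radiolabeled
#' antibody; the bound fraction rises toward the immunoreactive fraction as
#' antigen goes to excess.
#'
#' @param cells_per_tube Cell numbers per tube (> 0), at least 3 points.
#' @param bound_fraction Fraction of added radioactivity bound, in \[0, 1\].
#' @param label Curve identifier (e.g. the antibody name).
#' @return A data frame of class `"cell_binding_curve"`.
#' @export
cell_binding_curve <- function(cells_per_tube, bound_fraction, label = "") {
  stopifnot(length(cells_per_tube) == length(bound_fraction))
  if (length(cells_per_tube) < 3L) {
    stop("a cell-binding curve needs at least 3 points", call. = FALSE)
  }
  if (any(!is.finite(cells_per_tube)) || any(cells_per_tube <= 0)) {
    stop("`cells_per_tube` must be strictly positive", call. = FALSE)
  }
  if (any(!is.finite(bound_fraction)) || any(bound_fraction < 0) ||
      any(bound_fraction > 1)) {
    stop("`bound_fraction` must lie in [0, 1]", call. = FALSE)
  }
  structure(
    data.frame(cells_per_tube = as.numeric(cells_per_tube),
               bound_fraction = as.numeric(bound_fraction)),
    label = label,
    class = c("cell_binding_curve", "data.frame")
  )
}

#' Lindmo immunoreactive-fraction fit
#'
#' Double-inverse linearization of the saturation binding curve: regressing
#' y = total/bound on x = 1/cells gives intercept 1/r at infinite antigen
#' excess, where r is the immunoreactive fraction. The default weighting is
#' proportional to bound_fraction^2, which under multiplicative measurement
#' noise makes the transformed residual variance approximately constant.
#'
#' @param curve A [cell_binding_curve()]; all bound fractions must be > 0.
#' @param weighted Use bound^2 regression weights (default) or ordinary
#'   least squares.
#' @return A list of class `"binding_fit"` with elements
#'   `immunoreactive_fraction`, `se`, `rss`, `n_points`, `flags`.
#' @export
lindmo_fit <- function(curve, weighted = TRUE) {
  stopifnot(inherits(curve, "cell_binding_curve"))
  if (any(curve$bound_fraction <= 0)) {
    stop("Lindmo fit requires strictly positive bound fractions", call. = FALSE)
  }
  x <- 1 / curve$cells_per_tube
  y <- 1 / curve$bound_fraction
  w <- if (weighted) curve$bound_fraction^2 else rep(1, length(y))
  fit <- stats::lm(y ~ x, weights = w)
  intercept <- unname(stats::coef(fit)[1L])
  if (!is.finite(intercept) || intercept <= 0) {
    stop("Lindmo fit failed: non-positive intercept ", format(intercept),
         " (no saturation in the data?); coefficients: ",
         paste(format(stats::coef(fit)), collapse = ", "), call. = FALSE)
  }
  r <- 1 / intercept
  if (r > 1.5) {
    stop("Lindmo fit failed: immunoreactive fraction ", format(r),
         " outside the admissible range (0, 1.5]", call. = FALSE)
  }
  # noise-free curves fit exactly; summary.lm's perfect-fit warning is
  # uninformative there
  se_int <- suppressWarnings(summary(fit))$coefficients[1L, 2L]
  flags <- character(0)
  if (r > 1.05) flags <- c(flags, "immunoreactive_fraction_above_1")
  structure(
    list(method = "lindmo",
         immunoreactive_fraction = r,
         se = se_int / intercept^2,  # delta method for 1/intercept
         rss = sum(w * stats::residuals(fit)^2),
         n_points = nrow(curve),
         flags = flags),
    class = "binding_fit"
  )
}

#' Competition (homologous displacement) curve
#'
#' Bound signal at a fixed labeled-antibody concentration versus increasing
#' unlabeled-competitor concentration.
#'
#' @param conc_nM Competitor concentrations (nM, >= 0); at least 5 points,
#'   positive concentrations spanning at least two orders of magnitude, and
#'   at least one zero-competitor point.
#' @param bound_signal Bound counts (>= 0), same length.
#' @param labeled_conc_nM Concentration of the labeled antibody (nM, > 0).
#' @param label Curve identifier.
#' @return A data frame of class `"competition_curve"`.
#' @export
competition_curve <- function(conc_nM, bound_signal, labeled_conc_nM,
                              label = "") {
  stopifnot(length(conc_nM) == length(bound_signal))
  if (length(conc_nM) < 5L) {
    stop("a competition curve needs at least 5 points", call. = FALSE)
  }
  if (any(!is.finite(conc_nM)) || any(conc_nM < 0)) {
    stop("`conc_nM` must be >= 0", call. = FALSE)
  }
  if (!any(conc_nM == 0)) {
    stop("a competition curve needs at least one zero-competitor point",
         call. = FALSE)
  }
  pos <- conc_nM[conc_nM > 0]
  if (length(pos) < 2L || max(pos) / min(pos) < 100) {
    stop("positive competitor concentrations must span >= 2 orders of magnitude",
         call. = FALSE)
  }
  if (any(!is.finite(bound_signal)) || any(bound_signal < 0)) {
    stop("`bound_signal` must be >= 0", call. = FALSE)
  }
  if (!is.numeric(labeled_conc_nM) || labeled_conc_nM <= 0) {
    stop("`labeled_conc_nM` must be > 0", call. = FALSE)
  }
  structure(
    data.frame(conc_nM = as.numeric(conc_nM),
               bound_signal = as.numeric(bound_signal)),
    labeled_conc_nM = as.numeric(labeled_conc_nM),
    label = label,
    class = c("competition_curve", "data.frame")
  )
}

#' One-site homologous competition fit
#'
#' Fits B(c) = NS + (B0 - NS) / (1 + c/IC50) by constrained least squares,
#' starting from a deterministic grid of IC50 values and refining the best
#' start with Levenberg-Marquardt. Because labeled and unlabeled ligand are
#' the same antibody (homologous design), the dissociation constant is
#' Kd = IC50 - L where L is the labeled-antibody concentration; if the fit
#' puts IC50 at or below L, Kd is floored at a small positive epsilon and
#' flagged. Both IC50 and Kd are reported.
#'
#' @param curve A [competition_curve()].
#' @param ic50_grid Deterministic multi-start grid for IC50 (nM); defaults
#'   to a log-spaced grid over (1e-3, 1e4).
#' @return A list of class `"binding_fit"` with elements `kd_nM`, `ic50_nM`,
#'   `b0`, `ns`, `se_ic50`, `rss`, `n_points`, `flags`.
#' @export
homologous_competition_fit <- function(curve,
                                       ic50_grid = 10^seq(-3, 4, by = 0.5)) {
  stopifnot(inherits(curve, "competition_curve"))
  L <- attr(curve, "labeled_conc_nM")
  b0_start <- max(curve$bound_signal)
  ns_start <- max(min(curve$bound_signal), 1e-9)
  best <- NULL
  for (ic50_0 in ic50_grid) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        bound_signal ~ ns + (b0 - ns) / (1 + conc_nM / ic50),
        data = curve,
        start = list(b0 = b0_start, ns = ns_start, ic50 = ic50_0),
        lower = c(b0 = 1e-9, ns = 0, ic50 = 1e-6),
        upper = c(b0 = Inf, ns = Inf, ic50 = 1e4),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    rss <- sum(stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss - 1e-12) {
      best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best)) {
    stop("competition fit did not converge from any start", call. = FALSE)
  }
  cf <- stats::coef(best$fit)
  ic50 <- unname(cf["ic50"])
  flags <- character(0)
  kd <- ic50 - L
  if (kd <= 0) {
    kd <- 1e-6
    flags <- c(flags, "ic50_not_above_labeled_conc")
  }
  if (max(curve$conc_nM) < 10 * ic50) {
    flags <- c(flags, "plateau_not_covered")
  }
  se_ic50 <- tryCatch(summary(best$fit)$coefficients["ic50", "Std. Error"],
                      error = function(e) NA_real_)
  structure(
    list(method = "homologous_competition",
         kd_nM = kd,
         ic50_nM = ic50,
         labeled_conc_nM = L,
         b0 = unname(cf["b0"]),
         ns = unname(cf["ns"]),
         se_ic50 = se_ic50,
         rss = best$rss,
         n_points = nrow(curve),
         flags = flags),
    class = "binding_fit"
  )
}

#' @export
print.binding_fit <- function(x, ...) {
  if (x$method == "lindmo") {
    cat(sprintf("<binding_fit> Lindmo: r = %.4f (SE %.2g), n = %d, RSS = %.3g\n",
                x$immunoreactive_fraction, x$se, x$n_points, x$rss))
  } else {
    cat(sprintf(
      "<binding_fit> homologous competition: Kd = %.4g nM (IC50 = %.4g nM, L = %g nM), n = %d\n",
      x$kd_nM, x$ic50_nM, x$labeled_conc_nM, x$n_points))
  }
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Internalization time course
#'
#' Counts in the four compartments of the internalization assay at each
#' sampling time: acid-resistant cell pellet (internalized), acid-released
#' membrane-bound, and the TCA-precipitable (protein-bound) and soluble
#' (non-protein-bound) fractions of the culture medium.
#'
#' @param times_h Sampling times (hours, >= 0), strictly increasing.
#' @param internalized,membrane_bound,medium_protein_bound,medium_non_protein_bound
#'   Counts >= 0, one per time point.
#' @return A data frame of class `"internalization_timecourse"`.
#' @export
internalization_timecourse <- function(times_h, internalized, membrane_bound,
                                       medium_protein_bound,
                                       medium_non_protein_bound) {
  n <- length(times_h)
  stopifnot(length(internalized) == n, length(membrane_bound) == n,
            length(medium_protein_bound) == n,
            length(medium_non_protein_bound) == n)
  if (any(!is.finite(times_h)) || any(times_h < 0) ||
      any(diff(times_h) <= 0)) {
    stop("`times_h` must be >= 0 and strictly increasing", call. = FALSE)
  }
  counts <- cbind(internalized, membrane_bound, medium_protein_bound,
                  medium_non_protein_bound)
  if (any(!is.finite(counts)) || any(counts < 0)) {
    stop("compartment counts must be finite and >= 0", call. = FALSE)
  }
  structure(
    data.frame(times_h = as.numeric(times_h),
               internalized = as.numeric(internalized),
               membrane_bound = as.numeric(membrane_bound),
               medium_protein_bound = as.numeric(medium_protein_bound),
               medium_non_protein_bound = as.numeric(medium_non_protein_bound)),
    class = c("internalization_timecourse", "data.frame")
  )
}

#' Compartment fractions of total radioactivity
#'
#' At each time point divides each compartment count by the four-compartment
#' total, mirroring the "% of total radioactivity" presentation of
#' internalization assays. Fractions sum to 1 at every time.
#'
#' @param tc An [internalization_timecourse()].
#' @return Data frame with `times_h` and the four compartment fractions.
#' @export
internalization_fractions <- function(tc) {
  stopifnot(inherits(tc, "internalization_timecourse"))
  comp <- c("internalized", "membrane_bound", "medium_protein_bound",
            "medium_non_protein_bound")
  tot <- rowSums(tc[comp])
  if (any(tot <= 0)) {
    bad <- tc$times_h[tot <= 0]
    stop("total radioactivity is zero at time(s) ",
         paste(bad, collapse = ", "), " h", call. = FALSE)
  }
  out <- tc
  out[comp] <- tc[comp] / tot
  class(out) <- "data.frame"
  out
}
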