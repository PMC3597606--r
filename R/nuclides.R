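# Radionuclide constants and decay arithmetic.
#
# All decay arithmetic works in hours internally; day-indexed inputs are
# converted as day * 24 exactly.

#' Joules per MeV
#'
#' Conversion constant: 1 eV = 1.60218e-19 J, so 1 MeV = 1.60218e-13 J.
#' @export
JOULE_PER_MEV <- 1.60218e-13

#' Construct a radionuclide record
#'
#' A nuclide carries the physical constants needed by the dose chain: the
#' physical half-life (hours) and, for beta emitters, the mean emitted beta
#' energy per transition (MeV). Gamma-emitting surrogates used only for
#' counting (e.g. 111In) may omit the beta energy.
#'
#' @param name Identifier, e.g. `"90Y"`.
#' @param half_life_h Physical half-life in hours; must be positive.
#' @param mean_beta_energy_MeV Mean emitted beta energy per transition in
#'   MeV, or `NA` for nuclides not used as the therapeutic emitter.
#' @param emission_note Free-text annotation (e.g. maximum beta energy and
#'   particle range, which are not used computationally).
#' @return An object of class `"nuclide"`.
#' @examples
#' y90 <- nuclide("90Y", half_life_h = 64.1, mean_beta_energy_MeV = 0.9331)
#' decay_factor(y90, 64.1)  # one half-life -> 0.5
#' @export
nuclide <- function(name, half_life_h, mean_beta_energy_MeV = NA_real_,
                    emission_note = "") {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!is.numeric(half_life_h) || length(half_life_h) != 1L ||
      !is.finite(half_life_h) || half_life_h <= 0) {
    stop("`half_life_h` must be a single positive finite number (hours), got ",
         deparse(half_life_h), call. = FALSE)
  }
  if (!is.na(mean_beta_energy_MeV) &&
      (!is.numeric(mean_beta_energy_MeV) || mean_beta_energy_MeV < 0)) {
    stop("`mean_beta_energy_MeV` must be >= 0 or NA", call. = FALSE)
  }
  structure(
    list(name = name,
         half_life_h = as.numeric(half_life_h),
         mean_beta_energy_MeV = as.numeric(mean_beta_energy_MeV),
         emission_note = emission_note),
    class = "nuclide"
  )
}

#' @export
print.nuclide <- function(x, ...) {
  cat(sprintf("<nuclide> %s: T1/2 = %g h (lambda = %.6g /h)",
              x$name, x$half_life_h, decay_constant(x)))
  if (!is.na(x$mean_beta_energy_MeV)) {
    cat(sprintf(", mean beta energy = %g MeV", x$mean_beta_energy_MeV))
  }
  cat("\n")
  if (nzchar(x$emission_note)) cat("  note: ", x$emission_note, "\n", sep = "")
  invisible(x)
}

#' Physical decay constant
#'
#' @param nuclide A [nuclide()] object.
#' @return Decay constant lambda = ln(2) / half-life, per hour.
#' @export
decay_constant <- function(nuclide) {
  stopifnot(inherits(nuclide, "nuclide"))
  log(2) / nuclide$half_life_h
}

#' Physical decay factor
#'
#' Fraction of activity remaining after `t_h` hours: exp(-lambda t).
#'
#' @param nuclide A [nuclide()] object.
#' @param t_h Elapsed time in hours; vectorized, all values must be >= 0.
#' @return Dimensionless fraction(s) in (0, 1].
#' @export
decay_factor <- function(nuclide, t_h) {
  stopifnot(inherits(nuclide, "nuclide"))
  if (!is.numeric(t_h) || any(!is.finite(t_h)) || any(t_h < 0)) {
    stop("`t_h` must be finite and >= 0 (hours)", call. = FALSE)
  }
  exp(-decay_constant(nuclide) * t_h)
}

#' Mean energy emitted per transition
#'
#' Converts a mean emitted energy per decay (MeV) to absorbed-dose units:
#' Gy kg per (Bq s), i.e. joules per decay. For a pure beta emitter fully
#' absorbed in the source tissue this is the dose-conversion constant Delta;
#' for 90Y (mean beta energy 0.9331 MeV) it evaluates to 1.495e-13.
#'
#' @param mean_energy_MeV Mean emitted energy per transition, MeV (>= 0).
#' @return Delta in Gy kg / (Bq s).
#' @export
mean_energy_per_transition <- function(mean_energy_MeV) {
  if (!is.numeric(mean_energy_MeV) || any(!is.finite(mean_energy_MeV)) ||
      any(mean_energy_MeV < 0)) {
    stop("`mean_energy_MeV` must be finite and >= 0", call. = FALSE)
  }
  mean_energy_MeV * JOULE_PER_MEV
}

#' Built-in nuclide registry
#'
#' Default physical constants: 90Y (64.1 h half-life, mean beta energy
#' 0.9331 MeV), and the counting surrogates 111In (67.31 h) and 125I
#' (1425.6 h) whose half-lives come from standard references and never
#' enter the dose chain (biodistribution tables are decay-corrected).
#' Override any entry with [read_nuclide_registry()].
#'
#' @return Named list of [nuclide()] objects.
#' @export
default_nuclides <- function() {
  list(
    "90Y" = nuclide("90Y", 64.1, 0.9331,
                    "pure beta emitter; max energy 2.3 MeV, max range in water 11.3 mm (annotation only)"),
    "111In" = nuclide("111In", 67.31, NA_real_,
                      "gamma/Auger surrogate for counting; not a therapeutic beta source here"),
    "125I" = nuclide("125I", 1425.6, NA_real_,
                     "gamma/Auger label used in internalization assays")
  )
}

#' Look up a nuclide by name
#'
#' @param name Registry key, e.g. `"90Y"`.
#' @param registry Named list of nuclides; defaults to [default_nuclides()].
#' @export
get_nuclide <- function(name, registry = default_nuclides()) {
  if (!name %in% names(registry)) {
    stop("unknown nuclide '", name, "'; registry has: ",
         paste(names(registry), collapse = ", "), call. = FALSE)
  }
  registry[[name]]
}

#' Read a nuclide registry from JSON
#'
#' The file holds an array of records `{name, half_life_h,
#' mean_beta_energy_MeV, emission_note}`; entries override or extend the
#' built-in registry.
#'
#' @param path JSON file path.
#' @param base Registry to extend; defaults to [default_nuclides()].
#' @return Named list of [nuclide()] objects.
#' @export
read_nuclide_registry <- function(path, base = default_nuclides()) {
  recs <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  if (is.null(recs$name) || is.null(recs$half_life_h)) {
    stop("nuclide registry needs columns `name` and `half_life_h`: ", path,
         call. = FALSE)
  }
  for (i in seq_len(nrow(recs))) {
    base[[recs$name[i]]] <- nuclide(
      recs$name[i], recs$half_life_h[i],
      if ("mean_beta_energy_MeV" %in% names(recs) &&
          !is.na(recs$mean_beta_energy_MeV[i]))
        recs$mean_beta_energy_MeV[i] else NA_real_,
      if ("emission_note" %in% names(recs) && !is.na(recs$emission_note[i]))
        recs$emission_note[i] else ""
    )
  }
  base
}
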