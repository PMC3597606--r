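# Configuration, CSV readers with actionable errors, and machine-readable
# JSON reports binding the modules into reproducible runs.

#' Run configuration
#'
#' Bundles the tunable pipeline settings: normalization body weight,
#' integration flags, response thresholds and the RNG seed. Round-trips
#' through JSON unchanged via [write_run_config()] / [read_run_config()].
#'
#' @param reference_bw_g Body-weight normalization reference (g).
#' @param anchor_zero_at_origin Prepend (0, 0) to time-activity curves.
#' @param integration_window_day Upper AUC limit (days after injection).
#' @param disappearance_threshold_mm3,regrowth_factor,observation_end_day
#'   Response-classification settings.
#' @param endpoint_mm3 Humane-endpoint volume (mm^3).
#' @param allowed_exceptions Non-responders tolerated per qualifying arm.
#' @param seed RNG seed recorded in reports.
#' @return A list of class `"run_config"`.
#' @export
run_config <- function(reference_bw_g = 20, anchor_zero_at_origin = TRUE,
                       integration_window_day = 10,
                       disappearance_threshold_mm3 = 1, regrowth_factor = 2,
                       observation_end_day = 28, endpoint_mm3 = 200,
                       allowed_exceptions = 1, seed = 1L) {
  structure(
    list(reference_bw_g = reference_bw_g,
         anchor_zero_at_origin = anchor_zero_at_origin,
         integration_window_day = integration_window_day,
         disappearance_threshold_mm3 = disappearance_threshold_mm3,
         regrowth_factor = regrowth_factor,
         observation_end_day = observation_end_day,
         endpoint_mm3 = endpoint_mm3,
         allowed_exceptions = allowed_exceptions,
         seed = seed),
    class = "run_config"
  )
}

#' @rdname run_config
#' @param config A `"run_config"` object.
#' @param path JSON file path.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  vals <- jsonlite::fromJSON(path)
  do.call(run_config, vals)
}

check_columns <- function(df, need, what, path) {
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop(what, " file ", path, " is missing required column(s): ",
         paste(miss, collapse = ", "), "; found: ",
         paste(names(df), collapse = ", "), call. = FALSE)
  }
  invisible(df)
}

#' Assay CSV readers
#'
#' Read the module input schemas, rejecting files with missing required
#' columns. Schemas: binding `cells,bound_fraction`; competition
#' `conc_nM,counts`; internalization
#' `time_h,internalized,membrane,medium_protein,medium_free`; growth
#' `animal_id,arm,day,width_mm,height_mm,depth_mm[,body_weight_g]` (volumes
#' computed via [tumor_volume()]); apoptosis
#' `arm,field_id,tunel_positive,total_cells`.
#'
#' @param path CSV file path.
#' @return The corresponding validated object.
#' @export
read_binding_csv <- function(path) {
  df <- utils::read.csv(path)
  check_columns(df, c("cells", "bound_fraction"), "binding assay", path)
  cell_binding_curve(df$cells, df$bound_fraction, label = basename(path))
}

#' @rdname read_binding_csv
#' @param labeled_conc_nM Labeled-antibody concentration (nM).
#' @export
read_competition_csv <- function(path, labeled_conc_nM) {
  df <- utils::read.csv(path)
  check_columns(df, c("conc_nM", "counts"), "competition assay", path)
  competition_curve(df$conc_nM, df$counts, labeled_conc_nM,
                    label = basename(path))
}

#' @rdname read_binding_csv
#' @export
read_internalization_csv <- function(path) {
  df <- utils::read.csv(path)
  check_columns(df, c("time_h", "internalized", "membrane", "medium_protein",
                      "medium_free"), "internalization assay", path)
  internalization_timecourse(df$time_h, df$internalized, df$membrane,
                             df$medium_protein, df$medium_free)
}

#' @rdname read_binding_csv
#' @export
read_growth_csv <- function(path) {
  df <- utils::read.csv(path)
  if (nrow(df) == 0L) stop("growth file ", path, " is empty", call. = FALSE)
  check_columns(df, c("animal_id", "arm", "day", "width_mm", "height_mm",
                      "depth_mm"), "tumor growth", path)
  df$volume_mm3 <- tumor_volume(df$width_mm, df$height_mm, df$depth_mm)
  growth_records(df)
}

#' @rdname read_binding_csv
#' @export
read_apoptosis_csv <- function(path) {
  df <- utils::read.csv(path)
  check_columns(df, c("arm", "field_id", "tunel_positive", "total_cells"),
                "apoptosis field-count", path)
  df
}

provenance_block <- function(config) {
  list(package = "ritdose",
       version = as.character(utils::packageVersion("ritdose")),
       config = unclass(config))
}

#' Tumor-dose JSON report
#'
#' Runs the full dosimetry chain on a biodistribution table (or its CSV)
#' and assembles a deterministic machine-readable report: per-activity
#' doses, the AUC, the chain's assumptions, a literature annotation on
#' red-marrow dose (not computed here), and a provenance block (package
#' version and configuration). No timestamp is included, so repeat runs are
#' byte-identical.
#'
#' @param table A [biodist_table()] or path to a biodistribution CSV.
#' @param activities_MBq Injected activities (MBq).
#' @param therapeutic Therapeutic [nuclide()].
#' @param config A [run_config()].
#' @param path Optional output path; when given the report is written as
#'   JSON.
#' @return The report as a list, invisibly when written to `path`.
#' @export
dose_report <- function(table, activities_MBq,
                        therapeutic = get_nuclide("90Y"),
                        config = run_config(), path = NULL) {
  if (is.character(table)) table <- read_biodist_csv(table)
  dt <- dose_table(table, activities_MBq, therapeutic = therapeutic,
                   anchor_zero_at_origin = config$anchor_zero_at_origin)
  report <- list(
    antibody = attr(dt, "antibody"),
    nuclide = therapeutic$name,
    activities_MBq = as.numeric(activities_MBq),
    auc_pidg_day = attr(dt, "auc_pidg_day"),
    auc_s_per_kg = attr(dt, "auc_s_per_kg"),
    delta_Gy_kg_per_Bq_s = mean_energy_per_transition(therapeutic$mean_beta_energy_MeV),
    dose_Gy = dt$dose_Gy,
    integration_window_day = attr(dt, "window_day"),
    assumptions = attr(dt, "assumptions"),
    annotations = paste("red-marrow dose is not computed here; the study's",
                        "phantom-based literature estimate was 0.5 mGy/MBq",
                        "in a 70-kg reference adult"),
    provenance = provenance_block(config)
  )
  if (!is.null(path)) {
    jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    return(invisible(report))
  }
  report
}

#' Binding-assay fit JSON report
#'
#' @param curve A [cell_binding_curve()] or [competition_curve()].
#' @param config A [run_config()].
#' @param path Optional JSON output path.
#' @return Report list with the fit parameters and provenance.
#' @export
fit_report <- function(curve, config = run_config(), path = NULL) {
  fit <- if (inherits(curve, "cell_binding_curve")) {
    lindmo_fit(curve)
  } else if (inherits(curve, "competition_curve")) {
    homologous_competition_fit(curve)
  } else {
    stop("`curve` must be a cell_binding_curve or competition_curve",
         call. = FALSE)
  }
  report <- c(unclass(fit), list(label = attr(curve, "label"),
                                 provenance = provenance_block(config)))
  if (!is.null(path)) {
    jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    return(invisible(report))
  }
  report
}

#' RIT outcome JSON report
#'
#' Per-arm growth summaries, response classifications, and (when per-arm
#' absorbed doses are supplied) the minimal dose achieving complete
#' regression.
#'
#' @param records A [growth_records()] table.
#' @param arm_doses_Gy Optional named numeric vector of absorbed doses per
#'   arm.
#' @param config A [run_config()].
#' @param path Optional JSON output path.
#' @return Report list.
#' @export
rit_report <- function(records, arm_doses_Gy = NULL, config = run_config(),
                       path = NULL) {
  summ <- arm_summary(records, endpoint_mm3 = config$endpoint_mm3,
                      disappearance_threshold_mm3 = config$disappearance_threshold_mm3,
                      regrowth_factor = config$regrowth_factor,
                      observation_end_day = config$observation_end_day)
  report <- list(per_day = summ$per_day, per_arm = summ$per_arm,
                 provenance = provenance_block(config))
  if (!is.null(arm_doses_Gy)) {
    pa <- summ$per_arm
    doses <- arm_doses_Gy[match(pa$arm, names(arm_doses_Gy))]
    if (any(is.na(doses))) {
      stop("`arm_doses_Gy` lacks doses for arm(s): ",
           paste(pa$arm[is.na(doses)], collapse = ", "), call. = FALSE)
    }
    report$dose_response <- dose_response_threshold(
      doses, pa$complete_regression, pa$n_animals,
      allowed_exceptions = config$allowed_exceptions)
  }
  if (!is.null(path)) {
    jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, dataframe = "rows")
    return(invisible(report))
  }
  report
}

#' Write a synthetic dataset with its truth sidecar
#'
#' Emits the CSV schemas consumed by the readers plus a `truth.json`
#' sidecar echoing the seed, for a named biodistribution scenario together
#' with an RIT cohort at the scenario's dose arms.
#'
#' @param scenario `"12A8"` or `"67A2"`.
#' @param seed RNG seed (echoed into the sidecar).
#' @param outdir Output directory (created if missing).
#' @param activities_MBq Injected activities defining the RIT arms.
#' @return Invisibly, the list of written file paths.
#' @export
simulate_dataset <- function(scenario = c("12A8", "67A2"), seed = 1L,
                             outdir, activities_MBq = c(0.74, 1.85, 3.7)) {
  scenario <- match.arg(scenario)
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  sc <- biodist_scenario(scenario)
  bio <- sim_biodistribution(sc, seed = seed)
  tab <- build_biodist_table(bio$samples, bio$standard_cpm,
                             get_nuclide("111In"), antibody = sc$antibody)
  dt <- dose_table(tab, activities_MBq)
  arms <- data.frame(arm = c("untreated",
                             sprintf("%.2fMBq", activities_MBq)),
                     dose_Gy = c(0, dt$dose_Gy))
  rit <- sim_rit_cohort(arms, seed = seed + 1L, noise_cv = 0.1)
  paths <- c(
    biodist = file.path(outdir, "biodistribution.csv"),
    growth = file.path(outdir, "growth.csv"),
    truth = file.path(outdir, "truth.json")
  )
  write_biodist_csv(tab, paths[["biodist"]])
  utils::write.csv(rit$records, paths[["growth"]], row.names = FALSE)
  jsonlite::write_json(
    list(scenario = scenario, seed = seed,
         biodistribution_truth = bio$truth,
         dose_arms = arms, rit_truth = rit$truth),
    paths[["truth"]], auto_unbox = TRUE, digits = NA, pretty = TRUE,
    dataframe = "rows")
  invisible(paths)
}
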