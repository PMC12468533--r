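# File formats, configuration and analysis reports.
#
# Interchange CSVs are comma-separated UTF-8 with a mandatory header and
# `.` decimal separator; units are fixed by the schema (s, m/s^2, deg/s,
# a.u., BPM, mm) and never auto-converted. Trials are written as
# `*_imu.csv` (t, ax, ay, az, gx, gy, gz), `*_optical.csv`
# (t, intensity) and `*_labels.csv` (t, phase), with the ground truth as
# a JSON sidecar.

.trace_columns <- list(imu = c("t", "ax", "ay", "az", "gx", "gy", "gz"),
                       optical = c("t", "intensity"),
                       labels = c("t", "phase"))

#' Read a trace CSV
#'
#' Validates the header, finiteness and time monotonicity, reporting the
#' offending row numbers.
#'
#' @param path CSV file path.
#' @param kind `"imu"`, `"optical"` or `"labels"`.
#' @return An [imu_trace()], [optical_trace()] or [phase_label_series()].
#' @export
read_trace <- function(path, kind = c("imu", "optical", "labels")) {
  kind <- match.arg(kind)
  gs_assert(file.exists(path), sprintf("file not found: %s", path),
            "gaitsense_file_not_found")
  df <- utils::read.csv(path)
  need <- .trace_columns[[kind]]
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    gs_error(sprintf("missing column(s) in %s: %s", path,
                     paste(missing, collapse = ", ")),
             "gaitsense_missing_columns")
  }
  bad <- which(!stats::complete.cases(df[need]) |
                 !apply(as.matrix(df[need]), 1, function(r) all(is.finite(r))))
  if (length(bad)) {
    gs_error(sprintf("non-finite value(s) in %s at data row(s): %s", path,
                     paste(utils::head(bad, 5), collapse = ", ")),
             "gaitsense_nonfinite_values")
  }
  nonmono <- which(diff(df$t) <= 0)
  if (length(nonmono)) {
    gs_error(sprintf("non-monotone time in %s at data row %d", path,
                     nonmono[1] + 1),
             "gaitsense_nonmonotone_time")
  }
  switch(kind,
         imu = imu_trace(df$t, as.matrix(df[c("ax", "ay", "az")]),
                         as.matrix(df[c("gx", "gy", "gz")])),
         optical = optical_trace(df$t, df$intensity),
         labels = phase_label_series(df$t, df$phase))
}

#' Write a trace to CSV
#'
#' @param trace an [imu_trace()], [optical_trace()] or
#'   [phase_label_series()].
#' @param path destination CSV path.
#' @export
write_trace <- function(trace, path) {
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE)
  invisible(path)
}

#' Write a labeled trial to its CSV/JSON file set
#'
#' @param trial a `labeled_trial`.
#' @param dir destination directory (created if needed).
#' @param prefix file-name prefix.
#' @return The four file paths, invisibly.
#' @export
write_trial <- function(trial, dir, prefix = "trial") {
  gs_assert(inherits(trial, "labeled_trial"), "trial must be a labeled_trial")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, paste0(prefix, c("_imu.csv", "_optical.csv",
                                           "_labels.csv", "_truth.json")))
  write_trace(trial$imu, paths[1])
  write_trace(trial$optical, paths[2])
  write_trace(trial$labels, paths[3])
  jsonlite::write_json(trial$truth, paths[4], auto_unbox = TRUE,
                       digits = 10, dataframe = "columns")
  invisible(paths)
}

.default_config <- function() {
  list(imu_rate = 100, optical_rate = 50,
       window = 0.5, step = 0.1,
       fft_band = c(0.05, 1.0), fft_pad_factor = 8,
       n_estimators = 54, max_features = 6, split = 0.70, cv_folds = 5,
       smooth_kernel = 0.5,
       risk_rule_version = .fall_risk_rule_version,
       seed = 1)
}

#' Build a run configuration
#'
#' All pipeline tunables in one serializable list; unknown keys are
#' rejected so that a typo cannot silently fall back to a default.
#'
#' @param ... overrides of the default fields (sampling rates, window
#'   and step lengths, FFT band and padding, forest hyperparameters,
#'   smoothing kernel, risk-rule version, seed).
#' @return A list of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- .default_config()
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) {
    gs_error(sprintf("unknown config key(s): %s",
                     paste(unknown, collapse = ", ")),
             "gaitsense_unknown_config_key")
  }
  cfg[names(over)] <- over
  structure(cfg, class = "run_config")
}

#' Read a run configuration from YAML
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  gs_assert(file.exists(path), sprintf("file not found: %s", path),
            "gaitsense_file_not_found")
  do.call(run_config, yaml::read_yaml(path))
}

#' Write a run configuration to YAML
#' @param config a `run_config`.
#' @param path destination path.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

.report_schema_version <- "1.0"

#' Assemble an analysis report
#'
#' Bundles pipeline outputs with their provenance (config hash, seed,
#' package version) so every reported number is traceable to a
#' config + seed pair; with the same pair the report reproduces
#' bit-for-bit (floating-point values are serialized at fixed
#' precision, and no wall-clock fields are included).
#'
#' @param config the `run_config` used.
#' @param seed the seed used.
#' @param breathing optional breathing estimates (data frame or list).
#' @param intervals optional `phase_intervals`.
#' @param fall_risk optional `fall_risk`.
#' @param balance optional balance indices data frame.
#' @return A list of class `analysis_report`.
#' @export
analysis_report <- function(config, seed, breathing = NULL, intervals = NULL,
                            fall_risk = NULL, balance = NULL) {
  rep <- list(schema_version = .report_schema_version,
              provenance = list(config_hash = gs_hash(unclass(config)),
                                seed = seed,
                                package_version =
                                  as.character(utils::packageVersion("gaitsense"))),
              config = unclass(config))
  if (!is.null(breathing)) rep$breathing <- breathing
  if (!is.null(intervals)) {
    rep$intervals <- intervals$intervals
    rep$total_time <- intervals$total_time
  }
  if (!is.null(fall_risk)) rep$fall_risk <- unclass(fall_risk)
  if (!is.null(balance)) rep$balance <- balance
  class(rep) <- "analysis_report"
  rep
}

.validate_report <- function(report) {
  need <- c("schema_version", "provenance", "config")
  missing <- setdiff(need, names(report))
  if (length(missing)) {
    gs_error(sprintf("report is missing required field(s): %s",
                     paste(missing, collapse = ", ")),
             "gaitsense_invalid_report")
  }
  invisible(TRUE)
}

#' Write an analysis report as JSON
#'
#' Schema-validated on write; numbers are serialized at fixed precision
#' so identical inputs give byte-identical files.
#'
#' @param report an `analysis_report` (or compatible list).
#' @param path destination JSON path.
#' @export
write_report <- function(report, path) {
  .validate_report(report)
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = 10, dataframe = "columns", pretty = TRUE)
  invisible(path)
}

#' Read an analysis report from JSON
#' @param path JSON file path.
#' @return The report list (schema-validated).
#' @export
read_report <- function(path) {
  gs_assert(file.exists(path), sprintf("file not found: %s", path),
            "gaitsense_file_not_found")
  report <- jsonlite::read_json(path, simplifyVector = TRUE)
  .validate_report(report)
  report
}
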