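# Metrics and desk-scale protocol runners.
#
# The runners reproduce the system's characterization experiments
# end-to-end on synthetic data: the metronome breathing protocol (25
# recordings), the full TUG segmentation pipeline and the balance
# regression protocol. Every runner is fully determined by its
# arguments and seed.

#' RMSE and signed-error summary between estimates and references
#'
#' @param estimates,references numeric vectors of equal length (>= 1),
#'   same units.
#' @return A list of class `rmse_report` with `rmse`, `mean_error`,
#'   `sd_error` (SD of the signed errors; `NA` for a single pair) and
#'   `n`.
#' @export
rmse_report <- function(estimates, references) {
  gs_assert(length(estimates) == length(references),
            "estimates and references must have equal length",
            "gaitsense_length_mismatch")
  gs_assert(length(estimates) >= 1, "need at least one pair")
  err <- as.numeric(estimates) - as.numeric(references)
  structure(list(rmse = sqrt(mean(err^2)),
                 mean_error = mean(err),
                 sd_error = if (length(err) > 1) stats::sd(err) else NA_real_,
                 n = length(err)),
            class = "rmse_report")
}

#' @export
print.rmse_report <- function(x, ...) {
  cat(sprintf("<rmse_report> n = %d, RMSE %.4g, mean error %.4g, SD %.4g\n",
              x$n, x$rmse, x$mean_error, x$sd_error))
  invisible(x)
}

#' Confusion matrix and per-class accuracy
#'
#' Per-class accuracy is the recall (diagonal count over the true-class
#' row sum); classes with no support get `NA`.
#'
#' @param pred,truth aligned class vectors (or [phase_label_series()]
#'   objects) of equal length.
#' @param classes class labels spanning the matrix (default 0..6).
#' @return A list of class `confusion_report` with `matrix` (truth rows,
#'   prediction columns), `per_class_accuracy` and `overall_accuracy`.
#' @export
confusion_report <- function(pred, truth, classes = 0:6) {
  if (inherits(pred, "phase_label_series")) pred <- pred$phase
  if (inherits(truth, "phase_label_series")) truth <- truth$phase
  gs_assert(length(pred) == length(truth),
            "pred and truth must be aligned (equal length)",
            "gaitsense_length_mismatch")
  m <- table(factor(truth, levels = classes), factor(pred, levels = classes))
  m <- unclass(m)
  support <- rowSums(m)
  acc <- ifelse(support > 0, diag(m) / support, NA_real_)
  names(acc) <- classes
  structure(list(matrix = m,
                 per_class_accuracy = acc,
                 overall_accuracy = sum(diag(m)) / sum(m)),
            class = "confusion_report")
}

#' @export
print.confusion_report <- function(x, ...) {
  cat("<confusion_report> (rows = truth, columns = predicted)\n")
  print(x$matrix)
  cat("  per-class accuracy:",
      paste(sprintf("%s", round(x$per_class_accuracy, 3)), collapse = " "), "\n")
  cat(sprintf("  overall accuracy: %.4f\n", x$overall_accuracy))
  invisible(x)
}

#' Random subject profiles for protocol runners
#'
#' Draws per-subject variation around the default profile: multiplicative
#' log-normal jitter on the phase durations (SD 10%), cadence N(2, 0.15)
#' steps/s, breathing rate uniform on 10-20 BPM, wide-base sway
#' amplitudes N(33, 4) and N(6, 1.5) mm, LFS N(1.68, 0.25) — spreads a
#' clinician would call typical across an elderly cohort.
#'
#' @param n number of profiles.
#' @param seed integer seed or `NULL`.
#' @return A list of [subject_profile()]s.
#' @export
random_profiles <- function(n, seed = NULL) {
  gs_seed(seed)
  lapply(seq_len(n), function(i) {
    d <- .default_phase_durations * exp(stats::rnorm(7, 0, 0.1))
    subject_profile(
      walk_cadence = max(0.8, stats::rnorm(1, 2, 0.15)),
      phase_durations = d,
      sway_amp_anterior = max(5, stats::rnorm(1, 33, 4)),
      sway_amp_medial = max(1, stats::rnorm(1, 6, 1.5)),
      lfs_true = max(0.5, stats::rnorm(1, 1.68, 0.25)),
      breathing_bpm = stats::runif(1, 10, 20))
  })
}

#' Metronome characterization of the breathing estimator
#'
#' Simulates the 25-recording metronome protocol (five repeats at each
#' of 10, 13, 15, 17 and 20 BPM), estimates each breathing rate by FFT
#' peak detection and summarizes the error against the reference rates.
#'
#' @param seed integer seed.
#' @param ... passed to [simulate_metronome_protocol()].
#' @return A list of class `metronome_characterization` with
#'   `estimates` (data frame `bpm_ref`, `bpm_est`), `per_frequency`
#'   (mean estimate per reference rate) and `rmse_report`.
#' @export
run_metronome_characterization <- function(seed = 1, ...) {
  traces <- simulate_metronome_protocol(seed = seed, ...)
  est <- data.frame(
    bpm_ref = vapply(traces, function(tr) attr(tr, "bpm_true"), numeric(1)),
    bpm_est = vapply(traces, function(tr) estimate_breathing_rate(tr)$bpm,
                     numeric(1)))
  per_freq <- aggregate(bpm_est ~ bpm_ref, est, mean)
  structure(list(estimates = est,
                 per_frequency = per_freq,
                 rmse_report = rmse_report(est$bpm_est, est$bpm_ref)),
            class = "metronome_characterization")
}

#' @export
print.metronome_characterization <- function(x, ...) {
  cat("<metronome_characterization>\n  mean estimate per reference rate:\n")
  print(x$per_frequency, row.names = FALSE)
  cat(sprintf("  RMSE: %.3f BPM over %d recordings\n",
              x$rmse_report$rmse, x$rmse_report$n))
  invisible(x)
}

#' End-to-end TUG segmentation protocol
#'
#' Simulates labeled TUG trials across randomly varying subjects,
#' extracts windowed features (with the timestamp input, matching the
#' study's classifier input set), trains the Random Forest phase
#' classifier and reports held-out per-class accuracy plus per-trial
#' interval recovery (predicted vs. true phase durations and total
#' times after label smoothing).
#'
#' @param seed integer seed.
#' @param n_trials number of simulated trials, at least 10 (default 40).
#' @param config a [classifier_config()]; its seed defaults to `seed`.
#' @param window,step feature-window parameters in seconds.
#' @param smooth_kernel majority-filter width in seconds applied before
#'   interval extraction.
#' @param include_timestamp use the window-center time as a feature.
#' @return A list of class `tug_protocol_result` with `model`,
#'   `confusion` (held-out), `min_class_accuracy`, `interval_table`
#'   (per trial: true/estimated total time and absolute error) and
#'   `duration_rmse` (per-phase duration RMSE across trials, seconds).
#' @export
run_tug_acceptance <- function(seed = 1, n_trials = 40,
                               config = classifier_config(seed = seed),
                               window = 0.5, step = 0.1,
                               smooth_kernel = 0.5,
                               include_timestamp = TRUE) {
  gs_assert(n_trials >= 10, "n_trials must be at least 10")
  profiles <- random_profiles(n_trials, seed = seed)
  trials <- lapply(profiles, simulate_tug_trial)

  feats <- lapply(trials, function(tr)
    window_features(tr$imu, window, step, include_timestamp))
  labs <- unlist(lapply(seq_along(trials), function(i)
    labels_at(trials[[i]]$labels, feats[[i]]$t_center)))
  all_feats <- do.call(rbind, feats)

  model <- train_phase_classifier(all_feats, labs, config)

  rows <- lapply(seq_along(trials), function(i) {
    pred <- predict_phases(model, feats[[i]])
    pred <- smooth_labels(pred, smooth_kernel)
    pred <- resample_labels(pred, trials[[i]]$imu$t)
    iv <- suppressWarnings(extract_phase_intervals(pred))
    true_d <- trials[[i]]$truth$phase_durations[2:7]
    data.frame(trial = i,
               true_total = trials[[i]]$truth$total_time,
               est_total = iv$total_time,
               abs_err = abs(iv$total_time - trials[[i]]$truth$total_time),
               duration_rmse = sqrt(mean((iv$intervals$duration - true_d)^2)))
  })
  interval_table <- do.call(rbind, rows)

  structure(list(model = model,
                 confusion = model$confusion,
                 min_class_accuracy = min(model$confusion$per_class_accuracy),
                 interval_table = interval_table,
                 duration_rmse = mean(interval_table$duration_rmse),
                 n_trials = n_trials),
            class = "tug_protocol_result")
}

#' @export
print.tug_protocol_result <- function(x, ...) {
  cat(sprintf("<tug_protocol_result> %d trials\n", x$n_trials))
  cat(sprintf("  min held-out per-class accuracy: %.4f\n",
              x$min_class_accuracy))
  cat(sprintf("  median |total time error|: %.3f s\n",
              stats::median(x$interval_table$abs_err)))
  invisible(x)
}

#' End-to-end balance regression protocol
#'
#' Simulates quiet-stance trials (half wide, half narrow base) across
#' randomly varying subjects, builds per-trial aggregated features,
#' trains the multi-output balance regressor and reports held-out RMSE
#' per index together with the wide/narrow condition comparison of the
#' ground-truth indices.
#'
#' @param seed integer seed.
#' @param n_trials total number of trials (default 200).
#' @param config a [classifier_config()]; its seed defaults to `seed`.
#' @param duration trial length in seconds.
#' @return A list of class `balance_protocol_result` with `model`,
#'   `rmse` (named per-index held-out RMSE), `comparison` (see
#'   [compare_conditions()]) and `n_test`.
#' @export
run_balance_acceptance <- function(seed = 1, n_trials = 200,
                                   config = classifier_config(seed = seed),
                                   duration = 30) {
  gs_assert(n_trials >= 50, "n_trials must be at least 50")
  profiles <- random_profiles(n_trials, seed = seed)
  stances <- rep(c("wide", "narrow"), length.out = n_trials)
  trials <- lapply(seq_len(n_trials), function(i)
    simulate_balance_trial(profiles[[i]], stances[i], duration = duration))

  fm <- balance_feature_matrix(trials)
  model <- train_balance_regressor(fm$features, fm$truth, config)
  rmse <- vapply(model$rmse_report, function(r) r$rmse, numeric(1))

  comparison <- compare_conditions(
    fm$truth[fm$truth$stance == "wide", ],
    fm$truth[fm$truth$stance == "narrow", ])

  structure(list(model = model, rmse = rmse, comparison = comparison,
                 n_trials = n_trials, n_test = model$n_test),
            class = "balance_protocol_result")
}

#' @export
print.balance_protocol_result <- function(x, ...) {
  cat(sprintf("<balance_protocol_result> %d trials (%d held out)\n",
              x$n_trials, x$n_test))
  cat(sprintf("  held-out RMSE: anterior %.2f mm, medial %.2f mm, LFS %.3f\n",
              x$rmse["anterior_mm"], x$rmse["medial_mm"], x$rmse["lfs"]))
  invisible(x)
}
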