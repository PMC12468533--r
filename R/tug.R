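# TUG phase segmentation, interval extraction and fall-risk scoring.
#
# Phases are coded 0..6 (start/idle, sit-to-stand, forward walk, first
# turn, return walk, second turn, stand-to-sit). A Random Forest
# assigns one class per feature window; each phase's time interval is
# the difference between its first and last classification, and the
# total test time is the sum of the six phase intervals, which feeds
# the conventional fall-risk rule.

#' Random Forest configuration
#'
#' Defaults mirror the study configuration: 54 trees, 6 candidate
#' features per split, a stratified 70/30 train/test division and
#' 5-fold cross-validation.
#'
#' @param n_estimators number of trees.
#' @param max_features candidate features per split (`mtry`).
#' @param split training fraction, in (0, 1).
#' @param cv_folds cross-validation folds, at least 2.
#' @param seed integer seed for the split, the folds and the forest.
#' @return A list of class `classifier_config`.
#' @export
classifier_config <- function(n_estimators = 54, max_features = 6,
                              split = 0.70, cv_folds = 5, seed = 1) {
  gs_assert(n_estimators >= 1, "n_estimators must be >= 1")
  gs_assert(max_features >= 1, "max_features must be >= 1")
  gs_assert(split > 0 && split < 1, "split must lie in (0, 1)")
  gs_assert(cv_folds >= 2, "cv_folds must be >= 2")
  structure(list(n_estimators = as.integer(n_estimators),
                 max_features = as.integer(max_features),
                 split = split, cv_folds = as.integer(cv_folds),
                 seed = as.integer(seed)),
            class = "classifier_config")
}

#' Phase labels at given times
#'
#' Looks up the piecewise-constant label series at arbitrary times
#' (e.g. window centers), taking the label of the latest sample at or
#' before each query time.
#'
#' @param labels a [phase_label_series()].
#' @param t query times in seconds.
#' @return Integer phase classes.
#' @export
labels_at <- function(labels, t) {
  idx <- findInterval(t + 1e-9, labels$t)
  idx[idx < 1] <- 1
  labels$phase[idx]
}

.feature_matrix <- function(features) {
  cols <- setdiff(names(features), "t_center")
  as.matrix(features[, cols, drop = FALSE])
}

#' Train the Random Forest TUG phase classifier
#'
#' Splits the labeled windows into a stratified train/test division,
#' fits a Random Forest with the configured hyperparameters, reports
#' k-fold cross-validated per-class accuracy on the training portion
#' and the held-out confusion matrix. All randomness is governed by
#' `config$seed`.
#'
#' @param features data frame from [window_features()] (column
#'   `t_center` plus feature columns).
#' @param labels integer phase class per window (length `nrow(features)`),
#'   or a [phase_label_series()] to be sampled at the window centers.
#' @param config a [classifier_config()].
#'
#' @return A list of class `tug_classifier` with the fitted `forest`,
#'   `config`, `feature_names`, `cv_accuracy` (per-class, cross-
#'   validated), `confusion` (held-out [confusion_report()]) and
#'   `holdout_accuracy`.
#' @export
train_phase_classifier <- function(features, labels,
                                   config = classifier_config()) {
  if (inherits(labels, "phase_label_series")) {
    labels <- labels_at(labels, features$t_center)
  }
  gs_assert(length(labels) == nrow(features),
            "labels must align with the feature windows")
  gs_assert(nrow(features) >= 100, "need at least 100 labeled windows")
  present <- sort(unique(labels))
  if (!all(0:6 %in% present)) {
    gs_error(sprintf("all 7 phase classes must be present; missing: %s",
                     paste(setdiff(0:6, present), collapse = ", ")),
             "gaitsense_missing_class")
  }
  X <- .feature_matrix(features)
  y <- factor(labels, levels = 0:6)

  set.seed(config$seed)
  # stratified split: every class contributes `split` of its windows
  train_idx <- unlist(lapply(levels(y), function(cl) {
    i <- which(y == cl)
    sample(i, max(1, round(config$split * length(i))))
  }))
  train_idx <- sort(train_idx)
  test_idx <- setdiff(seq_len(nrow(X)), train_idx)
  gs_assert(length(unique(y[train_idx])) == 7 &&
              length(unique(y[test_idx])) == 7,
            "both partitions must contain all 7 classes",
            "gaitsense_missing_class")

  mtry <- min(config$max_features, ncol(X))
  forest <- randomForest::randomForest(
    x = X[train_idx, , drop = FALSE], y = y[train_idx],
    ntree = config$n_estimators, mtry = mtry)

  # k-fold CV on the training portion, stratified by class
  folds <- integer(length(train_idx))
  for (cl in levels(y)) {
    i <- which(y[train_idx] == cl)
    folds[i] <- sample(rep_len(seq_len(config$cv_folds), length(i)))
  }
  cv_conf <- matrix(0, 7, 7, dimnames = list(0:6, 0:6))
  for (f in seq_len(config$cv_folds)) {
    tr <- train_idx[folds != f]
    va <- train_idx[folds == f]
    if (length(unique(y[tr])) < 7 || !length(va)) next
    m <- randomForest::randomForest(x = X[tr, , drop = FALSE], y = y[tr],
                                    ntree = config$n_estimators, mtry = mtry)
    pr <- predict(m, X[va, , drop = FALSE])
    cv_conf <- cv_conf + table(factor(y[va], levels = 0:6),
                               factor(pr, levels = 0:6))
  }
  cv_accuracy <- diag(cv_conf) / pmax(1, rowSums(cv_conf))

  pred_test <- predict(forest, X[test_idx, , drop = FALSE])
  confusion <- confusion_report(as.integer(as.character(pred_test)),
                                as.integer(as.character(y[test_idx])))

  structure(list(forest = forest, config = config,
                 feature_names = colnames(X),
                 cv_accuracy = cv_accuracy,
                 confusion = confusion,
                 holdout_accuracy = confusion$overall_accuracy),
            class = "tug_classifier")
}

#' Predict TUG phases for feature windows
#'
#' @param model a `tug_classifier`.
#' @param features data frame with the same feature schema used in
#'   training; an empty frame yields an empty series.
#' @return A [phase_label_series()] on the window-center time grid.
#' @export
predict_phases <- function(model, features) {
  gs_assert(inherits(model, "tug_classifier"), "model must be a tug_classifier")
  if (nrow(features) == 0) {
    return(phase_label_series(numeric(0), integer(0)))
  }
  X <- .feature_matrix(features)
  if (!identical(colnames(X), model$feature_names)) {
    gs_error("feature schema does not match the trained model",
             "gaitsense_schema_mismatch")
  }
  pr <- predict(model$forest, X)
  phase_label_series(features$t_center, as.integer(as.character(pr)))
}

#' @export
predict.tug_classifier <- function(object, newdata, ...) {
  predict_phases(object, newdata)
}

#' @export
print.tug_classifier <- function(x, ...) {
  cat(sprintf("<tug_classifier> Random Forest, %d trees, mtry %d\n",
              x$config$n_estimators, x$config$max_features))
  cat(sprintf("  held-out overall accuracy: %.3f (min per-class %.3f)\n",
              x$holdout_accuracy, min(x$confusion$per_class_accuracy)))
  invisible(x)
}

#' @export
summary.tug_classifier <- function(object, ...) {
  cat("Random Forest TUG phase classifier\n")
  cat(sprintf("  trees: %d, mtry: %d, split: %.0f/%.0f, CV folds: %d\n",
              object$config$n_estimators, object$config$max_features,
              100 * object$config$split, 100 * (1 - object$config$split),
              object$config$cv_folds))
  cat("  cross-validated per-class accuracy:\n")
  print(round(object$cv_accuracy, 4))
  cat("  held-out per-class accuracy:\n")
  print(round(object$confusion$per_class_accuracy, 4))
  invisible(object)
}

#' Majority-filter a phase label series
#'
#' Sliding-mode filter guarding the first/last-detection rule against
#' isolated misclassifications: one stray label far from its phase would
#' otherwise corrupt the interval. Ties keep the current label when it
#' is among the modes, otherwise the smallest tied class.
#'
#' @param series a [phase_label_series()].
#' @param kernel filter width in seconds; 0 is the identity.
#' @return A filtered [phase_label_series()] of equal length.
#' @export
smooth_labels <- function(series, kernel = 0.5) {
  gs_assert(inherits(series, "phase_label_series"),
            "series must be a phase_label_series")
  gs_assert(kernel >= 0, "kernel must be >= 0")
  n <- nrow(series)
  if (kernel == 0 || n < 3) return(series)
  dt <- stats::median(diff(series$t))
  half <- floor(kernel / dt / 2)
  if (half < 1) return(series)
  out <- series$phase
  for (i in seq_len(n)) {
    lo <- max(1, i - half); hi <- min(n, i + half)
    tab <- tabulate(series$phase[lo:hi] + 1L, nbins = 7)
    modes <- which(tab == max(tab)) - 1L
    out[i] <- if (series$phase[i] %in% modes) series$phase[i] else min(modes)
  }
  phase_label_series(series$t, out)
}

#' Resample a label series onto a new time grid
#'
#' Window-level classifications live on the window-center grid, but the
#' first/last-detection rule is defined on the time stamps of the
#' sensors. This maps each sensor-grid time to the label of its nearest
#' window center (the piecewise-constant decoding of the window
#' sequence), so phase boundaries land halfway between adjacent window
#' centers instead of being truncated to the centers themselves —
#' removing the half-window bias at the trial ends and the half-step
#' bias at every phase boundary.
#'
#' @param series a [phase_label_series()] (e.g. from [predict_phases()]).
#' @param t target time grid in seconds (e.g. the IMU sample times).
#' @return A [phase_label_series()] on the target grid.
#' @export
resample_labels <- function(series, t) {
  gs_assert(inherits(series, "phase_label_series"),
            "series must be a phase_label_series")
  gs_assert(nrow(series) > 0, "series must be non-empty")
  # nearest-center lookup: boundaries at midpoints between centers
  mids <- series$t[-nrow(series)] + diff(series$t) / 2
  idx <- findInterval(t, mids) + 1
  phase_label_series(t, series$phase[idx])
}

#' Extract per-phase intervals from a label series
#'
#' For each class 1..6 the interval is the time difference between its
#' first and last classification (e.g. first detected at 0.2 s and last
#' at 1.2 s gives a 1 s interval); the total test time is the sum of
#' the six intervals. A class never detected yields a zero duration and
#' an `absent` flag (with a warning), not an error.
#'
#' @param series a [phase_label_series()].
#' @param accel_mag optional data frame `t, mag` from
#'   [accel_magnitude()]; when given, the maximum acceleration magnitude
#'   within each interval is reported.
#' @return A list of class `phase_intervals` with `intervals` (data
#'   frame: class, first_detect, last_detect, duration, max_accel,
#'   absent) and `total_time`.
#' @export
extract_phase_intervals <- function(series, accel_mag = NULL) {
  gs_assert(inherits(series, "phase_label_series"),
            "series must be a phase_label_series")
  gs_assert(nrow(series) > 0, "series must be non-empty")
  rows <- lapply(1:6, function(cl) {
    i <- which(series$phase == cl)
    if (!length(i)) {
      data.frame(class = cl, first_detect = NA_real_, last_detect = NA_real_,
                 duration = 0, max_accel = NA_real_, absent = TRUE)
    } else {
      first <- series$t[min(i)]; last <- series$t[max(i)]
      ma <- NA_real_
      if (!is.null(accel_mag)) {
        keep <- accel_mag$t >= first - 1e-9 & accel_mag$t <= last + 1e-9
        if (any(keep)) ma <- max(accel_mag$mag[keep])
      }
      data.frame(class = cl, first_detect = first, last_detect = last,
                 duration = last - first, max_accel = ma, absent = FALSE)
    }
  })
  intervals <- do.call(rbind, rows)
  if (any(intervals$absent)) {
    warning(sprintf("phase class(es) never detected: %s",
                    paste(intervals$class[intervals$absent], collapse = ", ")),
            call. = FALSE)
  }
  structure(list(intervals = intervals,
                 total_time = sum(intervals$duration)),
            class = "phase_intervals")
}

#' @export
print.phase_intervals <- function(x, ...) {
  cat("<phase_intervals>\n")
  print(x$intervals, row.names = FALSE)
  cat(sprintf("  total time: %.4g s\n", x$total_time))
  invisible(x)
}

.fall_risk_rule_version <- "conventional-tug-v1"
.fall_risk_rule_text <- paste(
  "low: total time < 10 s; moderate: 10 s <= total time < 20 s;",
  "high: total time >= 20 s (the conventional rule's unassigned",
  "[19, 20) s band resolves to moderate)")

#' Conventional TUG fall-risk category
#'
#' The conventional rule: below 10 s low risk, 10-19 s moderate, above
#' 20 s high. As printed the rule leaves [19, 20) s unassigned; in line
#' with the 20 s cutoff used across the TUG literature, moderate covers
#' [10, 20) and high [20, Inf). The applied rule text is versioned into
#' every result.
#'
#' @param total_time total TUG time in seconds, positive.
#' @return A list of class `fall_risk` with `category` (`"low"`,
#'   `"moderate"`, `"high"`), `total_time`, `rule_version`, `rule_text`.
#' @export
classify_fall_risk <- function(total_time) {
  gs_assert(length(total_time) == 1 && is.finite(total_time) &&
              total_time > 0,
            "total_time must be a single positive number",
            "gaitsense_invalid_time")
  category <- if (total_time < 10) "low"
              else if (total_time < 20) "moderate"
              else "high"
  structure(list(category = category, total_time = total_time,
                 rule_version = .fall_risk_rule_version,
                 rule_text = .fall_risk_rule_text),
            class = "fall_risk")
}

#' @export
print.fall_risk <- function(x, ...) {
  cat(sprintf("<fall_risk> %s (total time %.4g s, rule %s)\n",
              x$category, x$total_time, x$rule_version))
  invisible(x)
}

#' Compare TUG protocols
#'
#' Pairwise percent differences of total times (and, when full interval
#' objects are supplied, per-phase durations) between protocols, e.g.
#' conventional vs. dual-task TUG.
#'
#' @param results named list mapping protocol name to a
#'   `phase_intervals` object or a single total time in seconds.
#' @param digits rounding for the reported percent differences (default
#'   0, i.e. nearest integer percent).
#' @return A list of class `protocol_comparison` with `totals` and a
#'   data frame `pairs` (`a`, `b`, `percent_diff` = 100*(a-b)/b).
#' @export
compare_protocols <- function(results, digits = 0) {
  gs_assert(is.list(results) && length(results) >= 2 &&
              !is.null(names(results)) && all(nzchar(names(results))),
            "results must be a named list of at least 2 protocols",
            "gaitsense_missing_protocol")
  totals <- vapply(results, function(r) {
    if (inherits(r, "phase_intervals")) r$total_time else as.numeric(r)
  }, numeric(1))
  gs_assert(all(is.finite(totals)) && all(totals > 0),
            "protocol total times must be positive",
            "gaitsense_missing_protocol")
  nm <- names(totals)
  pairs <- expand.grid(a = nm, b = nm, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$a != pairs$b, ]
  pairs$percent_diff <- round(
    100 * (totals[pairs$a] - totals[pairs$b]) / totals[pairs$b], digits)
  rownames(pairs) <- NULL
  structure(list(totals = totals, pairs = pairs, digits = digits),
            class = "protocol_comparison")
}

#' @export
print.protocol_comparison <- function(x, ...) {
  cat("<protocol_comparison>\n  totals (s):\n")
  print(round(x$totals, 3))
  cat("  pairwise percent differences (a vs b):\n")
  print(x$pairs, row.names = FALSE)
  invisible(x)
}
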