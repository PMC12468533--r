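# Balance-index regression and condition comparison.
#
# Quiet-stance trials yield three per-trial scalars — anterior and
# medial displacement (mm) and local fractal stability (LFS, a
# dimensionless postural-control index with no closed-form definition
# here; it is learned from data, never computed from a formula). Inputs
# are time series, so each trial is summarized by aggregating the
# windowed IMU features (mean and SD of every window feature across the
# trial) before regression.

#' Aggregate window features into one per-trial feature vector
#'
#' @param features data frame from [window_features()].
#' @return A named numeric vector: for every window feature, its mean
#'   (`*_m`) and SD (`*_s`) across the trial's windows.
#' @export
aggregate_trial_features <- function(features) {
  cols <- setdiff(names(features), c("t_center", "t_stamp"))
  m <- vapply(features[cols], mean, numeric(1))
  s <- vapply(features[cols], stats::sd, numeric(1))
  out <- c(m, s)
  names(out) <- c(paste0(cols, "_m"), paste0(cols, "_s"))
  out
}

#' Per-trial feature matrix for a list of balance trials
#'
#' @param trials list of `labeled_trial` objects (kind `"balance"`).
#' @param window,step window parameters passed to [window_features()].
#' @return A list with `features` (trial x feature matrix) and `truth`
#'   (data frame `anterior_mm`, `medial_mm`, `lfs`, `stance`).
#' @export
balance_feature_matrix <- function(trials, window = 0.5, step = 0.1) {
  gs_assert(length(trials) >= 1, "need at least one trial")
  rows <- lapply(trials, function(tr) {
    aggregate_trial_features(window_features(tr$imu, window, step))
  })
  truth <- do.call(rbind, lapply(trials, function(tr) {
    data.frame(anterior_mm = tr$truth$anterior_mm,
               medial_mm = tr$truth$medial_mm,
               lfs = tr$truth$lfs,
               stance = tr$truth$stance)
  }))
  list(features = do.call(rbind, rows), truth = truth)
}

.balance_targets <- c("anterior_mm", "medial_mm", "lfs")

#' Train the multi-output balance regressor
#'
#' Fits one Random Forest regressor per balance index (anterior
#' displacement, medial displacement, LFS) behind a single model
#' object, on a seeded 70/30 trial split, and reports the held-out RMSE
#' per index.
#'
#' @param features trial-by-feature matrix (e.g. from
#'   [balance_feature_matrix()]).
#' @param truth data frame with columns `anterior_mm`, `medial_mm`,
#'   `lfs`; one row per trial.
#' @param config a [classifier_config()] (trees, mtry, split, seed).
#'
#' @return A list of class `balance_regressor` with `forests` (one per
#'   index), `config`, `feature_names` and `rmse_report` (held-out, per
#'   index).
#' @export
train_balance_regressor <- function(features, truth,
                                    config = classifier_config()) {
  features <- as.matrix(features)
  gs_assert(nrow(features) == nrow(truth),
            "features and truth must have one row per trial")
  gs_assert(nrow(features) >= 50, "need at least 50 trials with truth")
  gs_assert(all(.balance_targets %in% names(truth)),
            "truth must have columns anterior_mm, medial_mm, lfs")
  gs_assert(nrow(features) >= config$cv_folds,
            "fewer trials than folds")

  set.seed(config$seed)
  n <- nrow(features)
  train_idx <- sort(sample(n, round(config$split * n)))
  test_idx <- setdiff(seq_len(n), train_idx)
  mtry <- min(config$max_features, ncol(features))

  forests <- lapply(.balance_targets, function(target) {
    randomForest::randomForest(x = features[train_idx, , drop = FALSE],
                               y = truth[[target]][train_idx],
                               ntree = config$n_estimators, mtry = mtry)
  })
  names(forests) <- .balance_targets

  rmse <- lapply(.balance_targets, function(target) {
    pred <- predict(forests[[target]], features[test_idx, , drop = FALSE])
    rmse_report(pred, truth[[target]][test_idx])
  })
  names(rmse) <- .balance_targets

  structure(list(forests = forests, config = config,
                 feature_names = colnames(features),
                 rmse_report = rmse,
                 n_train = length(train_idx), n_test = length(test_idx)),
            class = "balance_regressor")
}

#' Predict balance indices for trials
#'
#' @param model a `balance_regressor`.
#' @param features trial-by-feature matrix with the training schema; an
#'   empty matrix yields an empty result.
#' @return A data frame with one row per trial: `anterior_mm`,
#'   `medial_mm`, `lfs`.
#' @export
predict_balance_indices <- function(model, features) {
  gs_assert(inherits(model, "balance_regressor"),
            "model must be a balance_regressor")
  features <- as.matrix(features)
  if (nrow(features) == 0) {
    return(data.frame(anterior_mm = numeric(0), medial_mm = numeric(0),
                      lfs = numeric(0)))
  }
  if (!identical(colnames(features), model$feature_names)) {
    gs_error("feature schema does not match the trained model",
             "gaitsense_schema_mismatch")
  }
  out <- lapply(model$forests, function(f) as.numeric(predict(f, features)))
  data.frame(anterior_mm = out$anterior_mm, medial_mm = out$medial_mm,
             lfs = out$lfs)
}

#' @export
predict.balance_regressor <- function(object, newdata, ...) {
  predict_balance_indices(object, newdata)
}

#' @export
print.balance_regressor <- function(x, ...) {
  cat(sprintf("<balance_regressor> 3 Random Forests, %d trees each (train %d / test %d trials)\n",
              x$config$n_estimators, x$n_train, x$n_test))
  for (target in names(x$rmse_report)) {
    cat(sprintf("  held-out RMSE %s: %.3f\n", target,
                x$rmse_report[[target]]$rmse))
  }
  invisible(x)
}

#' Compare wide- vs narrow-base balance conditions
#'
#' Computes the condition means of each balance index and their percent
#' changes, reported to one decimal place. The signed change is
#' 100*(narrow - wide)/wide; a negative change is a reduction (its
#' magnitude is also reported as `percent_reduction`, i.e.
#' 100*(wide - narrow)/wide).
#'
#' @param wide,narrow data frames of balance indices (`anterior_mm`,
#'   `medial_mm`, `lfs`), one row per trial; both non-empty.
#' @return A list of class `balance_comparison` with `means` and a data
#'   frame `change` (`index`, `percent_change`, `direction`,
#'   `percent_reduction`).
#' @export
compare_conditions <- function(wide, narrow) {
  gs_assert(is.data.frame(wide) && nrow(wide) > 0 &&
              is.data.frame(narrow) && nrow(narrow) > 0,
            "both conditions must be non-empty", "gaitsense_empty_condition")
  gs_assert(all(.balance_targets %in% names(wide)) &&
              all(.balance_targets %in% names(narrow)),
            "conditions must have columns anterior_mm, medial_mm, lfs")
  mw <- vapply(wide[.balance_targets], mean, numeric(1))
  mn <- vapply(narrow[.balance_targets], mean, numeric(1))
  change <- round(100 * (mn - mw) / mw, 1)
  reduction <- round(100 * (mw - mn) / mw, 1)
  tab <- data.frame(index = .balance_targets,
                    wide_mean = mw, narrow_mean = mn,
                    percent_change = change,
                    direction = ifelse(change > 0, "increase",
                                       ifelse(change < 0, "reduction",
                                              "unchanged")),
                    percent_reduction = reduction)
  rownames(tab) <- NULL
  structure(list(means = rbind(wide = mw, narrow = mn), change = tab),
            class = "balance_comparison")
}

#' @export
print.balance_comparison <- function(x, ...) {
  cat("<balance_comparison> condition means and changes (narrow vs wide)\n")
  cat(sprintf("  %-14s %10s %12s %10s\n",
              "index", "wide mean", "narrow mean", "change"))
  for (i in seq_len(nrow(x$change))) {
    r <- x$change[i, ]
    cat(sprintf("  %-14s %10.2f %12.2f %9.1f%% %s\n",
                r$index, r$wide_mean, r$narrow_mean,
                abs(r$percent_change), r$direction))
  }
  invisible(x)
}
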