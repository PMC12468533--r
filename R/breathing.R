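# Breathing-rate estimation and regime analysis.
#
# The chest belt converts chest-wall curvature to transmitted optical
# intensity; the breathing rate is the dominant frequency of that
# signal. Estimation is plain spectral peak picking with sub-bin
# refinement: a 60 s record has a raw FFT bin width of 1/60 Hz = 1 BPM,
# too coarse for sub-BPM accuracy, so the trace is Hann-tapered,
# zero-padded (>= 8x by default) and the peak refined by parabolic
# interpolation over the peak bin and its neighbors.

#' Estimate breathing rate from an optical-intensity trace
#'
#' Removes the mean and linear drift, applies a Hann taper, zero-pads,
#' locates the maximum-magnitude FFT bin inside the search band and
#' refines the peak frequency by parabolic interpolation. The breathing
#' rate is 60 times the peak frequency.
#'
#' @param trace an [optical_trace()] of at least 20 s.
#' @param band search band `c(f_lo, f_hi)` in Hz; the default 0.05-1 Hz
#'   (3-60 BPM) excludes residual drift and cardiac/motion harmonics.
#' @param pad_factor minimum zero-padding factor for the FFT (default 8).
#' @param min_peak_frac a peak is accepted only if its bin power is at
#'   least this fraction of the total in-band power; below it the trace
#'   has no dominant respiratory component.
#'
#' @return A list of class `breathing_estimate` with `bpm`, `peak_freq`
#'   (Hz), `peak_power`, `regime` (see [classify_regime()]) and `window`
#'   (the trace time span).
#' @export
estimate_breathing_rate <- function(trace, band = c(0.05, 1.0),
                                    pad_factor = 8, min_peak_frac = 0.05) {
  gs_assert(inherits(trace, "optical_trace"), "trace must be an optical_trace")
  rate <- attr(trace, "rate")
  n <- nrow(trace)
  dur <- n / rate  # record length: n samples each covering 1/rate s
  if (dur < 20 - 1e-9) {
    gs_error(sprintf("trace duration %.3g s is below the 20 s minimum", dur),
             "gaitsense_trace_too_short")
  }
  gs_assert(length(band) == 2 && band[1] > 0 && band[1] < band[2] &&
              band[2] <= rate / 2 + 1e-9,
            "band must satisfy 0 < f_lo < f_hi <= Nyquist")

  x <- trace$intensity
  # detrend: remove mean and linear drift
  fit <- stats::lm.fit(cbind(1, trace$t), x)
  x <- fit$residuals
  scale <- sqrt(mean(x^2))
  if (scale < 1e-12 * (1 + mean(abs(trace$intensity)))) {
    gs_error("trace has no dominant in-band spectral peak (flat signal)",
             "gaitsense_no_peak")
  }
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))  # Hann
  xw <- x * w
  nfft <- 2^ceiling(log2(n * pad_factor))
  spec <- stats::fft(c(xw, rep(0, nfft - n)))
  nb <- nfft %/% 2 + 1
  mag <- Mod(spec[seq_len(nb)])
  freqs <- (seq_len(nb) - 1) * rate / nfft

  in_band <- which(freqs >= band[1] & freqs <= band[2])
  p <- mag[in_band]^2
  total <- sum(p)
  if (total <= 0) {
    gs_error("trace has no dominant in-band spectral peak",
             "gaitsense_no_peak")
  }
  k_rel <- which.max(p)
  if (p[k_rel] < min_peak_frac * total) {
    gs_error("trace has no dominant in-band spectral peak",
             "gaitsense_no_peak")
  }
  k <- in_band[k_rel]
  # parabolic interpolation over the peak and its neighbors
  delta <- 0
  if (k > 1 && k < nb) {
    a <- mag[k - 1]; b <- mag[k]; cc <- mag[k + 1]
    den <- a - 2 * b + cc
    if (den < 0) delta <- 0.5 * (a - cc) / den
    delta <- max(-0.5, min(0.5, delta))
  }
  f_peak <- (k - 1 + delta) * rate / nfft
  bpm <- 60 * f_peak
  structure(list(bpm = bpm, peak_freq = f_peak, peak_power = mag[k]^2,
                 regime = classify_regime(bpm),
                 window = c(trace$t[1], trace$t[n]), band = band),
            class = "breathing_estimate")
}

#' @export
print.breathing_estimate <- function(x, ...) {
  cat(sprintf("<breathing_estimate> %.2f BPM (peak %.4f Hz, %s), window [%.6g, %.6g] s\n",
              x$bpm, x$peak_freq, x$regime, x$window[1], x$window[2]))
  invisible(x)
}

#' Sliding-window breathing-rate series
#'
#' Repeats [estimate_breathing_rate()] over sliding windows, giving the
#' breathing-rate variation throughout a test. Windows without a
#' dominant peak are flagged (`no_peak = TRUE`, `bpm = NA`), never
#' dropped silently.
#'
#' @param trace an [optical_trace()].
#' @param window window length in seconds, at least 20.
#' @param step hop between windows in seconds, positive.
#' @param ... passed to [estimate_breathing_rate()].
#'
#' @return A data frame with one row per window: `t_start`, `t_end`,
#'   `t_center`, `bpm`, `peak_freq`, `regime`, `no_peak`.
#' @export
sliding_breathing_series <- function(trace, window = 40, step = 20, ...) {
  gs_assert(inherits(trace, "optical_trace"), "trace must be an optical_trace")
  gs_assert(window >= 20, "window must be at least 20 s",
            "gaitsense_trace_too_short")
  gs_assert(step > 0, "step must be positive")
  rate <- attr(trace, "rate")
  dur <- nrow(trace) / rate
  gs_assert(window <= dur + 1e-9, "window exceeds trace duration")
  t0 <- trace$t[1]
  n_win <- floor((dur - window) / step + 1e-9) + 1
  rows <- vector("list", n_win)
  for (i in seq_len(n_win)) {
    ts <- t0 + (i - 1) * step
    te <- ts + window
    # half-open window: exactly window*rate samples
    sub <- trace[trace$t >= ts - 1e-9 & trace$t < te - 1e-9, , drop = FALSE]
    sub <- optical_trace(sub$t, sub$intensity, rate = attr(trace, "rate"))
    est <- tryCatch(estimate_breathing_rate(sub, ...),
                    gaitsense_no_peak = function(e) NULL)
    rows[[i]] <- if (is.null(est)) {
      data.frame(t_start = ts, t_end = te, t_center = (ts + te) / 2,
                 bpm = NA_real_, peak_freq = NA_real_,
                 regime = NA_character_, no_peak = TRUE)
    } else {
      data.frame(t_start = ts, t_end = te, t_center = (ts + te) / 2,
                 bpm = est$bpm, peak_freq = est$peak_freq,
                 regime = est$regime, no_peak = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Classify a breathing rate into a clinical regime
#'
#' Bradypnea below 12 BPM, normal breathing between 12 and 20 BPM
#' (boundaries inclusive), tachypnea above 20 BPM. The three regimes
#' partition (0, Inf).
#'
#' @param bpm breathing rate(s) in breaths/min, positive.
#' @return Character vector: `"bradypnea"`, `"normal"` or `"tachypnea"`.
#' @export
classify_regime <- function(bpm) {
  gs_assert(all(bpm > 0), "bpm must be positive", "gaitsense_invalid_bpm")
  ifelse(bpm < 12, "bradypnea", ifelse(bpm <= 20, "normal", "tachypnea"))
}

#' Assign breathing rates to clustering condition bins
#'
#' The reported condition bins are: condition 0 below 10 BPM, condition
#' 1 from 11 to 13, condition 2 from 14 to 16, condition 3 from 17 to
#' 19 and condition 5 above 19 BPM (the labels, including the absent
#' "4", are carried verbatim). The printed bins leave gaps (10-11,
#' 13-14, 16-17); values falling in a gap are assigned to the nearest
#' bin edge, which makes the effective cut points 10.5, 13.5, 16.5 and
#' 19 BPM.
#'
#' @param bpm_values breathing rates in breaths/min, positive.
#' @return Integer vector of bin labels in {0, 1, 2, 3, 5}.
#' @export
assign_condition_bins <- function(bpm_values) {
  gs_assert(all(bpm_values > 0), "breathing rates must be positive",
            "gaitsense_invalid_bpm")
  labels <- c(0L, 1L, 2L, 3L, 5L)
  idx <- findInterval(bpm_values, c(10.5, 13.5, 16.5, 19), left.open = TRUE) + 1
  labels[idx]
}

#' Cluster breathing-rate samples with silhouette-selected K-means
#'
#' Runs K-means at every k in the range (300 iteration cap by default),
#' scores each partition with the mean silhouette width, and keeps the
#' k with the highest score, ties broken toward the smaller k. The full
#' silhouette-versus-k curve is returned so the selection can be
#' inspected.
#'
#' @param samples breathing rates in breaths/min.
#' @param k_range `c(k_min, k_max)`, default 2..20. Truncated to (number
#'   of distinct samples - 1) when the sample set is small.
#' @param max_iter K-means iteration cap (default 300).
#' @param seed integer seed or `NULL`.
#' @param nstart random restarts per k.
#'
#' @return A list of class `br_clustering` with `k`, `centers` (chosen
#'   model, breaths/min), `assignments`, `silhouette_by_k` (named
#'   vector), `condition_bins` (see [assign_condition_bins()]) and
#'   `samples`.
#' @export
cluster_breathing_rates <- function(samples, k_range = c(2, 20),
                                    max_iter = 300, seed = NULL,
                                    nstart = 10) {
  samples <- as.numeric(samples)
  gs_assert(all(is.finite(samples)), "samples must be finite")
  n_distinct <- length(unique(samples))
  if (n_distinct < 3) {
    gs_error("need at least 3 distinct samples to cluster",
             "gaitsense_too_few_samples")
  }
  k_min <- max(2, k_range[1])
  k_max <- min(k_range[2], n_distinct - 1)
  gs_seed(seed)
  d <- stats::dist(samples)
  ks <- k_min:k_max
  sil <- numeric(length(ks))
  fits <- vector("list", length(ks))
  for (i in seq_along(ks)) {
    fit <- stats::kmeans(matrix(samples, ncol = 1), centers = ks[i],
                         iter.max = max_iter, nstart = nstart)
    fits[[i]] <- fit
    sil[i] <- mean(cluster::silhouette(fit$cluster, d)[, "sil_width"])
  }
  names(sil) <- ks
  best <- which.max(sil)  # first maximum: ties break toward smaller k
  fit <- fits[[best]]
  structure(list(k = ks[best],
                 centers = as.numeric(fit$centers),
                 assignments = as.integer(fit$cluster) - 1L,
                 silhouette_by_k = sil,
                 condition_bins = assign_condition_bins(samples),
                 samples = samples),
            class = "br_clustering")
}

#' @export
print.br_clustering <- function(x, ...) {
  cat(sprintf("<br_clustering> %d samples, silhouette-selected k = %d\n",
              length(x$samples), x$k))
  cat("  centers (BPM):", paste(sprintf("%.2f", sort(x$centers)),
                                collapse = ", "), "\n")
  cat(sprintf("  best silhouette: %.3f\n", max(x$silhouette_by_k)))
  invisible(x)
}

#' @export
plot.br_clustering <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  ks <- as.integer(names(x$silhouette_by_k))
  plot(ks, x$silhouette_by_k, type = "b", xlab = "number of clusters k",
       ylab = "mean silhouette width", main = "Silhouette selection", ...)
  graphics::abline(v = x$k, lty = 2)
  plot(seq_along(x$samples), x$samples, col = x$assignments + 1,
       xlab = "sample", ylab = "breathing rate (BPM)",
       main = sprintf("K-means, k = %d", x$k))
  invisible(x)
}
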