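# IMU preprocessing: windowed statistical features, complementary-filter
# orientation, acceleration magnitude.

.axes <- c("ax", "ay", "az", "gx", "gy", "gz")
.stats <- c("mean", "sd", "min", "max", "rms")

#' Names of the window feature columns, in their fixed order
#' @param include_timestamp append the timestamp feature name.
#' @return Character vector of feature names.
#' @export
feature_names <- function(include_timestamp = FALSE) {
  base <- as.vector(t(outer(.axes, .stats, paste, sep = "_")))
  if (include_timestamp) c(base, "t_stamp") else base
}

#' Sliding-window statistical features from an IMU trace
#'
#' For every window position computes, per axis, the mean, SD, min, max
#' and RMS — a fixed 30-feature vector whose order never changes across
#' calls. Optionally the window-center timestamp is appended as a
#' feature: the study's classifier consumed the time stamp as an input,
#' but with one trial per recording that lets a model learn time->phase
#' directly, so it is off by default and enabled explicitly where the
#' original configuration is wanted.
#'
#' @param trace an [imu_trace()].
#' @param window window length in seconds (default 0.5, short enough to
#'   resolve a ~1 s sit-to-stand).
#' @param step hop between windows in seconds (default 0.1).
#' @param include_timestamp append `t_center` as feature `t_stamp`.
#'
#' @return A data frame with `t_center` plus the feature columns.
#' @export
window_features <- function(trace, window = 0.5, step = 0.1,
                            include_timestamp = FALSE) {
  gs_assert(inherits(trace, "imu_trace"), "trace must be an imu_trace")
  rate <- attr(trace, "rate")
  n <- nrow(trace)
  win_n <- max(2L, round(window * rate))
  step_n <- max(1L, round(step * rate))
  gs_assert(win_n <= n, "window is longer than the trace",
            "gaitsense_window_too_long")
  starts <- seq.int(1L, n - win_n + 1L, by = step_n)
  idx <- outer(starts, 0:(win_n - 1L), "+")
  t_center <- trace$t[starts] + (win_n - 1) / (2 * rate)

  feats <- matrix(NA_real_, nrow = length(starts),
                  ncol = length(.axes) * length(.stats))
  j <- 1
  for (axis in .axes) {
    v <- trace[[axis]]
    M <- matrix(v[idx], nrow = length(starts))
    m <- rowMeans(M)
    msq <- rowMeans(M^2)
    sdv <- sqrt(pmax(0, (msq - m^2) * win_n / (win_n - 1)))
    feats[, j] <- m
    feats[, j + 1] <- sdv
    feats[, j + 2] <- apply(M, 1, min)
    feats[, j + 3] <- apply(M, 1, max)
    feats[, j + 4] <- sqrt(msq)
    j <- j + 5
  }
  out <- data.frame(t_center = t_center, feats)
  names(out) <- c("t_center", feature_names(FALSE))
  if (include_timestamp) out$t_stamp <- t_center
  out
}

#' Pitch and roll from complementary accelerometer/gyroscope fusion
#'
#' Per sample, `angle <- alpha * (angle + gyro * dt) + (1 - alpha) *
#' accel_inclination`, initialized from the first accelerometer sample.
#' Pitch (sagittal plane) is driven by the y gyro, roll (frontal plane)
#' by the x gyro. Samples whose acceleration norm falls below
#' `freefall_thresh` carry no usable inclination; the filter then holds
#' the gyro-only update and flags the sample.
#'
#' @param trace an [imu_trace()].
#' @param alpha gyro weighting in (0, 1); 0.98 is a standard wearable
#'   fusion constant at 100 Hz.
#' @param freefall_thresh acceleration-norm threshold in m/s^2 below
#'   which the accelerometer inclination is ignored.
#'
#' @return A data frame of class `orientation_series` with columns `t`,
#'   `pitch`, `roll` (degrees, in [-180, 180]) and `freefall`.
#' @export
estimate_orientation <- function(trace, alpha = 0.98, freefall_thresh = 2) {
  gs_assert(inherits(trace, "imu_trace"), "trace must be an imu_trace")
  gs_assert(alpha > 0 && alpha < 1, "alpha must lie in (0, 1)")
  n <- nrow(trace)
  dt <- 1 / attr(trace, "rate")
  deg <- 180 / pi
  pitch_acc <- atan2(trace$ax, sqrt(trace$ay^2 + trace$az^2)) * deg
  roll_acc <- atan2(trace$ay, sqrt(trace$ax^2 + trace$az^2)) * deg
  norm <- sqrt(trace$ax^2 + trace$ay^2 + trace$az^2)
  freefall <- norm < freefall_thresh

  pitch <- numeric(n); roll <- numeric(n)
  pitch[1] <- pitch_acc[1]; roll[1] <- roll_acc[1]
  for (i in 2:n) {
    p_gyro <- pitch[i - 1] + trace$gy[i] * dt
    r_gyro <- roll[i - 1] + trace$gx[i] * dt
    if (freefall[i]) {
      pitch[i] <- p_gyro
      roll[i] <- r_gyro
    } else {
      pitch[i] <- alpha * p_gyro + (1 - alpha) * pitch_acc[i]
      roll[i] <- alpha * r_gyro + (1 - alpha) * roll_acc[i]
    }
  }
  wrap <- function(a) ((a + 180) %% 360) - 180
  out <- data.frame(t = trace$t, pitch = wrap(pitch), roll = wrap(roll),
                    freefall = freefall)
  class(out) <- c("orientation_series", "data.frame")
  out
}

#' Maximum absolute sagittal and frontal angles over an interval
#'
#' @param orient an `orientation_series` from [estimate_orientation()].
#' @param interval `c(t0, t1)` in seconds; defaults to the whole series.
#' @return A list with `sagittal_max` and `frontal_max` in degrees
#'   (maxima of |pitch| and |roll|).
#' @export
max_angles_per_plane <- function(orient, interval = NULL) {
  gs_assert(inherits(orient, "orientation_series"),
            "orient must be an orientation_series")
  if (is.null(interval)) interval <- range(orient$t)
  keep <- orient$t >= interval[1] - 1e-9 & orient$t <= interval[2] + 1e-9
  gs_assert(any(keep), "interval contains no samples",
            "gaitsense_empty_interval")
  list(sagittal_max = max(abs(orient$pitch[keep])),
       frontal_max = max(abs(orient$roll[keep])))
}

#' Per-sample acceleration magnitude
#'
#' Euclidean norm of the acceleration vector; no gravity compensation is
#' applied (a static trace reads ~9.81 m/s^2).
#'
#' @param trace an [imu_trace()].
#' @return A data frame with columns `t` and `mag` (m/s^2).
#' @export
accel_magnitude <- function(trace) {
  gs_assert(inherits(trace, "imu_trace"), "trace must be an imu_trace")
  data.frame(t = trace$t, mag = sqrt(trace$ax^2 + trace$ay^2 + trace$az^2))
}
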