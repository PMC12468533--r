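# Core signal containers: IMU and optical-intensity traces.
#
# Axis convention (fixed, documented here because the hardware does not
# impose one): x anteroposterior, y mediolateral, z vertical. Units are
# m/s^2 for accelerations, deg/s for angular velocities, seconds for
# time, arbitrary units (a.u.) for optical intensity.

#' Construct a 6-axis IMU trace
#'
#' @param t numeric vector of sample times in seconds, strictly increasing
#'   and uniformly spaced.
#' @param accel n x 3 matrix of accelerations (x, y, z) in m/s^2.
#' @param gyro n x 3 matrix of angular velocities (x, y, z) in deg/s.
#' @param rate sampling rate in Hz; inferred from `t` when `NULL`.
#'
#' @return A data frame of class `imu_trace` with columns
#'   `t, ax, ay, az, gx, gy, gz` and a `rate` attribute.
#' @export
imu_trace <- function(t, accel, gyro, rate = NULL) {
  accel <- as.matrix(accel); gyro <- as.matrix(gyro)
  gs_assert(length(t) >= 2, "an IMU trace needs at least 2 samples")
  gs_assert(nrow(accel) == length(t) && nrow(gyro) == length(t) &&
              ncol(accel) == 3 && ncol(gyro) == 3,
            "accel and gyro must be n x 3 with n = length(t)")
  gs_assert(all(is.finite(accel)) && all(is.finite(gyro)),
            "accel and gyro must be finite")
  gs_assert(is_uniform_time(t),
            "t must be strictly increasing and uniformly spaced",
            "gaitsense_nonuniform_time")
  out <- data.frame(t = t,
                    ax = accel[, 1], ay = accel[, 2], az = accel[, 3],
                    gx = gyro[, 1], gy = gyro[, 2], gz = gyro[, 3])
  attr(out, "rate") <- if (is.null(rate)) 1 / stats::median(diff(t)) else rate
  class(out) <- c("imu_trace", "data.frame")
  out
}

#' Construct an optical-intensity trace
#'
#' @param t numeric vector of sample times in seconds.
#' @param intensity optical intensity in arbitrary units.
#' @param rate sampling rate in Hz; inferred from `t` when `NULL`.
#' @param bpm_true optional ground-truth breathing rate (breaths/min),
#'   carried as metadata by the simulator.
#'
#' @return A data frame of class `optical_trace` with columns `t, intensity`.
#' @export
optical_trace <- function(t, intensity, rate = NULL, bpm_true = NULL) {
  gs_assert(length(t) >= 2, "an optical trace needs at least 2 samples")
  gs_assert(length(intensity) == length(t), "t and intensity lengths differ")
  gs_assert(all(is.finite(intensity)), "intensity must be finite")
  gs_assert(is_uniform_time(t),
            "t must be strictly increasing and uniformly spaced",
            "gaitsense_nonuniform_time")
  out <- data.frame(t = t, intensity = intensity)
  attr(out, "rate") <- if (is.null(rate)) 1 / stats::median(diff(t)) else rate
  if (!is.null(bpm_true)) attr(out, "bpm_true") <- bpm_true
  class(out) <- c("optical_trace", "data.frame")
  out
}

#' Construct a per-sample phase label series
#'
#' TUG phases are coded 0..6: 0 start/idle, 1 sit-to-stand, 2 forward
#' walk, 3 first turn, 4 return walk, 5 second turn, 6 stand-to-sit.
#'
#' @param t sample times in seconds.
#' @param phase integer phase class per sample, in 0..6.
#' @return A data frame of class `phase_label_series`.
#' @export
phase_label_series <- function(t, phase) {
  gs_assert(length(t) == length(phase), "t and phase lengths differ")
  gs_assert(all(phase %in% 0:6), "phase classes must be integers in 0..6")
  out <- data.frame(t = t, phase = as.integer(phase))
  class(out) <- c("phase_label_series", "data.frame")
  out
}

#' @export
print.imu_trace <- function(x, ...) {
  cat(sprintf("<imu_trace> %d samples @ %.6g Hz, %.6g s\n",
              nrow(x), attr(x, "rate"), x$t[nrow(x)] - x$t[1]))
  invisible(x)
}

#' @export
print.optical_trace <- function(x, ...) {
  bpm <- attr(x, "bpm_true")
  cat(sprintf("<optical_trace> %d samples @ %.6g Hz, %.6g s%s\n",
              nrow(x), attr(x, "rate"), x$t[nrow(x)] - x$t[1],
              if (is.null(bpm)) "" else sprintf(", true BR %.6g BPM", bpm)))
  invisible(x)
}
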