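# Synthetic wearable-signal generator.
#
# The raw recordings behind the study protocols (TUG, quiet-stance
# balance, metronome-paced breathing) are not deposited, so every
# downstream stage is exercised against signals generated here with
# known ground truth. Templates are deliberately minimal: piecewise
# deterministic kinematic shapes plus additive Gaussian sensor noise,
# with amplitudes anchored to the magnitudes such sensors report in
# practice (sit-to-stand pitch pulses of tens of deg/s, walking
# accelerations around 1 m/s^2, quiet-stance accelerations well below
# 1 m/s^2).

# Default TUG phase durations in seconds, classes 0..6. Classes 1..6 sum
# to 10.96 s, a typical healthy completion time; sit-to-stand is 1.26 s.
.default_phase_durations <- c(2.00, 1.26, 2.80, 1.74, 2.80, 1.20, 1.16)

# Narrow-base factors relative to the wide-base defaults: medial sway
# grows (6 -> 16 mm), anterior sway shrinks (33 -> 20 mm), and local
# fractal stability drops (1.68 -> 0.92) when the feet are together.
.narrow_factors <- list(anterior = 20 / 33, medial = 16 / 6, lfs = 0.92 / 1.68)

#' Subject profile for the synthetic generators
#'
#' Bundles the per-subject ground-truth parameters that drive trial
#' simulation. Balance amplitudes default to the wide-base condition;
#' [simulate_balance_trial()] rescales them for the narrow base.
#'
#' @param walk_cadence step frequency in steps/s.
#' @param phase_durations numeric length-7 vector of TUG phase durations
#'   in seconds (classes 0..6).
#' @param sway_amp_anterior,sway_amp_medial peak quiet-stance sway
#'   displacement in mm (wide base).
#' @param lfs_true latent local fractal stability (dimensionless, wide
#'   base); higher values mean greater postural control.
#' @param breathing_bpm breathing rate in breaths/min, in (0, 60).
#' @param noise_sd_accel,noise_sd_gyro additive sensor noise SD in
#'   m/s^2 and deg/s.
#' @param seed integer seed making generation reproducible; `NULL` uses
#'   the current RNG stream.
#'
#' @return A list of class `subject_profile`.
#' @export
subject_profile <- function(walk_cadence = 2.0,
                            phase_durations = .default_phase_durations,
                            sway_amp_anterior = 33,
                            sway_amp_medial = 6,
                            lfs_true = 1.68,
                            breathing_bpm = 15,
                            noise_sd_accel = 0.1,
                            noise_sd_gyro = 1.0,
                            seed = NULL) {
  gs_assert(length(phase_durations) == 7 && all(phase_durations > 0),
            "phase_durations must be 7 positive values (classes 0..6)")
  gs_assert(sway_amp_anterior >= 0 && sway_amp_medial >= 0,
            "sway amplitudes must be >= 0")
  gs_assert(breathing_bpm > 0 && breathing_bpm < 60,
            "breathing_bpm must lie in (0, 60)")
  gs_assert(walk_cadence > 0, "walk_cadence must be positive")
  gs_assert(noise_sd_accel >= 0 && noise_sd_gyro >= 0,
            "noise SDs must be >= 0")
  structure(list(walk_cadence = walk_cadence,
                 phase_durations = as.numeric(phase_durations),
                 sway_amp_anterior = sway_amp_anterior,
                 sway_amp_medial = sway_amp_medial,
                 lfs_true = lfs_true,
                 breathing_bpm = breathing_bpm,
                 noise_sd_accel = noise_sd_accel,
                 noise_sd_gyro = noise_sd_gyro,
                 seed = seed),
            class = "subject_profile")
}

# Raised-cosine-edged plateau on (0,1); used for turn angular velocity.
.plateau <- function(s, edge = 0.2) {
  y <- rep(1, length(s))
  lo <- s < edge
  hi <- s > 1 - edge
  y[lo] <- 0.5 * (1 - cos(pi * s[lo] / edge))
  y[hi] <- 0.5 * (1 - cos(pi * (1 - s[hi]) / edge))
  y
}

#' Simulate a labeled Timed-Up-and-Go trial
#'
#' Emits per-phase kinematic templates on the fixed axis convention:
#' sit-to-stand (class 1) a half-sine pitch angular-velocity pulse with
#' a vertical-acceleration spike; walking phases (2, 4) an oscillation
#' at the cadence frequency on the anteroposterior and vertical axes;
#' turns (3, 5) a yaw angular-velocity plateau of opposite sign whose
#' area integrates to a 180 degree turn; stand-to-sit (class 6) the
#' mirrored transfer pulse. Additive Gaussian noise models the sensors.
#'
#' @param profile a [subject_profile()].
#' @param rate IMU sampling rate in Hz (default 100).
#' @param optical_rate chest-belt sampling rate in Hz (default 50).
#' @param seed overrides `profile$seed` when non-`NULL`.
#'
#' @return A list of class `labeled_trial` with elements `imu`
#'   ([imu_trace()]), `optical` ([optical_trace()]), `labels`
#'   ([phase_label_series()]) and `truth`. `truth$intervals` holds the
#'   per-class first/last detection times on the sample grid;
#'   `truth$total_time` is the exact sum of the generating durations of
#'   classes 1..6.
#' @export
simulate_tug_trial <- function(profile = subject_profile(), rate = 100,
                               optical_rate = 50, seed = NULL) {
  gs_assert(inherits(profile, "subject_profile"), "profile must be a subject_profile")
  gs_assert(rate > 0 && optical_rate > 0, "sampling rates must be positive",
            "gaitsense_invalid_rate")
  d <- profile$phase_durations
  gs_assert(sum(d) >= 1, "phase durations must sum to at least 1 s")
  gs_seed(if (is.null(seed)) profile$seed else seed)

  n_per <- pmax(1L, round(d * rate))
  n <- sum(n_per)
  dt <- 1 / rate
  t <- (seq_len(n) - 1) * dt
  phase <- rep(0:6, times = n_per)

  ax <- numeric(n); ay <- numeric(n); az <- rep(9.81, n)
  gx <- numeric(n); gy <- numeric(n); gz <- numeric(n)

  starts <- cumsum(c(1L, n_per[-7]))
  ends <- cumsum(n_per)
  for (c in 0:6) {
    i <- starts[c + 1]:ends[c + 1]
    s <- (seq_along(i) - 0.5) / length(i)   # local phase position in (0,1)
    tl <- (seq_along(i) - 1) * dt           # local time
    if (c == 1) {            # sit-to-stand: pitch pulse + vertical spike
      gy[i] <- gy[i] + 60 * sin(pi * s)
      az[i] <- az[i] + 2.0 * sin(pi * s)
      ax[i] <- ax[i] + 0.8 * sin(pi * s)
    } else if (c == 2 || c == 4) {  # walking at cadence frequency
      f <- profile$walk_cadence
      ax[i] <- ax[i] + 1.0 * sin(2 * pi * f * tl)
      az[i] <- az[i] + 0.6 * sin(2 * pi * f * tl + pi / 3)
      gy[i] <- gy[i] + 8 * sin(2 * pi * f * tl + pi / 6)
    } else if (c == 3 || c == 5) {  # turns: opposite-sign yaw plateaus
      sgn <- if (c == 3) 1 else -1
      # plateau height so the integrated yaw is ~180 deg over the phase
      gz[i] <- gz[i] + sgn * (180 / (d[c + 1] * (1 - 0.2))) * .plateau(s)
      ax[i] <- ax[i] + 0.3 * sin(pi * s)
    } else if (c == 6) {     # stand-to-sit: mirrored transfer
      gy[i] <- gy[i] - 60 * sin(pi * s)
      az[i] <- az[i] - 1.8 * sin(pi * s)
      ax[i] <- ax[i] - 0.6 * sin(pi * s)
    }
  }

  if (profile$noise_sd_accel > 0) {
    ax <- ax + stats::rnorm(n, 0, profile$noise_sd_accel)
    ay <- ay + stats::rnorm(n, 0, profile$noise_sd_accel)
    az <- az + stats::rnorm(n, 0, profile$noise_sd_accel)
  }
  if (profile$noise_sd_gyro > 0) {
    gx <- gx + stats::rnorm(n, 0, profile$noise_sd_gyro)
    gy <- gy + stats::rnorm(n, 0, profile$noise_sd_gyro)
    gz <- gz + stats::rnorm(n, 0, profile$noise_sd_gyro)
  }

  imu <- imu_trace(t, cbind(ax, ay, az), cbind(gx, gy, gz), rate = rate)
  labels <- phase_label_series(t, phase)
  optical <- simulate_breathing_trace(profile$breathing_bpm,
                                      duration = max(20, sum(d)),
                                      rate = optical_rate, seed = NULL)

  # Independent arithmetic for the per-class truth intervals on the
  # sample grid: first/last sample times of each class.
  intervals <- data.frame(
    class = 1:6,
    first_detect = t[starts[2:7]],
    last_detect = t[ends[2:7]],
    duration = t[ends[2:7]] - t[starts[2:7]]
  )
  truth <- list(phase_durations = d,
                intervals = intervals,
                total_time = sum(d[2:7]),
                breathing_bpm = profile$breathing_bpm,
                cadence = profile$walk_cadence)
  structure(list(imu = imu, optical = optical, labels = labels,
                 truth = truth, kind = "tug"),
            class = "labeled_trial")
}

#' Simulate a labeled quiet-stance balance trial
#'
#' Postural sway is modeled as band-limited noise: white noise band-pass
#' filtered between `band_lo` and an upper corner that scales inversely
#' with the latent local fractal stability (LFS), so that a more stable
#' subject produces smoother, lower-frequency sway. The displacement
#' series is scaled so its peak excursion equals the profile's sway
#' amplitude, and accelerations are its second time derivative plus
#' gravity and sensor noise. Narrow stance multiplies the medial
#' amplitude, shrinks the anterior amplitude and reduces LFS by fixed
#' factors relative to the wide-base profile values.
#'
#' @param profile a [subject_profile()]; its sway amplitudes and
#'   `lfs_true` are the wide-base values.
#' @param stance `"wide"` or `"narrow"`.
#' @param duration trial length in seconds (default 30).
#' @param rate IMU sampling rate in Hz.
#' @param optical_rate chest-belt sampling rate in Hz.
#' @param band_lo lower sway pass-band edge in Hz.
#' @param lfs_corner product of LFS and the upper pass-band edge in Hz
#'   (upper edge = lfs_corner / lfs, clamped to [0.15, 3] Hz).
#' @param seed overrides `profile$seed` when non-`NULL`.
#'
#' @return A `labeled_trial` whose `truth` carries
#'   `anterior_mm`, `medial_mm` and `lfs`; labels are all 0 (no TUG
#'   phases during quiet stance).
#' @export
simulate_balance_trial <- function(profile = subject_profile(),
                                   stance = c("wide", "narrow"),
                                   duration = 30, rate = 100,
                                   optical_rate = 50,
                                   band_lo = 0.1, lfs_corner = 0.8,
                                   seed = NULL) {
  gs_assert(inherits(profile, "subject_profile"), "profile must be a subject_profile")
  gs_assert(is.character(stance) && stance[1] %in% c("wide", "narrow"),
            "stance must be 'wide' or 'narrow'", "gaitsense_unknown_stance")
  stance <- stance[1]
  gs_assert(rate > 0 && duration > 0, "rate and duration must be positive",
            "gaitsense_invalid_rate")
  gs_seed(if (is.null(seed)) profile$seed else seed)

  ant <- profile$sway_amp_anterior
  med <- profile$sway_amp_medial
  lfs <- profile$lfs_true
  if (stance == "narrow") {
    ant <- ant * .narrow_factors$anterior
    med <- med * .narrow_factors$medial
    lfs <- lfs * .narrow_factors$lfs
  }

  n <- max(4L, round(duration * rate))
  dt <- 1 / rate
  t <- (seq_len(n) - 1) * dt

  f_hi <- min(3, max(0.15, lfs_corner / lfs))
  sway <- function(amp_mm) {
    if (amp_mm <= 0) return(numeric(n))
    w <- stats::rnorm(n)
    bf <- signal::butter(2, c(band_lo, f_hi) / (rate / 2), type = "pass")
    x <- signal::filtfilt(bf, w)
    x / max(abs(x)) * amp_mm
  }
  disp_x <- sway(ant)  # anterior (mm)
  disp_y <- sway(med)  # medial (mm)

  # acceleration = second derivative of displacement, mm -> m
  accel_of <- function(disp) {
    if (all(disp == 0)) return(numeric(n))
    a <- c(0, diff(disp, differences = 2), 0) / dt^2 / 1000
    a
  }
  ax <- accel_of(disp_x)
  ay <- accel_of(disp_y)
  az <- rep(9.81, n)
  gx <- numeric(n); gy <- numeric(n); gz <- numeric(n)

  if (profile$noise_sd_accel > 0) {
    ax <- ax + stats::rnorm(n, 0, profile$noise_sd_accel)
    ay <- ay + stats::rnorm(n, 0, profile$noise_sd_accel)
    az <- az + stats::rnorm(n, 0, profile$noise_sd_accel)
  }
  if (profile$noise_sd_gyro > 0) {
    gx <- gx + stats::rnorm(n, 0, profile$noise_sd_gyro)
    gy <- gy + stats::rnorm(n, 0, profile$noise_sd_gyro)
    gz <- gz + stats::rnorm(n, 0, profile$noise_sd_gyro)
  }

  imu <- imu_trace(t, cbind(ax, ay, az), cbind(gx, gy, gz), rate = rate)
  labels <- phase_label_series(t, rep(0L, n))
  optical <- simulate_breathing_trace(profile$breathing_bpm,
                                      duration = max(20, duration),
                                      rate = optical_rate, seed = NULL)
  truth <- list(anterior_mm = ant, medial_mm = med, lfs = lfs,
                stance = stance, breathing_bpm = profile$breathing_bpm)
  structure(list(imu = imu, optical = optical, labels = labels,
                 truth = truth, kind = "balance"),
            class = "labeled_trial")
}

#' Simulate a chest-belt optical-intensity breathing trace
#'
#' Chest-wall motion curves the fiber and modulates transmitted
#' intensity, so the trace is modeled as
#' `baseline + amplitude * sin(2*pi*(bpm/60)*t) + drift*t + noise`.
#'
#' @param bpm breathing rate in breaths/min, in (0, 60).
#' @param duration record length in seconds, at least 20.
#' @param rate sampling rate in Hz.
#' @param amplitude modulation amplitude in a.u. (default 0.45, i.e. a
#'   peak-to-peak swing of 0.9 a.u.).
#' @param baseline transmitted-intensity baseline in a.u.
#' @param noise_sd additive Gaussian noise SD in a.u.; the default is 5%
#'   of the amplitude.
#' @param drift linear baseline drift in a.u./s.
#' @param seed integer seed or `NULL`.
#'
#' @return An [optical_trace()] carrying the generating rate as
#'   `attr(, "bpm_true")`.
#' @export
simulate_breathing_trace <- function(bpm, duration = 60, rate = 50,
                                     amplitude = 0.45, baseline = 1,
                                     noise_sd = 0.05 * amplitude,
                                     drift = 0, seed = NULL) {
  gs_assert(bpm > 0 && bpm < 60, "bpm must lie in (0, 60)",
            "gaitsense_invalid_bpm")
  gs_assert(duration >= 20, "duration must be at least 20 s")
  gs_assert(rate > 0, "rate must be positive", "gaitsense_invalid_rate")
  gs_seed(seed)
  n <- round(duration * rate)
  t <- (seq_len(n) - 1) / rate
  x <- baseline + amplitude * sin(2 * pi * (bpm / 60) * t) + drift * t
  if (noise_sd > 0) x <- x + stats::rnorm(n, 0, noise_sd)
  optical_trace(t, x, rate = rate, bpm_true = bpm)
}

#' Simulate the metronome characterization protocol
#'
#' Five repeated belt recordings at each of five metronome-paced
#' breathing rates (10, 13, 15, 17 and 20 BPM), mirroring the bench
#' characterization of the breathing sensor.
#'
#' @param seed integer seed or `NULL`.
#' @param bpms reference rates in breaths/min.
#' @param n_repeats recordings per rate.
#' @param duration,rate,noise_sd passed to [simulate_breathing_trace()].
#'
#' @return A list of 25 [optical_trace()]s (by default), each with its
#'   reference rate in `attr(, "bpm_true")`.
#' @export
simulate_metronome_protocol <- function(seed = NULL,
                                        bpms = c(10, 13, 15, 17, 20),
                                        n_repeats = 5, duration = 60,
                                        rate = 50, noise_sd = 0.05 * 0.45) {
  gs_seed(seed)
  out <- vector("list", length(bpms) * n_repeats)
  k <- 1
  for (bpm in bpms) {
    for (r in seq_len(n_repeats)) {
      out[[k]] <- simulate_breathing_trace(bpm, duration = duration,
                                           rate = rate, noise_sd = noise_sd,
                                           seed = NULL)
      k <- k + 1
    }
  }
  out
}

#' Simulate a breathing-rate sample set with planted regime bands
#'
#' Draws rates from five Gaussian bands centered in the clustering
#' condition bins (below 10; 11-13; 14-16; 17-19; above 19 BPM, band
#' centers 8, 12, 15, 18 and 22), truncated to (0, 60). Samples are
#' allocated as evenly as possible across bands, remainders going to the
#' lowest bands first.
#'
#' @param n number of samples, at least 10 (default 145).
#' @param seed integer seed or `NULL`.
#' @param centers band centers in breaths/min.
#' @param sd within-band SD in breaths/min.
#'
#' @return A data frame with columns `bpm` and `band` (condition labels
#'   0, 1, 2, 3, 5).
#' @export
simulate_br_samples <- function(n = 145, seed = NULL,
                                centers = c(8, 12, 15, 18, 22), sd = 0.5) {
  gs_assert(n >= 10, "n must be at least 10", "gaitsense_invalid_n")
  gs_seed(seed)
  labels <- c(0L, 1L, 2L, 3L, 5L)
  base <- n %/% 5
  counts <- rep(base, 5) + c(rep(1L, n %% 5), rep(0L, 5 - n %% 5))
  bpm <- numeric(0); band <- integer(0)
  for (i in seq_along(centers)) {
    x <- stats::rnorm(counts[i], centers[i], sd)
    # truncate to the physiologic range by redrawing out-of-range values
    bad <- which(x <= 0 | x >= 60)
    while (length(bad)) {
      x[bad] <- stats::rnorm(length(bad), centers[i], sd)
      bad <- which(x <= 0 | x >= 60)
    }
    bpm <- c(bpm, x)
    band <- c(band, rep(labels[i], counts[i]))
  }
  data.frame(bpm = bpm, band = band)
}

#' @export
print.labeled_trial <- function(x, ...) {
  cat(sprintf("<labeled_trial: %s> %d IMU samples, %d optical samples\n",
              x$kind, nrow(x$imu), nrow(x$optical)))
  if (x$kind == "tug") {
    cat(sprintf("  true total time (classes 1..6): %.4g s\n",
                x$truth$total_time))
  } else {
    cat(sprintf("  truth: anterior %.3g mm, medial %.3g mm, LFS %.3g (%s)\n",
                x$truth$anterior_mm, x$truth$medial_mm, x$truth$lfs,
                x$truth$stance))
  }
  invisible(x)
}
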