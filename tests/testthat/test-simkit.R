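test_that("subject profiles validate their invariants", {
  expect_error(subject_profile(phase_durations = rep(1, 6)))
  expect_error(subject_profile(phase_durations = c(rep(1, 6), -1)))
  expect_error(subject_profile(sway_amp_anterior = -1))
  expect_error(subject_profile(breathing_bpm = 0))
  expect_error(subject_profile(breathing_bpm = 60))
  expect_s3_class(subject_profile(), "subject_profile")
})

test_that("TUG trial truth matches the generating durations", {
  trial <- simulate_tug_trial(subject_profile(), seed = 7)
  expect_equal(trial$truth$total_time, 10.96)
  # labels are piecewise constant and ordered 0 -> 6
  expect_identical(unique(trial$labels$phase), 0:6)
  expect_true(all(diff(trial$labels$phase) >= 0))
  # imu and labels share one time base
  expect_identical(trial$imu$t, trial$labels$t)
})

test_that("same seed reproduces a TUG trial bit for bit", {
  a <- simulate_tug_trial(subject_profile(), seed = 7)
  b <- simulate_tug_trial(subject_profile(), seed = 7)
  expect_identical(a$imu, b$imu)
  expect_identical(a$optical, b$optical)
  expect_identical(a$labels, b$labels)
})

test_that("different seeds change only the noise, not the labels", {
  a <- simulate_tug_trial(subject_profile(), seed = 7)
  b <- simulate_tug_trial(subject_profile(), seed = 8)
  expect_identical(a$labels, b$labels)
  expect_false(identical(a$imu$ax, b$imu$ax))
})

test_that("noiseless kinematics are seed-independent", {
  a <- simulate_tug_trial(quiet_profile(), seed = 1)
  b <- simulate_tug_trial(quiet_profile(), seed = 99)
  expect_identical(a$imu, b$imu)
})

test_that("interval extraction on true labels returns exactly the truth intervals", {
  for (seed in c(2, 5, 11)) {
    trial <- simulate_tug_trial(subject_profile(), seed = seed)
    iv <- extract_phase_intervals(trial$labels)
    expect_equal(iv$intervals$first_detect, trial$truth$intervals$first_detect)
    expect_equal(iv$intervals$last_detect, trial$truth$intervals$last_detect)
    expect_equal(iv$intervals$duration, trial$truth$intervals$duration)
    # grid durations agree with the generating durations to one sample
    dt <- 1 / attr(trial$imu, "rate")
    expect_lt(max(abs(iv$intervals$duration -
                        trial$truth$phase_durations[2:7])), dt + 1e-9)
  }
})

test_that("balance trial truth reflects stance defaults", {
  wide <- simulate_balance_trial(subject_profile(), "wide", seed = 3)
  expect_equal(wide$truth$anterior_mm, 33)
  expect_equal(wide$truth$medial_mm, 6)
  expect_equal(wide$truth$lfs, 1.68)
  narrow <- simulate_balance_trial(subject_profile(), "narrow", seed = 3)
  expect_equal(narrow$truth$anterior_mm, 20, tolerance = 1e-6)
  expect_equal(narrow$truth$medial_mm, 16, tolerance = 1e-6)
  expect_equal(narrow$truth$lfs, 0.92, tolerance = 1e-6)
  expect_error(simulate_balance_trial(subject_profile(), "sideways"),
               class = "gaitsense_unknown_stance")
})

test_that("zero sway amplitudes give pure-noise accelerations and zero truth", {
  p <- subject_profile(sway_amp_anterior = 0, sway_amp_medial = 0,
                       noise_sd_accel = 0, noise_sd_gyro = 0)
  trial <- simulate_balance_trial(p, "wide", seed = 4)
  expect_equal(trial$truth$anterior_mm, 0)
  expect_equal(trial$truth$medial_mm, 0)
  expect_true(all(trial$imu$ax == 0))
  expect_true(all(trial$imu$ay == 0))
})

test_that("narrow stance has larger medial acceleration variance than wide", {
  for (seed in c(1, 2, 3)) {
    w <- simulate_balance_trial(subject_profile(), "wide", seed = seed)
    n <- simulate_balance_trial(subject_profile(), "narrow", seed = seed)
    expect_gt(var(n$imu$ay), var(w$imu$ay))
  }
})

test_that("breathing traces carry the generating rate in their spectrum", {
  # 20.4 BPM corresponds to a 0.34 Hz dominant tone
  tr <- simulate_breathing_trace(20.4, 60, 50, noise_sd = 0, drift = 0,
                                 seed = 1)
  est <- estimate_breathing_rate(tr)
  expect_equal(est$peak_freq, 0.34, tolerance = 1e-3)
  # seeded noisy trace: recovery within one interpolated bin
  tr2 <- simulate_breathing_trace(15, 120, 50, seed = 2)
  expect_equal(estimate_breathing_rate(tr2)$bpm, 15, tolerance = 0.2)
  # drift does not bias the estimate
  tr3 <- simulate_breathing_trace(15, 60, 50, drift = 0.01, seed = 3)
  expect_equal(estimate_breathing_rate(tr3)$bpm, 15, tolerance = 0.2)
  expect_error(simulate_breathing_trace(0, 60), class = "gaitsense_invalid_bpm")
  expect_error(simulate_breathing_trace(65, 60), class = "gaitsense_invalid_bpm")
})

test_that("metronome protocol emits 25 tagged traces, deterministically", {
  a <- simulate_metronome_protocol(seed = 1)
  expect_length(a, 25)
  refs <- vapply(a, function(x) attr(x, "bpm_true"), numeric(1))
  expect_equal(sort(unique(refs)), c(10, 13, 15, 17, 20))
  expect_true(all(table(refs) == 5))
  durations <- vapply(a, function(x) nrow(x) / attr(x, "rate"), numeric(1))
  expect_true(all(durations == 60))
  b <- simulate_metronome_protocol(seed = 1)
  expect_identical(a, b)
})

test_that("breathing-rate sample sets respect range and band allocation", {
  s <- simulate_br_samples(145, seed = 3)
  expect_equal(nrow(s), 145)
  expect_true(all(s$bpm > 0 & s$bpm < 60))
  expect_setequal(unique(s$band), c(0, 1, 2, 3, 5))
  s10 <- simulate_br_samples(10, seed = 1)
  expect_equal(nrow(s10), 10)
  expect_true(all(table(s10$band) == 2))
  expect_error(simulate_br_samples(5), class = "gaitsense_invalid_n")
})
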