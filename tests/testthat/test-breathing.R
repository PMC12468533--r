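test_that("a clean single tone is recovered to sub-bin accuracy", {
  rate <- 50
  t <- (0:5999) / rate
  tr <- optical_trace(t, 1 + 0.5 * sin(2 * pi * 0.25 * t), rate = rate)
  est <- estimate_breathing_rate(tr)
  expect_equal(est$bpm, 15, tolerance = 0.01)
  expect_equal(est$bpm, 60 * est$peak_freq)
  expect_equal(est$regime, "normal")
})

test_that("degenerate traces raise classed errors", {
  t <- (0:1499) / 50
  expect_error(estimate_breathing_rate(optical_trace(t, rep(2, 1500))),
               class = "gaitsense_no_peak")
  short <- optical_trace((0:499) / 50, sin((0:499) / 8))
  expect_error(estimate_breathing_rate(short),
               class = "gaitsense_trace_too_short")
  # pure white noise has no dominant respiratory peak
  set.seed(42)
  noise <- optical_trace(t, rnorm(1500), rate = 50)
  expect_error(estimate_breathing_rate(noise), class = "gaitsense_no_peak")
})

test_that("noise robustness: sub-0.6 BPM error at 10 dB SNR over 100 trials", {
  # SNR = (A^2/2)/sigma^2 = 10  =>  sigma = A / sqrt(20)
  amp <- 0.45
  sigma <- amp / sqrt(20)
  set.seed(123)
  errs <- vapply(1:100, function(i) {
    bpm <- runif(1, 8, 25)
    tr <- simulate_breathing_trace(bpm, 60, 50, amplitude = amp,
                                   noise_sd = sigma, seed = NULL)
    abs(estimate_breathing_rate(tr)$bpm - bpm)
  }, numeric(1))
  expect_lt(max(errs), 0.6)
})

test_that("sliding series counts windows and flags peakless ones", {
  tr <- simulate_breathing_trace(15, 120, 50, seed = 1)
  s <- sliding_breathing_series(tr, window = 40, step = 20)
  expect_equal(nrow(s), 5)  # floor((120 - 40)/20) + 1
  # stationary trace: all estimates equal within one interpolated bin
  expect_lt(diff(range(s$bpm)), 0.1)
  expect_false(any(s$no_peak))
  # flat half: windows there are flagged, not dropped
  t <- (0:5999) / 50
  x <- c(1 + 0.5 * sin(2 * pi * 0.25 * t[1:3000]), rep(1, 3000))
  s2 <- sliding_breathing_series(optical_trace(t, x, rate = 50), 40, 20)
  expect_equal(nrow(s2), 5)
  expect_true(any(s2$no_peak))
  expect_true(all(is.na(s2$bpm[s2$no_peak])))
  expect_error(sliding_breathing_series(tr, window = 10),
               class = "gaitsense_trace_too_short")
})

test_that("a two-segment trace brackets the rate change", {
  t1 <- simulate_breathing_trace(12, 60, 50, seed = 2)
  t2 <- simulate_breathing_trace(24, 60, 50, seed = 3)
  comb <- optical_trace(c(t1$t, t2$t + 60), c(t1$intensity, t2$intensity),
                        rate = 50)
  s <- sliding_breathing_series(comb, 40, 20)
  # oracle: plain periodogram peak of each pure segment
  peak_of <- function(x, rate) {
    sp <- Mod(fft(x - mean(x)))[seq_len(length(x) %/% 2 + 1)]
    f <- (seq_along(sp) - 1) * rate / length(x)
    keep <- f >= 0.05 & f <= 1
    60 * f[keep][which.max(sp[keep])]
  }
  expect_equal(s$bpm[1], peak_of(t1$intensity, 50), tolerance = 0.3)
  expect_equal(s$bpm[nrow(s)], peak_of(t2$intensity, 50), tolerance = 0.3)
  expect_lt(s$bpm[1], 13)
  expect_gt(s$bpm[nrow(s)], 23)
})

test_that("regimes partition the positive axis at 12 and 20 BPM", {
  expect_equal(classify_regime(8), "bradypnea")
  expect_equal(classify_regime(15), "normal")
  expect_equal(classify_regime(25), "tachypnea")
  # boundaries are inclusive for normal
  expect_equal(classify_regime(c(11.999, 12, 20, 20.001)),
               c("bradypnea", "normal", "normal", "tachypnea"))
  expect_error(classify_regime(0), class = "gaitsense_invalid_bpm")
  # total on (0, Inf): every positive value maps to exactly one regime
  x <- seq(0.1, 59.9, by = 0.1)
  expect_true(all(classify_regime(x) %in%
                    c("bradypnea", "normal", "tachypnea")))
})

test_that("condition bins follow the printed bands with nearest-edge gaps", {
  expect_equal(assign_condition_bins(9), 0L)
  expect_equal(assign_condition_bins(15), 2L)
  expect_equal(assign_condition_bins(22), 5L)
  # gap values go to the nearest printed edge
  expect_equal(assign_condition_bins(c(10.4, 10.6, 13.4, 13.6, 16.4, 16.6)),
               c(0L, 1L, 1L, 2L, 2L, 3L))
  # 19 belongs to condition 3, above 19 to condition 5
  expect_equal(assign_condition_bins(c(19, 19.01)), c(3L, 5L))
  expect_error(assign_condition_bins(c(5, -1)),
               class = "gaitsense_invalid_bpm")
})

test_that("silhouette selection finds planted structure", {
  # two well-separated point masses -> k = 2
  set.seed(9)
  two <- c(rnorm(30, 8, 0.2), rnorm(30, 25, 0.2))
  expect_equal(cluster_breathing_rates(two, seed = 1)$k, 2)
  # three planted bands at 5, 15, 30 BPM, SD 0.3 -> k = 3
  set.seed(10)
  three <- c(rnorm(25, 5, 0.3), rnorm(25, 15, 0.3), rnorm(25, 30, 0.3))
  expect_equal(cluster_breathing_rates(three, seed = 1)$k, 3)
  expect_error(cluster_breathing_rates(c(1, 1, 1)),
               class = "gaitsense_too_few_samples")
})

test_that("clustering is deterministic at fixed seed and reports the full curve", {
  s <- simulate_br_samples(145, seed = 3)
  a <- cluster_breathing_rates(s$bpm, seed = 5)
  b <- cluster_breathing_rates(s$bpm, seed = 5)
  expect_identical(a$assignments, b$assignments)
  expect_identical(a$silhouette_by_k, b$silhouette_by_k)
  expect_equal(as.integer(names(a$silhouette_by_k)), 2:20)
  expect_true(all(a$silhouette_by_k >= -1 & a$silhouette_by_k <= 1))
  expect_true(all(a$assignments >= 0 & a$assignments < a$k))
})
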