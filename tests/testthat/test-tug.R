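test_that("label smoothing is identity at kernel 0 and removes isolated stray labels", {
  s <- make_labels(c(1, 1, 1, 4, 1, 1, 1), dt = 0.1)
  expect_identical(smooth_labels(s, 0), s)
  sm <- smooth_labels(s, 0.5)
  expect_equal(sm$phase, rep(1L, 7))
  # any input yields a valid label sequence of equal length
  alt <- make_labels(rep(c(2, 3), 10), dt = 0.1)
  out <- smooth_labels(alt, 0.5)
  expect_equal(nrow(out), nrow(alt))
  expect_true(all(out$phase %in% 0:6))
})

test_that("interval extraction follows the first/last classification rule", {
  # class 1 first detected at 0.2 s, last at 1.2 s -> interval 1.0 s
  phases <- c(0, 0, rep(1, 11), rep(2, 5))
  s <- make_labels(phases, dt = 0.1)
  iv <- suppressWarnings(extract_phase_intervals(s))
  r1 <- iv$intervals[iv$intervals$class == 1, ]
  expect_equal(r1$first_detect, 0.2)
  expect_equal(r1$last_detect, 1.2)
  expect_equal(r1$duration, 1.0)
})

test_that("absent classes yield zero duration and a flag, and totals add up", {
  phases <- c(0, 1, 1, 2, 2, 3, 4, 4, 6, 6)  # class 5 never predicted
  s <- make_labels(phases, dt = 0.1)
  expect_warning(iv <- extract_phase_intervals(s), "never detected")
  r5 <- iv$intervals[iv$intervals$class == 5, ]
  expect_true(r5$absent)
  expect_equal(r5$duration, 0)
  expect_equal(iv$total_time, sum(iv$intervals$duration))
})

test_that("max acceleration is taken within each phase interval", {
  s <- make_labels(c(0, 1, 1, 1, 2, 2), dt = 0.1)
  am <- data.frame(t = s$t, mag = c(9, 10, 14, 11, 12, 9))
  iv <- suppressWarnings(extract_phase_intervals(s, am))
  expect_equal(iv$intervals$max_accel[iv$intervals$class == 1], 14)
  expect_equal(iv$intervals$max_accel[iv$intervals$class == 2], 12)
})

test_that("label resampling onto the sensor grid removes the half-step bias", {
  trial <- simulate_tug_trial(subject_profile(), seed = 21)
  f <- window_features(trial$imu)
  grid_labels <- phase_label_series(f$t_center,
                                    labels_at(trial$labels, f$t_center))
  up <- resample_labels(grid_labels, trial$imu$t)
  iv <- extract_phase_intervals(up)
  expect_lt(abs(iv$total_time - trial$truth$total_time), 0.3)
})

test_that("fall-risk categories follow the conventional thresholds", {
  expect_equal(classify_fall_risk(10.96)$category, "moderate")
  expect_equal(classify_fall_risk(9.99)$category, "low")
  expect_equal(classify_fall_risk(10.0)$category, "moderate")
  expect_equal(classify_fall_risk(19.99)$category, "moderate")
  expect_equal(classify_fall_risk(20.0)$category, "high")
  expect_equal(classify_fall_risk(25)$category, "high")
  expect_error(classify_fall_risk(0), class = "gaitsense_invalid_time")
  expect_error(classify_fall_risk(-3), class = "gaitsense_invalid_time")
  # rule text is versioned into every result
  fr <- classify_fall_risk(12)
  expect_match(fr$rule_version, "conventional")
  expect_match(fr$rule_text, "moderate")
})

test_that("fall risk is non-decreasing in total time", {
  lv <- c(low = 1, moderate = 2, high = 3)
  times <- seq(1, 40, by = 0.5)
  cats <- lv[vapply(times, function(x) classify_fall_risk(x)$category,
                    character(1))]
  expect_true(all(diff(cats) >= 0))
})

test_that("protocol comparison computes rounded pairwise percent differences", {
  cp <- compare_protocols(list(motor = 12.01, cognitive = 11.63))
  d <- cp$pairs$percent_diff[cp$pairs$a == "motor"]
  expect_equal(d, 3)
  same <- compare_protocols(list(a = 10, b = 10))
  expect_true(all(same$pairs$percent_diff == 0))
  dbl <- compare_protocols(list(a = 20, b = 10))
  expect_equal(dbl$pairs$percent_diff[dbl$pairs$a == "a"], 100)
  expect_error(compare_protocols(list(a = 10)),
               class = "gaitsense_missing_protocol")
})

test_that("the phase classifier trains, predicts and is seed-deterministic", {
  set.seed(5)
  profiles <- random_profiles(8, seed = 5)
  trials <- lapply(profiles, simulate_tug_trial)
  feats <- lapply(trials, function(tr)
    window_features(tr$imu, include_timestamp = TRUE))
  labs <- unlist(lapply(seq_along(trials), function(i)
    labels_at(trials[[i]]$labels, feats[[i]]$t_center)))
  all_feats <- do.call(rbind, feats)

  cfg <- classifier_config(seed = 7)
  m1 <- train_phase_classifier(all_feats, labs, cfg)
  m2 <- train_phase_classifier(all_feats, labs, cfg)
  expect_identical(m1$confusion$matrix, m2$confusion$matrix)
  expect_gt(m1$holdout_accuracy, 0.9)
  expect_true(all(m1$cv_accuracy > 0.8))

  # prediction on training-distribution features is mostly ordered 0 -> 6
  pred <- predict_phases(m1, feats[[1]])
  truth <- labels_at(trials[[1]]$labels, feats[[1]]$t_center)
  expect_gt(mean(pred$phase == truth), 0.9)

  # single window and empty input
  one <- predict_phases(m1, feats[[1]][5, , drop = FALSE])
  expect_equal(nrow(one), 1)
  empty <- predict_phases(m1, feats[[1]][0, , drop = FALSE])
  expect_equal(nrow(empty), 0)

  # schema mismatch is an error
  bad <- feats[[1]][, -3]
  expect_error(predict_phases(m1, bad), class = "gaitsense_schema_mismatch")

  # a missing class is an error
  keep <- labs != 5
  expect_error(train_phase_classifier(all_feats[keep, ], labs[keep], cfg),
               class = "gaitsense_missing_class")
})
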