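test_that("classification applies the threshold with the boundary counting as good", {
  expect_true(classify_step(-102, -90))
  expect_false(classify_step(-48, -90))
  expect_true(classify_step(-90, -90))
  expect_identical(classify_step(c(-102, -48, -90)), c(TRUE, FALSE, TRUE))
  expect_error(classify_step(-100, 90), class = "gait_config_error")
})

test_that("an all-zero or empty trace yields no events", {
  expect_equal(nrow(detect_heel_strikes(sagittal_trace(rep(0, 500), 100))), 0)
  expect_equal(nrow(detect_heel_strikes(sagittal_trace(numeric(0), 100))), 0)
})

test_that("the smoothing filter must be realizable at the trace rate", {
  tr <- sagittal_trace(rep(0, 100), 25)
  expect_error(detect_heel_strikes(tr, detection_config(smoothing_cutoff = 15)),
               class = "gait_config_error")
})

test_that("a noise-free single stride is found with its peak within 1%", {
  for (peak in c(-300, -48, -150)) {
    w <- stride_waveform(peak, 1.2, 100)
    ev <- detect_heel_strikes(sagittal_trace(as.numeric(w), 100))
    expect_equal(nrow(ev), 1)
    expect_lt(abs(ev$peak_av - peak), 0.01 * abs(peak))
  }
})

test_that("noise-free sessions are recovered exactly: count, timing, classification", {
  for (i in 1:25) {
    sim <- simulate_session(random_profile(i, walk_range = c(30, 90)))
    tr <- extract_sagittal(sim$series)
    ev <- detect_heel_strikes(tr)
    expect_equal(nrow(ev), length(sim$truth$heel_strike_times))
    expect_lt(max(abs(ev$t - sim$truth$heel_strike_times)), 0.030)
    # classification can only disagree for peaks inside the 1% measurement
    # band around the threshold (a true boundary case, not a detector fault)
    flipped <- ev$good != sim$truth$is_good
    expect_true(all(abs(sim$truth$true_peak_av[flipped] - (-90)) <= 1))
  }
})

test_that("good-step proportion is recovered within 2 points under noise", {
  for (pg in c(0, 0.25, 0.5, 0.8, 1)) {
    sim <- simulate_session(separated_profile(pg, seed = 40 + round(100 * pg),
                                              noise_sd = 10))
    ev <- detect_heel_strikes(extract_sagittal(sim$series))
    truth_pct <- 100 * mean(sim$truth$is_good)
    est_pct <- 100 * mean(ev$good)
    expect_lt(abs(est_pct - truth_pct), 2)
    if (pg %in% c(0, 1)) expect_equal(est_pct, truth_pct)
  }
})

test_that("making the threshold more negative never adds good steps", {
  sim <- simulate_session(gait_profile(p_good = 0.6, noise_sd = 5,
                                       bout_plan = list(c(60, 0)), seed = 55))
  tr <- extract_sagittal(sim$series)
  counts <- vapply(seq(-30, -300, by = -15), function(th) {
    sum(detect_heel_strikes(tr, detection_config(threshold_av = th))$good)
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("detected events always satisfy the step-event invariants", {
  cfg <- detection_config()
  for (i in 1:20) {
    set.seed(200 + i)
    # arbitrary band-limited junk, not necessarily gait
    x <- cumsum(rnorm(2000, 0, 30)); x <- x - mean(x)
    ev <- detect_heel_strikes(sagittal_trace(x, 100), cfg)
    if (nrow(ev) > 1) expect_true(all(diff(ev$t) >= cfg$refractory))
    expect_true(all(ev$peak_av < 0))
    expect_identical(ev$good, ev$peak_av <= cfg$threshold_av)
  }
})

test_that("bout segmentation matches the brute-force gap-scan oracle", {
  for (i in 1:60) {
    set.seed(300 + i)
    n <- sample(2:40, 1)
    t <- sort(cumsum(runif(n, 0.4, 20)))
    ev <- data.frame(t = t, peak_av = -100, good = TRUE)
    bouts <- segment_bouts(ev, gap_limit = 10)
    oracle <- brute_force_bouts(t, 10)
    expect_equal(nrow(bouts), length(oracle))
    for (k in seq_along(oracle)) {
      expect_equal(bouts$first_step[k], min(oracle[[k]]))
      expect_equal(bouts$last_step[k], max(oracle[[k]]))
    }
  }
})

test_that("bout durations and splits follow the gap limit", {
  # 12 min of continuous stepping -> one bout of about 12 min
  t1 <- seq(0, 720, by = 0.6)
  b1 <- segment_bouts(data.frame(t = t1, peak_av = -100, good = TRUE), 10)
  expect_equal(nrow(b1), 1)
  expect_equal(b1$end - b1$start, 720.6, tolerance = 0.01)
  # two 6-min walks separated by a 30 s rest -> two bouts
  t2 <- c(seq(0, 360, by = 0.6), seq(390, 750, by = 0.6))
  b2 <- segment_bouts(data.frame(t = t2, peak_av = -100, good = TRUE), 10)
  expect_equal(nrow(b2), 2)
  # empty input -> empty result
  expect_equal(nrow(segment_bouts(data.frame(t = numeric(0),
                                             peak_av = numeric(0),
                                             good = logical(0)), 10)), 0)
})
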