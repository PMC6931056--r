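test_that("coefficient of variation matches hand-computed values and is scale-invariant", {
  expect_equal(coefficient_of_variation(c(-100, -100, -100)), 0)
  expect_equal(coefficient_of_variation(c(-90, -110)), 14.14, tolerance = 1e-3)
  v <- c(-80, -120, -95, -140)
  expect_equal(coefficient_of_variation(2 * v), coefficient_of_variation(v))
  expect_error(coefficient_of_variation(-100), class = "gait_stat_error")
  expect_error(coefficient_of_variation(c(-1, 1)), class = "gait_stat_error")
})

test_that("metrics compute proportion, cadence and AV statistics as defined", {
  t <- seq(0.25, by = 0.5, length.out = 120)          # 120 steps in ~60 s
  ev <- data.frame(t = t, peak_av = rep(c(-120, -60), 60),
                   good = rep(c(TRUE, FALSE), 60))
  bouts <- data.frame(start = 0, end = 60, first_step = 1L, last_step = 120L,
                      n_steps = 120L)
  m <- compute_metrics(ev, bouts)
  expect_equal(m$pct_good, 50)
  expect_equal(m$cadence, 120)
  expect_equal(m$total_walk_time, 60)
  expect_equal(m$av_mean, -90)
  expect_equal(m$av_sd, stats::sd(ev$peak_av))
  expect_equal(m$av_cv, 100 * stats::sd(ev$peak_av) / 90)
  expect_false(m$empty_session)

  ev8 <- data.frame(t = seq(1, 10), peak_av = rep(-100, 10),
                    good = c(rep(TRUE, 8), FALSE, FALSE))
  m8 <- compute_metrics(ev8, data.frame(start = 0, end = 11, first_step = 1L,
                                        last_step = 10L, n_steps = 10L))
  expect_equal(m8$pct_good, 80)
})

test_that("an empty session is flagged rather than divided by zero", {
  ev <- data.frame(t = numeric(0), peak_av = numeric(0), good = logical(0))
  m <- compute_metrics(ev, segment_bouts(ev))
  expect_true(m$empty_session)
  expect_equal(m$pct_good, 0)
  expect_equal(m$cadence, 0)
  expect_true(is.na(m$av_mean))
})

test_that("steps outside every bout are a consistency error", {
  ev <- data.frame(t = c(1, 50), peak_av = c(-100, -100), good = c(TRUE, TRUE))
  bouts <- data.frame(start = 0, end = 10, first_step = 1L, last_step = 1L,
                      n_steps = 1L)
  expect_error(compute_metrics(ev, bouts), class = "gait_validation_error")
})

test_that("recovered AV mean and CV track the generating profile", {
  p <- gait_profile(cadence = 105, av_mean = -150, av_sd = 30, p_good = 1,
                    noise_sd = 5, bout_plan = list(c(300, 0)), seed = 71)
  sim <- simulate_session(p)
  ev <- detect_heel_strikes(extract_sagittal(sim$series))
  m <- compute_metrics(ev, segment_bouts(ev))
  expect_gte(m$n_steps, 450)
  expect_lt(abs(m$av_mean - (-150)), 4)
  expect_lt(abs(m$av_cv - 20), 2)
})

test_that("CV of ground-truth peaks converges to the profile CV at large n", {
  p <- gait_profile(cadence = 110, av_mean = -180, av_sd = 36, p_good = 1,
                    noise_sd = 0, bout_plan = list(c(560, 0)), seed = 72)
  sim <- simulate_session(p)
  expect_gte(length(sim$truth$true_peak_av), 1000)
  expect_lt(abs(coefficient_of_variation(sim$truth$true_peak_av) - 20), 1.5)
})

test_that("the 10% rule flags improvements in the improving direction only", {
  mk <- function(pct_good, cadence, av_mean, av_cv)
    structure(list(pct_good = pct_good, cadence = cadence, av_mean = av_mean,
                   av_cv = av_cv), class = "gait_metrics")
  r <- compare_sessions(mk(43, 95, -97, 39), mk(80, 104, -126, 33))
  p <- r$parameters
  expect_equal(p$pct_change[p$parameter == "pct_good"], 86.05, tolerance = 1e-3)
  expect_true(p$important[p$parameter == "pct_good"])
  expect_true(r$overall_important)

  r2 <- compare_sessions(mk(92, 113, -165, 24), mk(95, 113, -165, 24))
  p2 <- r2$parameters
  expect_equal(p2$pct_change[p2$parameter == "pct_good"], 3.26, tolerance = 1e-2)
  expect_false(any(p2$important))

  same <- compare_sessions(mk(80, 100, -150, 20), mk(80, 100, -150, 20))
  expect_false(same$overall_important)

  # uniformly worse post never earns an "important gain" flag
  worse <- compare_sessions(mk(80, 100, -150, 20), mk(60, 85, -110, 30))
  expect_false(any(worse$parameters$important))
  expect_true(all(worse$parameters$pct_change < 0))
})

test_that("percent changes flip sign when pre and post are swapped", {
  mk <- function(pct_good, cadence, av_mean, av_cv)
    structure(list(pct_good = pct_good, cadence = cadence, av_mean = av_mean,
                   av_cv = av_cv), class = "gait_metrics")
  a <- mk(43, 95, -97, 39); b <- mk(80, 104, -126, 33)
  fwd <- compare_sessions(a, b)$parameters$pct_change
  bwd <- compare_sessions(b, a)$parameters$pct_change
  expect_true(all(sign(fwd) == -sign(bwd)))
})

test_that("zero pre proportion falls back to percentage points and is flagged", {
  mk <- function(pct_good)
    structure(list(pct_good = pct_good, cadence = 70, av_mean = -48,
                   av_cv = 59), class = "gait_metrics")
  r <- compare_sessions(mk(0), mk(29))
  row <- r$parameters[r$parameters$parameter == "pct_good", ]
  expect_equal(row$basis, "percentage_points")
  expect_equal(row$pct_change, 29)
  expect_true(row$important)
})

test_that("guideline check needs cadence >= 100 and a 10-minute bout", {
  mk <- function(cadence, bout_min) {
    ev <- data.frame(t = seq(1, bout_min * 60, by = 60 / cadence),
                     peak_av = -120, good = TRUE)
    m <- compute_metrics(ev, segment_bouts(ev))
    m$cadence <- cadence  # pin the rate; padding perturbs it slightly
    m
  }
  expect_true(meets_guideline(mk(110, 11)))
  expect_false(meets_guideline(mk(95, 12)))
  expect_false(meets_guideline(mk(120, 9.5)))
})

test_that("metric proportion equals the feedback/step event ratio", {
  sim <- simulate_session(separated_profile(0.7, seed = 81, walk = 60))
  tr <- extract_sagittal(sim$series)
  res <- stream_session(tr)
  m <- compute_metrics(res$steps, segment_bouts(res$steps))
  expect_equal(m$pct_good, 100 * nrow(res$feedback) / nrow(res$steps))
})
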