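# Shared fixtures and independent oracles for the test suite.

# A profile whose good and bad morphologies are widely separated around the
# -90 deg/s threshold: good peaks ~N(-150, 15), bad (attenuated x0.4)
# ~N(-60, 6). Used wherever classification recovery is measured.
separated_profile <- function(p_good, seed, walk = 180, rest = 0,
                              noise_sd = 5, cadence = 105) {
  gait_profile(cadence = cadence, av_mean = -150, av_sd = 15,
               p_good = p_good, noise_sd = noise_sd,
               bout_plan = list(c(walk, rest)), seed = seed)
}

random_profile <- function(seed, walk_range = c(60, 300), noise_sd = 0) {
  set.seed(seed)
  gait_profile(
    cadence = runif(1, 70, 120),
    av_mean = runif(1, -260, -100),
    av_sd = runif(1, 5, 30),
    p_good = runif(1),
    noise_sd = noise_sd,
    swing_amp = runif(1, 150, 300),
    bout_plan = list(c(runif(1, walk_range[1], walk_range[2]), 0)),
    seed = seed + 1000L
  )
}

# O(n^2) brute-force bout partition: step k and step j are in the same bout
# iff every consecutive gap on the path between them is < gap_limit.
brute_force_bouts <- function(t, gap_limit) {
  n <- length(t)
  if (n == 0) return(list())
  same <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      lo <- min(i, j); hi <- max(i, j)
      same[i, j] <- lo == hi ||
        all(diff(t[lo:hi]) < gap_limit)
    }
  }
  groups <- list()
  assigned <- rep(FALSE, n)
  for (i in seq_len(n)) {
    if (assigned[i]) next
    g <- which(same[i, ])
    groups[[length(groups) + 1]] <- g
    assigned[g] <- TRUE
  }
  groups
}

# run a full trace through the streaming detector in one go
stream_session <- function(trace, config = detection_config(),
                           chunks = 1L) {
  st <- feedback_stream(config, trace$sample_rate)
  t <- trace$t0 + (seq_len(trace$n_samples) - 1) / trace$sample_rate
  idx <- split(seq_len(trace$n_samples),
               ceiling(seq_len(trace$n_samples) / ceiling(trace$n_samples / chunks)))
  fb <- list()
  for (part in idx) fb[[length(fb) + 1]] <- push_samples(st, t[part], trace$av[part])
  fb[[length(fb) + 1]] <- finalize_stream(st)
  list(feedback = do.call(rbind, fb), steps = stream_steps(st))
}
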