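# Shared fixtures, built in code.

# A noise-only epoch on the canonical grid (band-limited background, no
# reflex activity), already band-pass filtered.
noise_epoch <- function(seed = 1, sd = 5, participant_id = "P01",
                        site = "FS", trial_index = 1L) {
  ep <- nwreflex:::with_seed(seed, {
    nz <- nwreflex:::bandlimited_noise_pair(3501, 1000, sd)
    emg_epoch(participant_id, trial_index, site,
              samples_TA = nz$a, samples_SO = nz$b)
  })
  preprocess_epochs(list(ep))[[1]]
}

# Epoch with a burst planted on the TA channel at a known latency, in
# seeded noise; returns the filtered epoch.
planted_epoch <- function(seed = 1, latency_ms = 200, duration_ms = 150,
                          amplitude_uV = 80, n_phases = 8, noise_sd = 5,
                          u = NULL, site = "FS") {
  ep <- nwreflex:::with_seed(seed, {
    nz <- nwreflex:::bandlimited_noise_pair(3501, 1000, noise_sd)
    b <- simulate_burst(latency_ms, duration_ms, amplitude_uV, n_phases,
                        u = u)
    emg_epoch("P01", 1L, site, samples_TA = nz$a + b, samples_SO = nz$b)
  })
  preprocess_epochs(list(ep))[[1]]
}

# Small cohort configuration for pipeline tests.
small_config <- function(seed = 7, n_sci = 3, n_ndc = 2, n_trials = 8,
                         sites = c("FS", "FH")) {
  run_config(seed = seed, n_trials = n_trials, sites = sites,
             clinical = clinical_sim_params(n_sci = n_sci, n_ndc = n_ndc))
}

# Independent brute-force oracles -------------------------------------------

# Fisher two-sided p by full enumeration over the conditional distribution,
# using only choose().
oracle_fisher_two_sided <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  supp <- max(0, k - n):min(k, m)
  pr <- vapply(supp, function(i) {
    choose(m, i) * choose(n, k - i) / choose(m + n, k)
  }, 0)
  p_obs <- choose(m, a) * choose(n, k - a) / choose(m + n, k)
  sum(pr[pr <= p_obs * (1 + 1e-7)])
}

# Kendall tau-b by explicit O(n^2) pair counting.
oracle_tau_b <- function(x, y) {
  n <- length(x)
  C <- D <- tx <- ty <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    dx <- x[j] - x[i]; dy <- y[j] - y[i]
    if (dx == 0 && dy == 0) next
    if (dx == 0) tx <- tx + 1
    else if (dy == 0) ty <- ty + 1
    else if (sign(dx) == sign(dy)) C <- C + 1
    else D <- D + 1
  }
  n0 <- n * (n - 1) / 2
  tiex <- table(x); tiey <- table(y)
  (C - D) / sqrt((n0 - sum(tiex * (tiex - 1) / 2)) *
                   (n0 - sum(tiey * (tiey - 1) / 2)))
}

# Riemann AUC of the background-corrected rectified trace over an interval.
oracle_auc <- function(rect, times, onset, offset, mu) {
  dt <- times[2] - times[1]
  s <- 0
  for (i in seq_along(rect)) {
    if (times[i] >= onset && times[i] < offset) {
      v <- rect[i] - mu
      if (v > 0) s <- s + v * dt / 1000
    }
  }
  s
}
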