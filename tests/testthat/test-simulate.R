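# Synthetic cohort generator: determinism, burst contracts, clinical
# structure, conduction-velocity consistency of planted latencies.

test_that("participant simulation is deterministic and respects group invariants", {
  gp <- group_sim_params("SCI")
  cp <- clinical_sim_params()
  a <- simulate_participant(gp, cp, 3, 99)
  b <- simulate_participant(gp, cp, 3, 99)
  expect_identical(a, b)
  expect_equal(a$record$group, "SCI")
  expect_false(is.na(a$record$AIS))
  expect_gt(a$latent$cv_tw2_mps, 0)

  ndc <- simulate_participant(group_sim_params("NDC"), cp, 1, 99)
  expect_true(is.na(ndc$record$AIS))
  expect_true(is.na(ndc$record$NLI))
  expect_true(is.na(ndc$record$TSI_years))
})

test_that("the neuropathic-pain prevalence matches the generating probability", {
  cp <- clinical_sim_params()  # p_cpg = 8/15
  draws <- vapply(1:4000, function(i) {
    simulate_participant(group_sim_params("SCI"), cp, i, 5)$record$CPG_neuropathic
  }, NA)
  p_hat <- mean(draws)
  se <- sqrt(cp$p_cpg * (1 - cp$p_cpg) / length(draws))
  expect_lt(abs(p_hat - cp$p_cpg), 3 * se)
})

test_that("the clinical generator reproduces the inverse pain-spasticity association", {
  cp <- clinical_sim_params()
  recs <- do.call(rbind, lapply(1:2000, function(i) {
    simulate_participant(group_sim_params("SCI"), cp, i, 11)$record
  }))
  flags <- classify_clinical(recs)
  p_sp_pain <- mean(flags$spasticity_relevant[recs$CPG_neuropathic])
  p_sp_nopain <- mean(flags$spasticity_relevant[!recs$CPG_neuropathic])
  # logistic defaults target 2/8 = 0.25 and 6/7 = 0.857
  expect_lt(abs(p_sp_pain - 0.25), 3 * sqrt(0.25 * 0.75 / sum(recs$CPG_neuropathic)))
  expect_lt(abs(p_sp_nopain - 6 / 7),
            3 * sqrt((6 / 7) * (1 / 7) / sum(!recs$CPG_neuropathic)))
})

test_that("simulated bursts satisfy the polyphasic waveform contract", {
  for (seed in 1:10) {
    out <- nwreflex:::with_seed(seed, {
      np <- sample(3:8, 1)
      A <- runif(1, 20, 500)
      dur <- runif(1, np * 12, np * 25)
      lat <- runif(1, 100, 2000)
      b <- simulate_burst(lat, dur, A, np)
      list(b = b, np = np, A = A, dur = dur, lat = lat)
    })
    b <- out$b
    tt <- -500 + 0:3500
    # peak within 10% of the nominal amplitude
    expect_gte(max(abs(b)), 0.9 * out$A)
    expect_lte(max(abs(b)), 1.1 * out$A)
    # support inside [latency, latency + duration)
    expect_true(all(b[tt < out$lat | tt >= out$lat + out$dur] == 0))
    # at least n_phases - 1 sign changes between qualifying excursions
    nz <- b[tt >= out$lat & tt < out$lat + out$dur]
    s <- sign(nz); s <- s[s != 0]
    expect_gte(sum(diff(s) != 0), out$np - 1)
  }
  expect_error(simulate_burst(100, 3, 10, 5), "shorter")
  expect_error(simulate_burst(100, 50, 10, 2), "at least 3")
})

test_that("planted latencies are conduction-velocity-consistent across sites", {
  gp <- group_sim_params("SCI",
                         p_respond_tw1 = c(FS = 0, FD = 0, FH = 0),
                         p_respond_tw2 = c(FS = 1, FD = 1, FH = 1),
                         responder_prob_tw1 = 0, responder_prob_tw2 = 1,
                         latency_jitter_ms = 0, cv_jitter_frac = 0,
                         coactivation_prob = 0, ta_only_prob = 1)
  p <- simulate_participant(gp, clinical_sim_params(), 2, 31)
  lat <- p$latent
  lat$propensity$tw2[] <- 1
  lat$cv_tw2_mps <- 1.0
  lat$distance_FS_FH_m <- 0.40
  fs <- attr(simulate_trial(lat, gp, "FS", 1, "X", seed = 1), "planted")
  fh <- attr(simulate_trial(lat, gp, "FH", 1, "X", seed = 1), "planted")
  expect_equal(fs$latency_ms[fs$tw == "TW2"] - fh$latency_ms[fh$tw == "TW2"],
               400)
})

test_that("co-activated trials plant both muscles within 50 ms", {
  gp <- group_sim_params("SCI", coactivation_prob = 1,
                         p_respond_tw2 = c(FS = 1, FD = 1, FH = 1),
                         responder_prob_tw2 = 1)
  p <- simulate_participant(gp, clinical_sim_params(), 1, 8)
  p$latent$propensity$tw2[] <- 1
  for (tr in 1:5) {
    pl <- attr(simulate_trial(p$latent, gp, "FS", tr, "X", seed = 4), "planted")
    tw2 <- pl[pl$tw == "TW2", ]
    expect_setequal(tw2$muscle, c("TA", "SO"))
    expect_lte(abs(diff(tw2$latency_ms)), 50)
  }
})

test_that("noise-only trials contain no reflex events", {
  gp <- group_sim_params("NDC", p_respond_tw2 = c(FS = 0, FD = 0, FH = 0),
                         responder_prob_tw2 = 0)
  p <- simulate_participant(gp, clinical_sim_params(), 1, 17)
  eps <- lapply(1:25, function(tr) {
    simulate_trial(p$latent, gp, "FS", tr, "N01", seed = 17)
  })
  expect_true(all(vapply(eps, function(e) nrow(attr(e, "planted")) == 0, NA)))
  det <- detect_epochs(preprocess_epochs(eps))
  expect_equal(nrow(det$events), 0)
})

test_that("cohort simulation writes the expected artifact set deterministically", {
  cfg <- run_config(seed = 5, n_trials = 5,
                    clinical = clinical_sim_params(n_sci = 2, n_ndc = 2))
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  res1 <- simulate_cohort(cfg, dir = d1, keep_epochs = FALSE)
  res2 <- simulate_cohort(cfg, dir = d2, keep_epochs = FALSE)
  # 4 participants x 3 sites epoch files + clinical + manifest
  expect_length(list.files(d1, pattern = "^epochs_"), 12)
  expect_equal(nrow(res1$manifest), 4 * 3 * 5)
  # byte-identical under the same seed and configuration
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = paste("file", f))
  }
  # artifacts parse back with the package's own readers
  cl <- read_clinical_table(file.path(d1, "clinical.tsv"))
  expect_equal(nrow(cl), 4)
  man <- read_trial_manifest(file.path(d1, "manifest.tsv"))
  expect_true(all(man$ISI_ms %in% c(6000, 7000, 9000)))
  expect_true(all(man$energy_mJ[man$site == "FS"] %in% c(600, 660)))
  expect_true(all(man$energy_mJ[man$site != "FS"] %in% c(540, 600)))
  eps <- read_epochs(list.files(d1, pattern = "^epochs_", full.names = TRUE)[1])
  expect_length(eps[[1]]$samples_TA, 3501)
})

test_that("analgesic participants rate every stimulus at zero", {
  gp <- group_sim_params("SCI", analgesia_prob = 1)
  p <- simulate_participant(gp, clinical_sim_params(), 4, 23)
  expect_true(p$latent$analgesic)
  ratings <- vapply(1:10, function(tr) {
    simulate_trial(p$latent, gp, "FD", tr, "X", seed = 23)$pain_rating
  }, 0)
  expect_true(all(ratings == 0))
})
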