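# Threshold-based reflex detection and burst characterization.

times_canonical <- -500 + 0:3500

test_that("background statistics are the mean/SD of the rectified pre-stimulus window", {
  ep <- emg_epoch("P01", 1L, "FS", samples_TA = rep(-3, 3501),
                  samples_SO = rep(0, 3501))
  bg <- estimate_background(ep, "TA")
  expect_equal(bg$mu_bg_uV, 3)
  expect_equal(bg$sigma_bg_uV, 0)
  expect_equal(bg$window_ms, c(-500, 0))

  # folded-normal check: rectified white noise of SD sigma has
  # SD sigma * sqrt(1 - 2/pi)
  sigma <- 7
  ep2 <- nwreflex:::with_seed(5, {
    emg_epoch("P01", 1L, "FS", samples_TA = rnorm(3501, sd = sigma),
              samples_SO = rnorm(3501))
  })
  bg2 <- estimate_background(ep2, "TA")
  expect_equal(bg2$sigma_bg_uV, sigma * sqrt(1 - 2 / pi), tolerance = 0.15)
  expect_equal(bg2$mu_bg_uV, sigma * sqrt(2 / pi), tolerance = 0.15)

  cfg_bad <- detection_config(noise_window_ms = c(-500, -499.9))
  short <- emg_epoch("P01", 1L, "FS", t0_offset_ms = -100,
                     samples_TA = rnorm(3101), samples_SO = rnorm(3101))
  expect_error(estimate_background(short, "TA", cfg_bad), "no samples")
})

test_that("burst detection finds planted bursts at the planted onset", {
  # all-zero trace with nonzero background never crosses threshold
  none <- detect_bursts(rep(0, 3501), times_canonical,
                        list(mu_bg_uV = 0.8, sigma_bg_uV = 1))
  expect_equal(nrow(none), 0)

  # rectangular burst of 10 background SDs at 200-300 ms in seeded noise
  rect <- nwreflex:::with_seed(3, abs(bandlimited_noise(3501, 1000, 5)))
  bg <- list(mu_bg_uV = mean(rect[1:500]), sigma_bg_uV = sd(rect[1:500]))
  sel <- times_canonical >= 200 & times_canonical < 300
  rect[sel] <- 10 * bg$sigma_bg_uV
  bursts <- detect_bursts(rect, times_canonical, bg)
  expect_equal(nrow(bursts), 1)
  expect_gte(bursts$onset_ms, 195)
  expect_lte(bursts$onset_ms, 210)
  expect_gte(bursts$offset_ms, 300)
})

test_that("bursts closer than the merge gap are merged", {
  rect <- rep(0, 3501)
  bg <- list(mu_bg_uV = 0, sigma_bg_uV = 1)
  rect[times_canonical >= 200 & times_canonical < 240] <- 10
  rect[times_canonical >= 260 & times_canonical < 300] <- 10
  bursts <- detect_bursts(rect, times_canonical, bg)
  expect_equal(nrow(bursts), 1)
  expect_equal(bursts$onset_ms, 200)
  expect_gte(bursts$offset_ms, 300)
})

test_that("crossings shorter than min_burst_ms never open a burst", {
  rect <- rep(0, 3501)
  rect[times_canonical >= 500 & times_canonical < 505] <- 10  # 5 ms only
  bursts <- detect_bursts(rect, times_canonical,
                          list(mu_bg_uV = 0, sigma_bg_uV = 1))
  expect_equal(nrow(bursts), 0)
})

test_that("phase counting operationalizes the polyphasic criterion", {
  tt <- times_canonical
  # pure positive half-wave -> 1 phase
  half <- numeric(3501)
  sel <- tt >= 100 & tt < 200
  half[sel] <- sin(pi * (tt[sel] - 100) / 100)
  expect_equal(count_phases(half, tt, c(100, 200), threshold = 0.5), 1L)
  # one full sine cycle -> 2 phases (one sign change)
  full <- numeric(3501)
  full[sel] <- sin(2 * pi * (tt[sel] - 100) / 100)
  expect_equal(count_phases(full, tt, c(100, 200), threshold = 0.5), 2L)
  # sub-floor excursions do not count
  expect_equal(count_phases(0.1 * full, tt, c(100, 200), threshold = 1), 0L)

  # generator contract: an n-phase burst yields at least n phases when all
  # phase amplitudes clear the floor
  b <- nwreflex:::with_seed(9, simulate_burst(300, 120, 60, 5))
  expect_gte(count_phases(b, tt, c(300, 420), threshold = 30,
                          detection_config(phase_amplitude_fraction = 0.5)),
             5L)
})

test_that("burst characterization integrates the background-corrected rectified trace", {
  rect <- rep(0, 3501)
  rect[times_canonical >= 1000 & times_canonical < 1300] <- 50  # 50 uV, 0.3 s
  ev <- characterize_burst(rect, times_canonical, c(1000, 1300),
                           list(mu_bg_uV = 0, sigma_bg_uV = 1))
  expect_equal(ev$auc_uVs, 15)     # 50 uV * 0.3 s
  expect_equal(ev$peak_uV, 50)
  expect_equal(ev$onset_ms, 1000)

  # equality with the brute-force Riemann oracle on identical inputs
  ep <- planted_epoch(seed = 21, latency_ms = 1200, duration_ms = 200,
                      amplitude_uV = 120)
  rect2 <- rectify(ep$samples_TA)
  bg <- estimate_background(ep, "TA")
  ev2 <- characterize_burst(rect2, times_canonical, c(1200, 1400), bg)
  expect_equal(ev2$auc_uVs,
               oracle_auc(rect2, times_canonical, 1200, 1400, bg$mu_bg_uV),
               tolerance = 1e-9)

  # noise-free template: AUC close to the template integral
  b <- nwreflex:::with_seed(4, simulate_burst(1200, 200, 120, 10))
  ev3 <- characterize_burst(abs(b), times_canonical, c(1200, 1400),
                            list(mu_bg_uV = 0, sigma_bg_uV = 0))
  expect_equal(ev3$auc_uVs, sum(abs(b)) / 1000, tolerance = 1e-12)
})

test_that("rectangular-envelope bursts integrate to amplitude x duration", {
  b <- simulate_burst(500, 120, 80, 4, envelope = "rect")
  integral <- sum(abs(b)) / 1000
  expect_equal(integral, 80 * 0.120, tolerance = 0.1)
})

test_that("time-window assignment follows the early/late dichotomy", {
  # latencies characteristic of A-delta (early) and C-fiber (late) reflexes
  expect_equal(assign_window(187), "TW1")
  expect_equal(assign_window(1460), "TW2")
  expect_equal(assign_window(800), "intermediate")
  expect_equal(assign_window(c(90, 599.9, 600, 999.9, 1000, 3000, 3000.1, 10)),
               c("TW1", "TW1", "intermediate", "intermediate", "TW2", "TW2",
                 "none", "none"))
})

test_that("detect_trial runs both channels, flags artifacts and co-activation", {
  # noise-only epoch: valid, and (at this seed) no events
  det0 <- detect_trial(noise_epoch(seed = 2))
  expect_true(det0$valid)
  expect_equal(nrow(det0$events), 0)

  # TA and SO bursts 20 ms apart in the late window -> co-activation
  ep <- nwreflex:::with_seed(13, {
    nz <- nwreflex:::bandlimited_noise_pair(3501, 1000, 5)
    emg_epoch("P01", 1L, "FS",
              samples_TA = nz$a + simulate_burst(1500, 150, 200, 8),
              samples_SO = nz$b + simulate_burst(1520, 150, 200, 8))
  })
  det <- detect_trial(preprocess_epochs(list(ep))[[1]])
  expect_true("TW2" %in% det$coactivated_tw)
  expect_setequal(unique(det$events$muscle), c("TA", "SO"))
  expect_true(all(det$events$coactivated[det$events$window == "TW2"]))

  # background SD above the artifact cap invalidates the trial
  noisy <- nwreflex:::with_seed(3, {
    nz <- nwreflex:::bandlimited_noise_pair(3501, 1000, 100)
    emg_epoch("P01", 1L, "FS", samples_TA = nz$a, samples_SO = nz$b)
  })
  detn <- detect_trial(preprocess_epochs(list(noisy))[[1]])
  expect_false(detn$valid)
  expect_equal(nrow(detn$events), 0)
})

test_that("raising the threshold multiplier never increases the burst count", {
  for (seed in 1:5) {
    ep <- planted_epoch(seed = seed, latency_ms = 400, amplitude_uV = 40)
    rect <- rectify(ep$samples_TA)
    bg <- estimate_background(ep, "TA")
    counts <- vapply(c(1, 1.5, 2, 3, 4), function(k) {
      nrow(detect_bursts(rect, times_canonical, bg,
                         detection_config(threshold_sd_multiplier = k)))
    }, 0L)
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("detection is translation-consistent", {
  for (seed in 1:5) {
    on <- vapply(c(0, 100), function(shift) {
      ep <- planted_epoch(seed = seed, latency_ms = 600 + shift,
                          amplitude_uV = 100)
      det <- detect_trial(ep)
      min(det$events$onset_ms[det$events$muscle == "TA"])
    }, 0)
    expect_equal(on[2] - on[1], 100, tolerance = 2)
  }
})
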