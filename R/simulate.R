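# Seeded synthetic cohort generator.  Emulates the statistical structure the
# analysis assumes: band-limited background EMG, polyphasic reflex bursts in
# an early (A-delta) and late (C-fiber) latency window, site-to-site latency
# shifts consistent with a per-participant conduction velocity, TA/SO
# co-activation in SCI versus TA-dominant responses in NDC, zero-inflated
# per-participant response propensities, and a clinical table with a
# configurable inverse pain-spasticity association.
#
# Reproducibility: one master seed fans out into per-participant and
# per-trial substreams, so changing cohort size or trial count never
# reshuffles previously generated participants.

#' Band-limited Gaussian background noise
#'
#' White Gaussian noise restricted to a frequency band by spectral masking
#' and rescaled to the requested standard deviation.  Used as the
#' surface-EMG background of simulated epochs.
#'
#' @param n Number of samples.
#' @param rate Sampling rate (Hz).
#' @param sd Target standard deviation (microvolts).
#' @param band Pass band in Hz (default 20-450).
#' @return Numeric vector of length `n`.
#' @export
bandlimited_noise <- function(n, rate, sd = 5, band = c(20, 450)) {
  x <- stats::rnorm(n)
  freq <- (seq_len(n) - 1) * rate / n
  freq <- pmin(freq, rate - freq)  # two-sided spectrum
  keep <- freq >= band[1] & freq <= band[2]
  X <- stats::fft(x)
  X[!keep] <- 0
  y <- Re(stats::fft(X, inverse = TRUE)) / n
  s <- stats::sd(y)
  if (s == 0) return(rep(0, n))
  y * (sd / s)
}

# Two independent band-limited noise channels from a single complex FFT
# (real and imaginary parts of a spectrally masked complex white noise are
# independent Gaussian streams).
bandlimited_noise_pair <- function(n, rate, sd = 5, band = c(20, 450)) {
  z <- complex(real = stats::rnorm(n), imaginary = stats::rnorm(n))
  freq <- (seq_len(n) - 1) * rate / n
  freq <- pmin(freq, rate - freq)
  Z <- stats::fft(z)
  Z[!(freq >= band[1] & freq <= band[2])] <- 0
  w <- stats::fft(Z, inverse = TRUE) / n
  a <- Re(w); b <- Im(w)
  sa <- stats::sd(a); sb <- stats::sd(b)
  list(a = if (sa > 0) a * (sd / sa) else a,
       b = if (sb > 0) b * (sd / sb) else b)
}

#' Simulate one polyphasic reflex burst
#'
#' Builds an unrectified burst of `n_phases` alternating-sign excursions
#' on the epoch sample grid, zero outside `[latency, latency + duration)`.
#' Each phase is a half-sine (`envelope = "hann"`) or a rectangular pulse
#' (`envelope = "rect"`).  Per-phase amplitudes are `amplitude * u`, with
#' `u` in `[0.6, 1]` and at least one phase at 1, so the peak equals
#' `amplitude` and every excursion clears half the peak -- the burst is
#' polyphasic by the detector's own criterion.
#'
#' @param latency_ms Burst onset (ms relative to stimulus).
#' @param duration_ms Burst duration (ms).
#' @param amplitude_uV Peak amplitude (microvolts).
#' @param n_phases Number of phases (at least 3).
#' @param rate Sampling rate (Hz).
#' @param t0_offset_ms Time of the first sample.
#' @param n_samples Epoch length in samples.
#' @param envelope `"hann"` or `"rect"`.
#' @param u Optional per-phase amplitude fractions (length `n_phases`).
#' @param polarity Optional per-phase sign vector; the default strictly
#'   alternates, giving `n_phases - 1` sign changes.  The cohort generator
#'   passes a mirrored pattern that additionally cancels the burst's first
#'   moment, minimizing sub-passband content.
#' @return Numeric vector of length `n_samples`.
#' @export
simulate_burst <- function(latency_ms, duration_ms, amplitude_uV, n_phases,
                           rate = 1000, t0_offset_ms = -500,
                           n_samples = 3501,
                           envelope = c("hann", "rect"), u = NULL,
                           polarity = NULL) {
  envelope <- match.arg(envelope)
  n_phases <- as.integer(n_phases)
  if (n_phases < 3) stop("n_phases must be at least 3 (polyphasic burst)")
  dt <- 1000 / rate
  if (duration_ms < n_phases * dt) {
    stop("duration (", duration_ms, " ms) shorter than ", n_phases,
         " phases at ", dt, " ms per sample")
  }
  if (is.null(u)) {
    if (envelope == "rect") {
      u <- rep(1, n_phases)
    } else {
      u <- stats::runif(n_phases, 0.6, 1)
      u[sample.int(n_phases, 1)] <- 1
    }
  }
  stopifnot(length(u) == n_phases)
  if (is.null(polarity)) polarity <- rep_len(c(1, -1), n_phases)
  stopifnot(length(polarity) == n_phases)
  tt <- t0_offset_ms + (seq_len(n_samples) - 1) * dt
  out <- numeric(n_samples)
  sel <- which(tt >= latency_ms & tt < latency_ms + duration_ms)
  if (!length(sel)) return(out)
  dp <- duration_ms / n_phases
  pos <- (tt[sel] - latency_ms) / dp
  k <- pmin(floor(pos), n_phases - 1)         # phase index, 0-based
  frac <- pos - k
  shape <- if (envelope == "hann") sin(pi * frac) else 1
  out[sel] <- amplitude_uV * u[k + 1] * polarity[k + 1] * shape
  out
}

draw_truncnorm <- function(mean, sd, lo, hi) {
  if (sd <= 0) return(min(max(mean, lo), hi))
  for (i in 1:100) {
    x <- stats::rnorm(1, mean, sd)
    if (x >= lo && x <= hi) return(x)
  }
  min(max(mean, lo), hi)
}

clampi <- function(x, lo, hi) as.integer(min(max(round(x), lo), hi))

sim_joint_scores <- function(spastic, n_joints) {
  # Any-joint > 1 rule: spastic participants get 1-3 joints above grade 1.
  mas <- sample(c(0, 0.5, 1), n_joints, replace = TRUE, prob = c(5, 3, 2))
  scat <- sample(c(0, 0.5, 1), n_joints, replace = TRUE, prob = c(5, 3, 2))
  if (spastic) {
    n_hi <- sample.int(3, 1)
    idx <- sample.int(n_joints, n_hi)
    mas[idx] <- sample(c(1.5, 2, 2.5, 3, 3.5), n_hi, replace = TRUE)
    if (stats::runif(1) < 0.5) {
      scat[sample.int(n_joints, 1)] <- sample(c(1.5, 2, 2.5, 3), 1)
    }
  }
  list(MAS = mas, SCAT = scat)
}

sim_clinical_record <- function(group, gp, cp, index) {
  id <- sprintf("%s%02d", group, index)
  age <- sample(18:63, 1)
  sex <- sample(c("M", "F"), 1)
  if (group == "SCI") {
    ais <- sample(c("A", "C", "D"), 1, prob = c(6, 1, 8))
    nli <- sample(c("C2", "C3", "C5", "C6", "T1", "T3", "T4", "T5", "T7", "T8"), 1)
    tsi <- round(min(max(stats::rlnorm(1, log(3), 1.1), 0.9), 35), 1)
    cpg <- stats::runif(1) < cp$p_cpg
    p_spast <- stats::plogis(cp$spasticity_intercept +
                               cp$spasticity_given_pain_logodds * cpg)
    spastic <- stats::runif(1) < p_spast
    js <- sim_joint_scores(spastic, cp$n_joints)
    scipi <- clampi(stats::rnorm(1, if (cpg) 5.2 else 1.8, 1.4), 0, 7)
    nrs <- if (cpg) {
      clampi(stats::rnorm(1, 6.4, 1.3), 0, 10)
    } else {
      sample(0:7, 1, prob = c(8, 4, 3, 2, 1, 1, 0.5, 0.5))
    }
    nocp <- !cpg && nrs > 0
    rec <- data.frame(
      participant_id = id, group = "SCI", age_years = age, sex = sex,
      AIS = ais, NLI = nli, TSI_years = tsi, SCIPI_score = scipi,
      CPG_neuropathic = cpg, NocP = nocp, NRS_spontaneous = nrs,
      MAS_mean = round(mean(js$MAS), 2), SCAT_mean = round(mean(js$SCAT), 2),
      MAS_joints = paste(js$MAS, collapse = ";"),
      SCAT_joints = paste(js$SCAT, collapse = ";"),
      stringsAsFactors = FALSE)
  } else {
    rec <- data.frame(
      participant_id = id, group = "NDC", age_years = age, sex = sex,
      AIS = NA_character_, NLI = NA_character_, TSI_years = NA_real_,
      SCIPI_score = NA_integer_, CPG_neuropathic = NA, NocP = FALSE,
      NRS_spontaneous = 0, MAS_mean = NA_real_, SCAT_mean = NA_real_,
      MAS_joints = "", SCAT_joints = "", stringsAsFactors = FALSE)
  }
  rec$distance_FS_FH_m <- round(min(max(
    stats::rnorm(1, cp$distance_FS_FH_m[["mean"]], cp$distance_FS_FH_m[["sd"]]),
    0.30), 0.55), 3)
  rec$distance_FD_FH_m <- cp$distance_FD_FH_m
  rec
}

sim_latent <- function(record, gp) {
  cv_tw2 <- draw_truncnorm(gp$cv_tw2_mean_mps, gp$cv_tw2_sd_mps, 0.3, 3.5)
  cv_tw1 <- stats::runif(1, gp$cv_tw1_range_mps[1], gp$cv_tw1_range_mps[2])
  prop <- list()
  base <- list()
  stereo <- list()
  bounds <- list(tw1 = c(120, 480), tw2 = c(1050, 2100))
  for (tw in c("tw1", "tw2")) {
    rp <- gp[[paste0("responder_prob_", tw)]]
    responder <- stats::runif(1) < rp
    p_sites <- stats::setNames(numeric(length(NWR_SITES)), NWR_SITES)
    if (responder && rp > 0) {
      for (s in NWR_SITES) {
        mu <- min(0.95, gp[[paste0("p_respond_", tw)]][[s]] / rp)
        k <- gp$propensity_shape
        p_sites[s] <- if (mu > 0) stats::rbeta(1, mu * k, (1 - mu) * k) else 0
      }
    }
    prop[[tw]] <- p_sites
    anchor <- gp[[paste0("latency_anchor_", tw, "_ms")]]
    base[[tw]] <- if (is.na(anchor[["mean"]])) NA_real_ else {
      draw_truncnorm(anchor[["mean"]], anchor[["sd"]],
                     bounds[[tw]][1], bounds[[tw]][2])
    }
    # Waveform stereotype: phases come in pairs of equal amplitude and
    # opposite sign (zero net area), with the polarity of the second half
    # of the pairs flipped and amplitudes mirrored so the burst's first
    # moment also cancels -- this keeps essentially all burst energy
    # inside the 1-450 Hz analysis band and prevents the zero-phase
    # high-pass from smearing a slow rebound around large bursts.  Phase
    # durations mimic motor-unit potential phases (10-16 ms).
    dur <- stats::runif(1, gp$burst_duration_ms[[tw]][1],
                        gp$burst_duration_ms[[tw]][2])
    dp <- stats::runif(1, gp$phase_duration_ms[1], gp$phase_duration_ms[2])
    m <- 2L * max(1L, as.integer(round(dur / dp / 4)))  # pairs, even
    np <- 2L * m
    q <- stats::runif(m / 2, 0.6, 1)
    q[sample.int(max(m / 2, 1), 1)] <- 1
    v <- c(q, rev(q))
    u <- rep(v, each = 2)
    pol <- rep_len(c(1, -1), np)
    flip <- seq(m + 1L, np)
    pol[flip] <- -pol[flip]
    stereo[[tw]] <- list(n_phases = np, duration_ms = dur, u = u,
                         polarity = pol)
  }
  # analgesia: forced for sensorimotor complete injury, otherwise topped up
  # to the configured marginal probability
  forced <- identical(record$AIS, "A")
  p_extra <- if (gp$group == "SCI") {
    p_a <- 0.4  # AIS-A prevalence in the generator
    max(0, (gp$analgesia_prob - p_a) / (1 - p_a))
  } else {
    gp$analgesia_prob
  }
  analgesic <- forced || stats::runif(1) < p_extra
  list(cv_tw1_mps = cv_tw1, cv_tw2_mps = cv_tw2,
       propensity = prop, base_latency_ms = base, stereotype = stereo,
       analgesic = analgesic,
       distance_FS_FH_m = record$distance_FS_FH_m,
       distance_FD_FH_m = record$distance_FD_FH_m)
}

#' Simulate one study participant
#'
#' Draws the clinical record and the latent quantities (per-window
#' conduction velocities, response propensities, base latencies, burst
#' waveform stereotype, analgesia flag) that the trial simulator conditions
#' on.  Deterministic given `(seed, index)`.
#'
#' @param group_params A [group_sim_params()].
#' @param clinical_params A [clinical_sim_params()].
#' @param index Participant index within the group.
#' @param seed Master seed.
#' @return List with `record` (one-row clinical `data.frame`) and `latent`.
#' @export
simulate_participant <- function(group_params,
                                 clinical_params = clinical_sim_params(),
                                 index = 1L, seed = 1L) {
  salt <- if (group_params$group == "SCI") 1L else 2L
  with_seed(nwr_substream_seed(seed, index, salt), {
    record <- sim_clinical_record(group_params$group, group_params,
                                  clinical_params, index)
    latent <- sim_latent(record, group_params)
    list(record = record, latent = latent)
  })
}

site_shift_ms <- function(site, latent, tw, cv_jitter_frac = 0) {
  d <- switch(site, FH = 0, FD = latent$distance_FD_FH_m,
              FS = latent$distance_FS_FH_m)
  if (d == 0) return(0)
  cv <- if (tw == "tw1") latent$cv_tw1_mps else latent$cv_tw2_mps
  if (cv_jitter_frac > 0) {
    cv <- cv * (1 + stats::rnorm(1, 0, cv_jitter_frac))
  }
  1000 * d / cv
}

#' Simulate one stimulus-locked trial
#'
#' Plants 0, 1 or 2 reflex bursts (early and/or late window) into
#' band-limited background noise on both channels.  Late-window latencies
#' at the distal sites are the participant's fibula-head base latency plus
#' `distance / conduction velocity`; co-activated trials plant bursts on
#' both muscles with onset difference at most 50 ms.
#'
#' @param latent Latent participant state from [simulate_participant()].
#' @param group_params A [group_sim_params()].
#' @param site Stimulation site.
#' @param trial_index Trial number.
#' @param participant_id Identifier copied into the epoch.
#' @param seed Master seed (per-trial substream is derived internally).
#' @param rate,t0_offset_ms,post_ms Epoch geometry.
#' @return An `nwr_epoch`; attribute `"planted"` holds the ground-truth
#'   planted events, attribute `"ISI_ms"` the inter-stimulus interval.
#' @export
simulate_trial <- function(latent, group_params, site = "FS",
                           trial_index = 1L, participant_id = "P01",
                           seed = 1L, rate = 1000, t0_offset_ms = -500,
                           post_ms = 3000) {
  gp <- group_params
  site_idx <- match(site, NWR_SITES)
  tseed <- nwr_substream_seed(seed, site_idx * 100000 + trial_index, 3L)
  with_seed(tseed, {
    n <- as.integer(round((post_ms - t0_offset_ms) * rate / 1000)) + 1L
    nz <- bandlimited_noise_pair(n, rate, gp$noise_sd_uV)
    ta <- nz$a
    so <- nz$b
    energy <- if (site == "FS") sample(c(600, 660), 1) else sample(c(540, 600), 1)
    isi <- sample(c(6000, 7000, 9000), 1)
    planted <- list()
    for (tw in c("tw1", "tw2")) {
      p <- latent$propensity[[tw]][[site]]
      if (is.na(p) || stats::runif(1) >= p) next
      if (is.na(latent$base_latency_ms[[tw]])) next
      st <- latent$stereotype[[tw]]
      lat <- latent$base_latency_ms[[tw]] +
        site_shift_ms(site, latent, tw, gp$cv_jitter_frac)
      if (gp$latency_jitter_ms > 0) {
        lat <- lat + stats::rnorm(1, 0, gp$latency_jitter_ms)
      }
      amp <- gp$burst_amplitude_uV[[tw]]
      if (gp$amplitude_sdlog > 0) {
        amp <- amp * stats::rlnorm(1, 0, gp$amplitude_sdlog)
      }
      coact <- stats::runif(1) < gp$coactivation_prob
      muscles <- if (coact) {
        c("TA", "SO")
      } else if (stats::runif(1) < gp$ta_only_prob) "TA" else "SO"
      lat_m <- c(TA = lat, SO = lat)
      if (coact) lat_m["SO"] <- lat + stats::runif(1, -30, 30)
      for (m in muscles) {
        burst <- simulate_burst(lat_m[[m]], st$duration_ms, amp, st$n_phases,
                                rate = rate, t0_offset_ms = t0_offset_ms,
                                n_samples = n, u = st$u,
                                polarity = st$polarity)
        if (m == "TA") ta <- ta + burst else so <- so + burst
        planted[[length(planted) + 1L]] <- data.frame(
          tw = toupper(tw), muscle = m, latency_ms = lat_m[[m]],
          amplitude_uV = amp, duration_ms = st$duration_ms,
          coactivated = coact, stringsAsFactors = FALSE)
      }
    }
    rating <- if (latent$analgesic) 0 else {
      min(max(round(stats::rnorm(1, gp$pain_rating_mean, gp$pain_rating_sd)),
              0), 100)
    }
    ep <- emg_epoch(participant_id = participant_id,
                    trial_index = trial_index, site = site,
                    energy_mJ = energy, sampling_rate_Hz = rate,
                    t0_offset_ms = t0_offset_ms,
                    samples_TA = ta, samples_SO = so, pain_rating = rating)
    attr(ep, "planted") <- if (length(planted)) {
      do.call(rbind, planted)
    } else {
      data.frame(tw = character(), muscle = character(),
                 latency_ms = numeric(), amplitude_uV = numeric(),
                 duration_ms = numeric(), coactivated = logical(),
                 stringsAsFactors = FALSE)
    }
    attr(ep, "ISI_ms") <- isi
    ep
  })
}

#' Simulate a full synthetic cohort
#'
#' Generates the clinical table, trial manifest and stimulus-locked EMG
#' epochs for both study groups.  With `dir` given, writes one epoch TSV
#' per participant and site plus `manifest.tsv` and `clinical.tsv`
#' (byte-identical across runs with the same configuration).
#'
#' @param config A [run_config()].
#' @param dir Optional output directory.
#' @param keep_epochs Keep epochs in memory (default `TRUE`; set `FALSE`
#'   for large cohorts written to disk).
#' @return List with `clinical`, `manifest`, `epochs` (possibly `NULL`),
#'   `latents` and `truth` (planted ground-truth event table).
#' @export
simulate_cohort <- function(config = run_config(), dir = NULL,
                            keep_epochs = is.null(dir)) {
  if (!is.null(dir) && !dir.exists(dir)) {
    dir.create(dir, recursive = TRUE)
  }
  clinical <- list()
  manifest <- list()
  epochs <- list()
  truth <- list()
  latents <- list()
  groups <- list(SCI = list(gp = config$sci, n = config$clinical$n_sci),
                 NDC = list(gp = config$ndc, n = config$clinical$n_ndc))
  for (gname in names(groups)) {
    g <- groups[[gname]]
    if (g$n < 1) next
    for (i in seq_len(g$n)) {
      p <- simulate_participant(g$gp, config$clinical, i, config$seed)
      clinical[[length(clinical) + 1L]] <- p$record
      latents[[p$record$participant_id]] <- p$latent
      for (site in config$sites) {
        eps <- lapply(seq_len(config$n_trials), function(tr) {
          simulate_trial(p$latent, g$gp, site, tr, p$record$participant_id,
                         seed = nwr_substream_seed(config$seed, i,
                                                   if (gname == "SCI") 1L else 2L))
        })
        for (ep in eps) {
          manifest[[length(manifest) + 1L]] <- data.frame(
            participant_id = ep$participant_id, site = site,
            trial_index = ep$trial_index, energy_mJ = ep$energy_mJ,
            ISI_ms = attr(ep, "ISI_ms"), pain_rating = ep$pain_rating,
            valid = TRUE, stringsAsFactors = FALSE)
          pl <- attr(ep, "planted")
          if (nrow(pl)) {
            pl$participant_id <- ep$participant_id
            pl$site <- site
            pl$trial_index <- ep$trial_index
            truth[[length(truth) + 1L]] <- pl
          }
        }
        if (!is.null(dir)) {
          write_epochs(eps, file.path(dir, sprintf("epochs_%s_%s.tsv",
                                                   p$record$participant_id,
                                                   site)))
        }
        if (keep_epochs) epochs <- c(epochs, eps)
      }
    }
  }
  clinical <- do.call(rbind, clinical)
  class(clinical) <- c("nwr_clinical", "data.frame")
  manifest <- do.call(rbind, manifest)
  truth <- if (length(truth)) do.call(rbind, truth) else NULL
  if (!is.null(dir)) {
    write_clinical_table(clinical, file.path(dir, "clinical.tsv"))
    write_trial_manifest(manifest, file.path(dir, "manifest.tsv"))
  }
  list(clinical = clinical, manifest = manifest,
       epochs = if (keep_epochs) epochs else NULL,
       latents = latents, truth = truth)
}

#' Simulate the clinical table only
#'
#' Clinical records for both groups without any EMG simulation; used for
#' clinical-statistics calibration at scale.
#'
#' @param config A [run_config()].
#' @return A clinical `data.frame`.
#' @export
simulate_clinical_cohort <- function(config = run_config()) {
  recs <- list()
  groups <- list(SCI = list(gp = config$sci, n = config$clinical$n_sci),
                 NDC = list(gp = config$ndc, n = config$clinical$n_ndc))
  for (gname in names(groups)) {
    g <- groups[[gname]]
    if (g$n < 1) next
    for (i in seq_len(g$n)) {
      recs[[length(recs) + 1L]] <-
        simulate_participant(g$gp, config$clinical, i, config$seed)$record
    }
  }
  out <- do.call(rbind, recs)
  out$distance_FD_FH_m <- config$clinical$distance_FD_FH_m
  class(out) <- c("nwr_clinical", "data.frame")
  out
}
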