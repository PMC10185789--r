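#' Reflex detection configuration
#'
#' Parameters of the threshold-based burst detector.  The reflex definition
#' is polyphasic EMG activity exceeding two standard deviations above
#' background noise; everything else here operationalizes that definition on
#' discretely sampled, rectified EMG.
#'
#' Windows follow the half-open convention `[a, b)` except `tw2_ms`, which is
#' closed at the epoch end.  Times are milliseconds relative to stimulus
#' onset (onset = 0).
#'
#' @param noise_window_ms Pre-stimulus interval used for background
#'   statistics, default `c(-500, 0)` (half-open at 0).
#' @param threshold_sd_multiplier Burst threshold is
#'   `mu_bg + threshold_sd_multiplier * sigma_bg` on the rectified trace.
#' @param min_burst_ms A burst must open with at least this many
#'   milliseconds of consecutive supra-threshold samples.
#' @param offset_hold_ms A burst ends once the trace stays below threshold
#'   for this long; shorter sub-threshold dips are bridged.
#' @param merge_gap_ms Bursts separated by less than this are merged.
#' @param min_phases Minimum phase count for the polyphasic criterion.
#' @param phase_amplitude_fraction Excursions on the unrectified trace must
#'   reach this fraction of the threshold to count as a phase.
#' @param tw1_ms Early (A-delta fiber) latency window, default `[90, 600)` ms.
#' @param tw2_ms Late (C-fiber) latency window, default `[1000, 3000]` ms.
#' @param artifact_sigma_max_uV Trials whose background SD exceeds this are
#'   flagged invalid (movement/electrode artifact guard).
#' @return An object of class `nwr_detection_config`.
#' @export
detection_config <- function(noise_window_ms = c(-500, 0),
                             threshold_sd_multiplier = 2,
                             min_burst_ms = 6,
                             offset_hold_ms = 50,
                             merge_gap_ms = 50,
                             min_phases = 3,
                             phase_amplitude_fraction = 0.5,
                             tw1_ms = c(90, 600),
                             tw2_ms = c(1000, 3000),
                             artifact_sigma_max_uV = 30) {
  stopifnot(length(noise_window_ms) == 2, noise_window_ms[1] < noise_window_ms[2])
  if (noise_window_ms[2] > 0) {
    stop("noise window must precede stimulus onset (t = 0)")
  }
  if (threshold_sd_multiplier <= 0) stop("threshold_sd_multiplier must be > 0")
  stopifnot(length(tw1_ms) == 2, length(tw2_ms) == 2,
            tw1_ms[1] < tw1_ms[2], tw2_ms[1] < tw2_ms[2])
  if (tw1_ms[2] > tw2_ms[1]) stop("tw1_ms and tw2_ms must be disjoint")
  cfg <- list(
    noise_window_ms = as.numeric(noise_window_ms),
    threshold_sd_multiplier = threshold_sd_multiplier,
    min_burst_ms = min_burst_ms,
    offset_hold_ms = offset_hold_ms,
    merge_gap_ms = merge_gap_ms,
    min_phases = as.integer(min_phases),
    phase_amplitude_fraction = phase_amplitude_fraction,
    tw1_ms = as.numeric(tw1_ms),
    tw2_ms = as.numeric(tw2_ms),
    artifact_sigma_max_uV = artifact_sigma_max_uV
  )
  structure(cfg, class = "nwr_detection_config")
}

#' EMG preprocessing configuration
#'
#' Conditioning chain applied before detection: zero-phase Butterworth
#' band-pass (1-450 Hz by default), epoch segmentation, full-wave
#' rectification.  The sampling rate is validated, never resampled.
#'
#' @param band_low_Hz Lower band edge in Hz.
#' @param band_high_Hz Upper band edge in Hz; must be below Nyquist.
#' @param filter_order Butterworth order applied at each band edge.
#' @param zero_phase Apply the filter forward-backward so onset latencies
#'   carry no filter delay.
#' @param target_rate_Hz Expected sampling rate of the recordings.
#' @return An object of class `nwr_preprocess_config`.
#' @export
preprocess_config <- function(band_low_Hz = 1,
                              band_high_Hz = 450,
                              filter_order = 4,
                              zero_phase = TRUE,
                              target_rate_Hz = 1000) {
  if (!(band_low_Hz > 0 && band_low_Hz < band_high_Hz &&
        band_high_Hz < target_rate_Hz / 2)) {
    stop("require 0 < band_low_Hz < band_high_Hz < target_rate_Hz/2")
  }
  structure(list(
    band_low_Hz = band_low_Hz,
    band_high_Hz = band_high_Hz,
    filter_order = as.integer(filter_order),
    zero_phase = isTRUE(zero_phase),
    target_rate_Hz = target_rate_Hz
  ), class = "nwr_preprocess_config")
}

#' Group-level simulation parameters
#'
#' Returns the generating parameters of the synthetic EMG cohort for one
#' study group.  Defaults transcribe the cohort-level readouts of the study
#' conditions: per-site response rates in the two time windows, the 74%/28%
#' (SCI/NDC) late-window responder fractions, fibula-head latency
#' distributions, C-fiber conduction-velocity distributions (SCI
#' 1.34 +/- 0.46 m/s, NDC 1.08 +/- 0.38 m/s), the roughly two orders of
#' magnitude reflex-magnitude contrast (amplitude x40, duration x2.5), TA/SO
#' co-activation in SCI versus TA-dominant (78%) single-muscle responses in
#' NDC, and per-stimulus pain ratings with an analgesia mass in SCI.
#'
#' Latencies at the two distal sites are derived from the fibula-head (FH)
#' anchor through each participant's latent conduction velocity, so
#' inter-site latency shifts are consistent by construction.
#'
#' @param group `"SCI"` or `"NDC"`.
#' @param ... Named overrides of any returned field.
#' @return An object of class `nwr_group_sim_params`.
#' @export
group_sim_params <- function(group = c("SCI", "NDC"), ...) {
  group <- match.arg(group)
  p <- if (group == "SCI") {
    list(
      group = "SCI",
      p_respond_tw1 = c(FS = 0.096, FD = 0.144, FH = 0.143),
      p_respond_tw2 = c(FS = 0.199, FD = 0.207, FH = 0.162),
      responder_prob_tw1 = 0.70,
      responder_prob_tw2 = 0.74,
      propensity_shape = 2,
      latency_anchor_tw1_ms = c(mean = 278, sd = 111),
      latency_anchor_tw2_ms = c(mean = 1257, sd = 158),
      latency_jitter_ms = 10,
      burst_amplitude_uV = c(tw1 = 370, tw2 = 1600),
      amplitude_sdlog = 0.6,
      burst_duration_ms = list(tw1 = c(100, 250), tw2 = c(150, 400)),
      phase_duration_ms = c(10, 16),
      coactivation_prob = 0.5,
      ta_only_prob = 0.7,
      noise_sd_uV = 5,
      cv_tw2_mean_mps = 1.34,
      cv_tw2_sd_mps = 0.46,
      cv_tw1_range_mps = c(5.2, 16.7),
      cv_jitter_frac = 0.05,
      pain_rating_mean = 3.5,
      pain_rating_sd = 6,
      analgesia_prob = 0.45
    )
  } else {
    list(
      group = "NDC",
      p_respond_tw1 = c(FS = 0, FD = 0, FH = 0),
      p_respond_tw2 = c(FS = 0.025, FD = 0.043, FH = 0.031),
      responder_prob_tw1 = 0,
      responder_prob_tw2 = 0.28,
      propensity_shape = 2,
      latency_anchor_tw1_ms = c(mean = NA_real_, sd = NA_real_),
      latency_anchor_tw2_ms = c(mean = 1030, sd = 249),
      latency_jitter_ms = 10,
      burst_amplitude_uV = c(tw1 = NA_real_, tw2 = 40),
      amplitude_sdlog = 0.6,
      burst_duration_ms = list(tw1 = c(40, 100), tw2 = c(60, 160)),
      phase_duration_ms = c(10, 16),
      coactivation_prob = 0,
      ta_only_prob = 0.78,
      noise_sd_uV = 5,
      cv_tw2_mean_mps = 1.08,
      cv_tw2_sd_mps = 0.38,
      cv_tw1_range_mps = c(5.2, 16.7),
      cv_jitter_frac = 0.05,
      pain_rating_mean = 14.9,
      pain_rating_sd = 9.7,
      analgesia_prob = 0
    )
  }
  dots <- list(...)
  if (length(dots)) {
    unknown <- setdiff(names(dots), names(p))
    if (length(unknown)) stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
    p[names(dots)] <- dots
  }
  stopifnot(all(unlist(p[c("p_respond_tw1", "p_respond_tw2")]) >= 0),
            all(unlist(p[c("p_respond_tw1", "p_respond_tw2")]) <= 1),
            p$noise_sd_uV > 0)
  structure(p, class = "nwr_group_sim_params")
}

#' Clinical cohort simulation parameters
#'
#' Generating model for the clinical table: below-level neuropathic pain
#' grading (CPG) prevalence, and an inverse pain-spasticity association
#' produced by a logistic model
#' `logit P(spasticity) = a + b * 1[CPG = yes]` whose defaults reproduce the
#' observed 2/8 (spasticity given pain) versus 6/7 (spasticity given no
#' pain) split in expectation (`a = log(6)`, `b = log(1/18)`).
#'
#' @param n_sci,n_ndc Cohort sizes.
#' @param p_cpg Probability of a positive neuropathic-pain grading (SCI).
#' @param spasticity_intercept Logistic intercept `a` (CPG = no).
#' @param spasticity_given_pain_logodds Logistic slope `b` for CPG = yes;
#'   `exp(b)` is the spasticity odds ratio pain vs no-pain.
#' @param n_joints Number of joints scored for MAS/SCAT.
#' @param distance_FS_FH_m Mean and SD of the FS-FH inter-site distance (m).
#' @param distance_FD_FH_m Fixed FD-FH distance (m).
#' @param seed Optional default seed carried with the parameter set.
#' @return An object of class `nwr_clinical_sim_params`.
#' @export
clinical_sim_params <- function(n_sci = 15,
                                n_ndc = 12,
                                p_cpg = 8 / 15,
                                spasticity_intercept = log(6),
                                spasticity_given_pain_logodds = log(1 / 18),
                                n_joints = 6,
                                distance_FS_FH_m = c(mean = 0.42, sd = 0.03),
                                distance_FD_FH_m = 0.40,
                                seed = NULL) {
  stopifnot(n_sci >= 0, n_ndc >= 0, p_cpg >= 0, p_cpg <= 1, n_joints >= 1)
  structure(list(
    n_sci = as.integer(n_sci),
    n_ndc = as.integer(n_ndc),
    p_cpg = p_cpg,
    spasticity_intercept = spasticity_intercept,
    spasticity_given_pain_logodds = spasticity_given_pain_logodds,
    n_joints = as.integer(n_joints),
    distance_FS_FH_m = distance_FS_FH_m,
    distance_FD_FH_m = distance_FD_FH_m,
    seed = seed
  ), class = "nwr_clinical_sim_params")
}

#' Full simulation / pipeline run configuration
#'
#' Bundles every tunable of an end-to-end run in one place.
#'
#' @param seed Master seed; all randomness fans out from it.
#' @param n_trials Stimuli per participant and site (nominal 60).
#' @param sites Stimulation sites to simulate.
#' @param sci,ndc Group parameter sets, see [group_sim_params()].
#' @param clinical Clinical generator, see [clinical_sim_params()].
#' @param preprocess See [preprocess_config()].
#' @param detection See [detection_config()].
#' @return An object of class `nwr_run_config`.
#' @export
run_config <- function(seed = 1L,
                       n_trials = 60,
                       sites = NWR_SITES,
                       sci = group_sim_params("SCI"),
                       ndc = group_sim_params("NDC"),
                       clinical = clinical_sim_params(),
                       preprocess = preprocess_config(),
                       detection = detection_config()) {
  stopifnot(all(sites %in% NWR_SITES), n_trials >= 1)
  structure(list(
    seed = as.integer(seed),
    n_trials = as.integer(n_trials),
    sites = sites,
    sci = sci, ndc = ndc, clinical = clinical,
    preprocess = preprocess, detection = detection
  ), class = "nwr_run_config")
}

#' Read a run configuration from a YAML file
#'
#' The file may set any subset of the configuration: top-level `seed`,
#' `n_trials`, `sites`, and nested `sci` / `ndc` (see [group_sim_params()]),
#' `clinical` ([clinical_sim_params()]), `preprocess`
#' ([preprocess_config()]) and `detection` ([detection_config()]) blocks.
#' Unset fields keep their defaults; unknown fields raise an error.  The
#' file written as `config.yaml` by [run_pipeline()] reads back to an
#' equivalent configuration.
#'
#' @param path YAML file path.
#' @return An `nwr_run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  override <- function(obj, spec, rebuild = NULL) {
    if (is.null(spec)) return(obj)
    unknown <- setdiff(names(spec), names(obj))
    if (length(unknown)) {
      stop("unknown configuration field(s): ", paste(unknown, collapse = ", "))
    }
    for (nm in names(spec)) {
      v <- spec[[nm]]
      old <- obj[[nm]]
      if (is.list(old) && !is.null(names(old))) {
        # nested named list (e.g. burst_duration_ms per window)
        obj[[nm]][names(v)] <- v
      } else if (!is.null(names(old)) && is.numeric(old)) {
        vv <- unlist(v)
        if (!is.null(names(vv))) old[names(vv)] <- vv else old[] <- vv
        obj[[nm]] <- old
      } else {
        obj[[nm]] <- unlist(v, use.names = FALSE)
      }
    }
    obj
  }
  cfg <- run_config(
    seed = y$seed %||% 1L,
    n_trials = y$n_trials %||% 60,
    sites = unlist(y$sites) %||% NWR_SITES)
  cfg$sci <- override(cfg$sci, y$sci)
  cfg$ndc <- override(cfg$ndc, y$ndc)
  cfg$clinical <- override(cfg$clinical, y$clinical)
  cfg$preprocess <- override(cfg$preprocess, y$preprocess)
  cfg$detection <- override(cfg$detection, y$detection)
  cfg
}
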