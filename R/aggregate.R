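# Participant-level aggregation and conduction-velocity estimation.
#
# A response trial counts once per time window regardless of whether the
# tibialis anterior, the soleus, or both fired.  Within a window, the
# trial's latency is the earliest onset and its AUC the sum over that
# window's events.  Invalid trials never enter a denominator.

#' Summarize detections per participant, site and time window
#'
#' Builds one row per (participant, site, window) for windows `TW1`, `TW2`
#' and `any`: valid-trial count, response-trial count, response rate (%),
#' responder flag, latency mean/SD and AUC mean over response trials,
#' co-activation rate (% of response trials with near-simultaneous TA and
#' SO events), mean per-stimulus pain rating and an analgesia flag (all
#' ratings zero).
#'
#' @param events Event table from [detect_epochs()] (or [read_events()]).
#' @param trials Per-trial table with `participant_id`, `site`,
#'   `trial_index`, `valid` and optionally `pain_rating` (a trial manifest
#'   works).
#' @return `data.frame` of response summaries.
#' @export
summarize_responses <- function(events, trials) {
  stopifnot(all(c("participant_id", "site", "trial_index", "valid")
                %in% names(trials)))
  if (!"pain_rating" %in% names(trials)) trials$pain_rating <- NA_real_
  keys <- unique(trials[, c("participant_id", "site")])
  out <- list()
  for (k in seq_len(nrow(keys))) {
    pid <- keys$participant_id[k]
    site <- keys$site[k]
    tr <- trials[trials$participant_id == pid & trials$site == site, ]
    ev <- events[events$participant_id == pid & events$site == site &
                   events$trial_index %in% tr$trial_index[tr$valid], ,
                 drop = FALSE]
    n_valid <- sum(tr$valid)
    ratings <- tr$pain_rating[tr$valid]
    ratings <- ratings[!is.na(ratings)]
    for (w in c("TW1", "TW2", "any")) {
      evw <- if (w == "any") ev else ev[ev$window == w, , drop = FALSE]
      resp_trials <- unique(evw$trial_index)
      n_resp <- length(resp_trials)
      # per-trial window latency = earliest onset; AUC = sum within window
      lat <- auc <- coact <- numeric(0)
      if (n_resp) {
        lat <- vapply(resp_trials, function(ti) {
          min(evw$onset_ms[evw$trial_index == ti])
        }, 0)
        auc <- vapply(resp_trials, function(ti) {
          sum(evw$auc_uVs[evw$trial_index == ti])
        }, 0)
        coact <- vapply(resp_trials, function(ti) {
          any(evw$coactivated[evw$trial_index == ti])
        }, NA)
      }
      out[[length(out) + 1L]] <- data.frame(
        participant_id = pid, site = site, window = w,
        n_valid_trials = n_valid, n_response_trials = n_resp,
        response_rate_pct = if (n_valid > 0) 100 * n_resp / n_valid else NA_real_,
        responder = n_resp > 0,
        latency_mean_ms = if (n_resp) mean(lat) else NA_real_,
        latency_sd_ms = if (n_resp > 1) stats::sd(lat) else NA_real_,
        auc_mean_uVs = if (n_resp) mean(auc) else NA_real_,
        coactivation_rate_pct = if (n_resp) 100 * mean(coact) else NA_real_,
        pain_rating_mean = if (length(ratings)) mean(ratings) else NA_real_,
        analgesic = if (length(ratings)) all(ratings == 0) else NA,
        flagged = n_valid == 0,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Conduction velocity from distance and latency shift
#'
#' @param distance_m Inter-site distance in meters (> 0).
#' @param delta_latency_ms Latency shift distal minus proximal, ms.
#' @return Conduction velocity in m/s (`NA` when the shift is not positive).
#' @export
#' @examples
#' conduction_velocity(0.42, 561)  # 0.75 m/s
conduction_velocity <- function(distance_m, delta_latency_ms) {
  if (any(distance_m <= 0)) stop("distance_m must be positive")
  ifelse(delta_latency_ms > 0, distance_m / (delta_latency_ms / 1000),
         NA_real_)
}

#' Estimate a participant's conduction velocity from inter-site latencies
#'
#' Takes per-trial reflex onsets at a distal and a proximal stimulation
#' site (same time window), forms the difference of the median latencies
#' and divides the inter-site distance by it.  The estimate is undefined
#' (not an error) when either site has fewer than `min_events` response
#' trials or the latency shift is not positive.
#'
#' @param events Event table (one participant, or filtered by caller).
#' @param participant_id Participant to estimate.
#' @param distance_m Distance between the two stimulation sites (m).
#' @param window Time window (default `"TW2"`, the C-fiber range).
#' @param distal,proximal Site codes (defaults FS distal, FH proximal).
#' @param min_events Minimum response trials per site (default 3).
#' @return One-row `data.frame`: `participant_id`, `window`, `distance_m`,
#'   `delta_latency_ms`, `cv_mps`, `n_events_distal`, `n_events_proximal`,
#'   `defined`.
#' @export
estimate_cv <- function(events, participant_id, distance_m,
                        window = "TW2", distal = "FS", proximal = "FH",
                        min_events = 3) {
  if (!is.na(distance_m) && distance_m <= 0) stop("distance_m must be positive")
  ev <- events[events$participant_id == participant_id &
                 events$window == window, , drop = FALSE]
  lat_site <- function(s) {
    evs <- ev[ev$site == s, , drop = FALSE]
    if (!nrow(evs)) return(numeric())
    vapply(unique(evs$trial_index), function(ti) {
      min(evs$onset_ms[evs$trial_index == ti])
    }, 0)
  }
  ld <- lat_site(distal)
  lp <- lat_site(proximal)
  delta <- if (length(ld) && length(lp)) {
    stats::median(ld) - stats::median(lp)
  } else {
    NA_real_
  }
  defined <- !is.na(distance_m) && !is.na(delta) && delta > 0 &&
    length(ld) >= min_events && length(lp) >= min_events
  data.frame(
    participant_id = participant_id, window = window,
    distance_m = distance_m, delta_latency_ms = delta,
    cv_mps = if (defined) conduction_velocity(distance_m, delta) else NA_real_,
    n_events_distal = length(ld), n_events_proximal = length(lp),
    defined = defined, stringsAsFactors = FALSE)
}

#' Conduction-velocity estimates for a whole cohort
#'
#' @param events Event table.
#' @param clinical Clinical table providing `distance_FS_FH_m` per
#'   participant.
#' @param window Time window (default `"TW2"`).
#' @param min_events Minimum response trials per site.
#' @return `data.frame` with one [estimate_cv()] row per participant.
#' @export
estimate_cv_cohort <- function(events, clinical, window = "TW2",
                               min_events = 3) {
  do.call(rbind, lapply(seq_len(nrow(clinical)), function(k) {
    estimate_cv(events, clinical$participant_id[k],
                clinical$distance_FS_FH_m[k], window = window,
                min_events = min_events)
  }))
}

#' Grand-average rectified traces
#'
#' Pointwise mean of the rectified epochs, per muscle; the standard
#' reporting view of cohort-level reflex activity.
#'
#' @param epochs List of `nwr_epoch` objects (equal geometry).
#' @return List with `time_ms`, `TA`, `SO` (mean rectified traces) and `n`.
#' @export
grand_average <- function(epochs) {
  epochs <- Filter(function(e) isTRUE(e$valid), epochs)
  if (!length(epochs)) stop("grand_average needs at least one valid epoch")
  ta <- rowMeans(vapply(epochs, function(e) rectify(e$samples_TA),
                        numeric(length(epochs[[1]]$samples_TA))))
  so <- rowMeans(vapply(epochs, function(e) rectify(e$samples_SO),
                        numeric(length(epochs[[1]]$samples_SO))))
  list(time_ms = epoch_times(epochs[[1]]), TA = ta, SO = so,
       n = length(epochs))
}
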