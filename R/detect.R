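# Threshold-based reflex detection.  A reflex event is polyphasic EMG
# activity whose rectified amplitude exceeds the background mean plus
# `threshold_sd_multiplier` background standard deviations.  The threshold
# includes the background mean so it is invariant to the positive offset
# rectification introduces.

#' Background-noise statistics of one channel
#'
#' Mean and standard deviation of the rectified pre-stimulus trace,
#' computed over the half-open noise window (default `[-500, 0)` ms).
#'
#' @param epoch A preprocessed (filtered) `nwr_epoch`.
#' @param channel `"TA"` or `"SO"`.
#' @param config A [detection_config()].
#' @return List with `mu_bg_uV`, `sigma_bg_uV`, `window_ms`.
#' @export
estimate_background <- function(epoch, channel = c("TA", "SO"),
                                config = detection_config()) {
  channel <- match.arg(channel)
  x <- rectify(epoch[[paste0("samples_", channel)]])
  tt <- epoch_times(epoch)
  w <- config$noise_window_ms
  sel <- tt >= w[1] & tt < w[2]
  if (!any(sel)) stop("noise window [", w[1], ", ", w[2], ") contains no samples")
  xs <- x[sel]
  list(mu_bg_uV = mean(xs),
       sigma_bg_uV = if (length(xs) > 1) stats::sd(xs) else 0,
       window_ms = w)
}

#' Detect supra-threshold bursts on a rectified trace
#'
#' A burst opens at the first sample of at least `min_burst_ms` of
#' consecutive supra-threshold samples; sub-threshold dips shorter than
#' `offset_hold_ms` are bridged; the burst closes once the trace stays
#' below threshold for `offset_hold_ms`.  Bursts closer than
#' `merge_gap_ms` are merged.  Detection is restricted to the post-stimulus
#' interval `[0, 3000)` ms.
#'
#' @param rect Rectified sample vector.
#' @param times Sample times in ms (same length).
#' @param background Output of [estimate_background()].
#' @param config A [detection_config()].
#' @return `data.frame` with `onset_ms`, `offset_ms` (offset exclusive),
#'   possibly zero rows.
#' @export
detect_bursts <- function(rect, times, background,
                          config = detection_config()) {
  thr <- background$mu_bg_uV +
    config$threshold_sd_multiplier * background$sigma_bg_uV
  dt <- if (length(times) > 1) times[2] - times[1] else 1
  sel <- which(times >= 0 & times < 3000)
  if (!length(sel)) return(data.frame(onset_ms = numeric(), offset_ms = numeric()))
  x <- rect[sel]
  tt <- times[sel]
  above <- x >= thr
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  run_above <- r$values
  min_run <- max(1L, ceiling(config$min_burst_ms / dt))
  hold <- config$offset_hold_ms / dt
  # seed runs: long enough to open a burst
  seeds <- which(run_above & r$lengths >= min_run)
  if (!length(seeds)) {
    return(data.frame(onset_ms = numeric(), offset_ms = numeric()))
  }
  bursts <- list()
  k <- 1L
  while (k <= length(seeds)) {
    s <- seeds[k]
    b_start <- starts[s]
    # extend: bridge below-runs shorter than the offset hold
    j <- s
    repeat {
      nxt <- j + 2L  # next above-run (j + 1 is a below-run)
      if (nxt > length(run_above) || !run_above[nxt]) break
      if (r$lengths[j + 1L] >= hold) break
      j <- nxt
    }
    b_end <- ends[j]
    bursts[[length(bursts) + 1L]] <- c(b_start, b_end)
    k <- k + 1L
    while (k <= length(seeds) && starts[seeds[k]] <= b_end) k <- k + 1L
  }
  m <- do.call(rbind, bursts)
  # merge bursts separated by less than merge_gap_ms
  gap <- config$merge_gap_ms / dt
  if (nrow(m) > 1) {
    keep <- list(m[1, ])
    for (i in 2:nrow(m)) {
      last <- keep[[length(keep)]]
      if (m[i, 1] - last[2] < gap) {
        keep[[length(keep)]] <- c(last[1], max(last[2], m[i, 2]))
      } else {
        keep[[length(keep) + 1L]] <- m[i, ]
      }
    }
    m <- do.call(rbind, keep)
  }
  data.frame(onset_ms = tt[m[, 1]],
             offset_ms = tt[m[, 2]] + dt)
}

#' Count phases of a burst on the unrectified trace
#'
#' A phase is a same-sign excursion between zero crossings whose absolute
#' peak reaches `phase_amplitude_fraction` of the detection threshold;
#' the count is one plus the number of sign changes between successive
#' qualifying excursions.  The polyphasic criterion requires at least
#' `min_phases` phases.
#'
#' @param filt Filtered, unrectified sample vector.
#' @param times Sample times in ms.
#' @param burst One-row burst interval (`onset_ms`, `offset_ms`) or a
#'   numeric length-2 vector.
#' @param threshold Detection threshold (microvolts).
#' @param config A [detection_config()].
#' @return Integer phase count (0 if no excursion qualifies).
#' @export
count_phases <- function(filt, times, burst, threshold,
                         config = detection_config()) {
  iv <- as.numeric(burst[1:2])
  sel <- times >= iv[1] & times < iv[2]
  x <- filt[sel]
  if (!length(x)) return(0L)
  s <- sign(x)
  # zeros inherit the previous sign so they do not split excursions
  for (i in seq_along(s)) if (s[i] == 0) s[i] <- if (i > 1) s[i - 1] else 1
  r <- rle(s)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  peaks <- vapply(seq_along(r$values), function(i) {
    max(abs(x[starts[i]:ends[i]]))
  }, 0)
  floor_amp <- config$phase_amplitude_fraction * threshold
  keep <- peaks >= floor_amp
  if (!any(keep)) return(0L)
  ksign <- r$values[keep]
  as.integer(1L + sum(diff(ksign) != 0))
}

#' Characterize a detected burst
#'
#' Onset latency, offset, rectified peak and area under the
#' background-corrected rectified curve (AUC, microvolt-seconds):
#' `sum(max(rect - mu_bg, 0)) * dt`.
#'
#' @param rect Rectified sample vector.
#' @param times Sample times in ms.
#' @param burst Burst interval (`onset_ms`, `offset_ms`).
#' @param background Output of [estimate_background()].
#' @return List with `onset_ms`, `offset_ms`, `peak_uV`, `auc_uVs`.
#' @export
characterize_burst <- function(rect, times, burst, background) {
  iv <- as.numeric(burst[1:2])
  sel <- times >= iv[1] & times < iv[2]
  x <- rect[sel]
  dt_s <- (if (length(times) > 1) times[2] - times[1] else 1) / 1000
  list(onset_ms = iv[1],
       offset_ms = iv[2],
       peak_uV = if (length(x)) max(x) else NA_real_,
       auc_uVs = sum(pmax(x - background$mu_bg_uV, 0)) * dt_s)
}

#' Assign a reflex latency to a time window
#'
#' `TW1` (early, A-delta-fiber range) is `[90, 600)` ms by default, `TW2`
#' (late, C-fiber range) `[1000, 3000]` ms; onsets in the gap are labelled
#' `intermediate`, anything else `none`.  Nothing is silently discarded.
#'
#' @param onset_ms Onset latency (vectorized).
#' @param config A [detection_config()].
#' @return Character vector of window labels.
#' @export
assign_window <- function(onset_ms, config = detection_config()) {
  tw1 <- config$tw1_ms
  tw2 <- config$tw2_ms
  ifelse(onset_ms >= tw1[1] & onset_ms < tw1[2], "TW1",
  ifelse(onset_ms >= tw2[1] & onset_ms <= tw2[2], "TW2",
  ifelse(onset_ms >= tw1[2] & onset_ms < tw2[1], "intermediate", "none")))
}

#' Detect and characterize reflex events in one trial
#'
#' Runs both channels of a preprocessed epoch through background
#' estimation, burst detection, the polyphasic criterion and burst
#' characterization.  The trial is invalid (and carries no events) when the
#' epoch is flagged invalid or either channel's background SD exceeds
#' `artifact_sigma_max_uV`.  A time window is co-activated when both
#' muscles have events there with onset difference at most 100 ms.
#'
#' @param epoch A preprocessed `nwr_epoch`.
#' @param config A [detection_config()].
#' @return An object of class `nwr_trial_detection`: list with `epoch_key`,
#'   `background` (per channel), `events` (`data.frame`: `muscle`,
#'   `onset_ms`, `offset_ms`, `peak_uV`, `auc_uVs`, `n_phases`, `window`,
#'   `coactivated`), `valid`, `coactivated_tw`.
#' @export
detect_trial <- function(epoch, config = detection_config()) {
  key <- list(participant_id = epoch$participant_id, site = epoch$site,
              trial_index = epoch$trial_index,
              pain_rating = epoch$pain_rating)
  empty <- data.frame(muscle = character(), onset_ms = numeric(),
                      offset_ms = numeric(), peak_uV = numeric(),
                      auc_uVs = numeric(), n_phases = integer(),
                      window = character(), coactivated = logical(),
                      stringsAsFactors = FALSE)
  out <- list(epoch_key = key, background = list(), events = empty,
              valid = isTRUE(epoch$valid), coactivated_tw = character())
  class(out) <- "nwr_trial_detection"
  if (!out$valid) return(out)
  tt <- epoch_times(epoch)
  ev <- list()
  for (ch in NWR_MUSCLES) {
    filt <- epoch[[paste0("samples_", ch)]]
    rect <- rectify(filt)
    bg <- estimate_background(epoch, ch, config)
    out$background[[ch]] <- bg
    if (bg$sigma_bg_uV > config$artifact_sigma_max_uV) {
      out$valid <- FALSE
      out$events <- empty
      return(out)
    }
    thr <- bg$mu_bg_uV + config$threshold_sd_multiplier * bg$sigma_bg_uV
    bursts <- detect_bursts(rect, tt, bg, config)
    if (!nrow(bursts)) next
    for (b in seq_len(nrow(bursts))) {
      np <- count_phases(filt, tt, c(bursts$onset_ms[b], bursts$offset_ms[b]),
                         thr, config)
      if (np < config$min_phases) next
      ch_ev <- characterize_burst(rect, tt,
                                  c(bursts$onset_ms[b], bursts$offset_ms[b]),
                                  bg)
      ev[[length(ev) + 1L]] <- data.frame(
        muscle = ch, onset_ms = ch_ev$onset_ms, offset_ms = ch_ev$offset_ms,
        peak_uV = ch_ev$peak_uV, auc_uVs = ch_ev$auc_uVs,
        n_phases = np, window = assign_window(ch_ev$onset_ms, config),
        coactivated = FALSE, stringsAsFactors = FALSE)
    }
  }
  if (length(ev)) {
    events <- do.call(rbind, ev)
    for (w in c("TW1", "TW2", "intermediate")) {
      ta <- events$onset_ms[events$muscle == "TA" & events$window == w]
      so <- events$onset_ms[events$muscle == "SO" & events$window == w]
      if (length(ta) && length(so) &&
          min(abs(outer(ta, so, "-"))) <= 100) {
        out$coactivated_tw <- c(out$coactivated_tw, w)
        events$coactivated[events$window == w] <- TRUE
      }
    }
    out$events <- events
  }
  out
}

#' Detect reflex events across many epochs
#'
#' @param epochs List of preprocessed `nwr_epoch` objects.
#' @param config A [detection_config()].
#' @return List with `detections` (one [detect_trial()] result per epoch),
#'   `events` (combined event table keyed by participant/site/trial) and
#'   `trials` (per-trial validity and pain-rating table).
#' @export
detect_epochs <- function(epochs, config = detection_config()) {
  detections <- lapply(epochs, detect_trial, config = config)
  list(detections = detections,
       events = events_table(detections),
       trials = trials_table(detections))
}

events_table <- function(detections) {
  rows <- lapply(detections, function(d) {
    if (!nrow(d$events)) return(NULL)
    cbind(data.frame(participant_id = d$epoch_key$participant_id,
                     site = d$epoch_key$site,
                     trial_index = d$epoch_key$trial_index,
                     valid = d$valid,
                     stringsAsFactors = FALSE),
          d$events)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows)) {
    return(data.frame(participant_id = character(), site = character(),
                      trial_index = integer(), valid = logical(),
                      muscle = character(), onset_ms = numeric(),
                      offset_ms = numeric(), peak_uV = numeric(),
                      auc_uVs = numeric(), n_phases = integer(),
                      window = character(), coactivated = logical(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

trials_table <- function(detections) {
  do.call(rbind, lapply(detections, function(d) {
    data.frame(participant_id = d$epoch_key$participant_id,
               site = d$epoch_key$site,
               trial_index = d$epoch_key$trial_index,
               pain_rating = d$epoch_key$pain_rating %||% NA_real_,
               valid = d$valid,
               stringsAsFactors = FALSE)
  }))
}
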