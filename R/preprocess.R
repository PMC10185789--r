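# EMG conditioning: band-pass filter, segment, rectify.
#
# The band-pass is realized as a cascade of a Butterworth high-pass at the
# low edge and a Butterworth low-pass at the high edge (order `filter_order`
# each), applied forward-backward (zero phase) so detected onset latencies
# carry no filter delay.  A direct transfer-function band-pass of combined
# order 8 with a 0.002x Nyquist low edge is numerically fragile; the cascade
# keeps each polynomial at order 4.

.filter_cache <- new.env(parent = emptyenv())

bandpass_coefs <- function(rate, config) {
  key <- paste(rate, config$band_low_Hz, config$band_high_Hz,
               config$filter_order, sep = "|")
  hit <- .filter_cache[[key]]
  if (!is.null(hit)) return(hit)
  ny <- rate / 2
  hp <- signal::butter(config$filter_order, config$band_low_Hz / ny, type = "high")
  lp <- signal::butter(config$filter_order, config$band_high_Hz / ny, type = "low")
  val <- list(hp = hp, lp = lp,
              hp_zi = lfilter_zi(hp$b, hp$a), lp_zi = lfilter_zi(lp$b, lp$a))
  .filter_cache[[key]] <- val
  val
}

# Steady-state unit-step initial filter state: starting from
# zi * x[1] the filter is already settled on a constant input, which
# removes the startup transient of each filtfilt pass (essential for the
# 1 Hz high-pass, whose transient far outlives any reasonable padding).
lfilter_zi <- function(b, a) {
  n <- max(length(a), length(b))
  a0 <- a[1]
  a <- c(a, rep(0, n - length(a))) / a0
  b <- c(b, rep(0, n - length(b))) / a0
  if (n == 1) return(numeric(0))
  if (n == 2) {
    A <- matrix(-a[2], 1, 1)
  } else {
    A <- rbind(-a[2:n], cbind(diag(n - 2), 0))
  }
  B <- b[2:n] - a[2:n] * b[1]
  as.numeric(solve(diag(n - 1) - t(A), B))
}

# Zero-phase application of one (b, a) filter with odd-reflection padding at
# both ends and steady-state initial conditions.
zero_phase_filter <- function(b, a, x, zi = lfilter_zi(b, a)) {
  pad <- max(3L * (max(length(a), length(b)) - 1L), 250L)
  as.numeric(iir_filtfilt(b, a, x, pad, zi))
}

#' Band-pass filter an EMG trace
#'
#' Butterworth band-pass (high-pass/low-pass cascade) with optional
#' zero-phase (forward-backward) application.  Output length equals input
#' length; the DC component is strongly attenuated.
#'
#' @param trace Numeric sample vector.
#' @param rate Sampling rate in Hz; must exceed twice the upper band edge.
#' @param config A [preprocess_config()].
#' @return Filtered sample vector of the same length.
#' @export
#' @examples
#' x <- sin(2 * pi * 100 * (0:999) / 1000)
#' y <- bandpass(x, 1000, preprocess_config())
bandpass <- function(trace, rate, config = preprocess_config()) {
  stopifnot(is.numeric(trace))
  if (config$band_high_Hz >= rate / 2) {
    stop("band_high_Hz (", config$band_high_Hz,
         " Hz) must lie below the Nyquist frequency (", rate / 2, " Hz)")
  }
  co <- bandpass_coefs(rate, config)
  if (config$zero_phase) {
    y <- zero_phase_filter(co$hp$b, co$hp$a, trace, co$hp_zi)
    zero_phase_filter(co$lp$b, co$lp$a, y, co$lp_zi)
  } else {
    y <- iir_filter(co$hp$b, co$hp$a, trace)
    as.numeric(iir_filter(co$lp$b, co$lp$a, y))
  }
}

#' Full-wave rectification
#'
#' @param trace Numeric sample vector.
#' @return `abs(trace)`.
#' @export
rectify <- function(trace) abs(trace)

#' Segment a continuous two-channel recording into stimulus-locked epochs
#'
#' Cuts one epoch per stimulus marker, from `pre_ms` before to `post_ms`
#' after the marker (canonically -500 to +3000 ms at 1000 Hz, 3501 samples).
#' Markers too close to the recording edge yield an epoch flagged invalid
#' rather than being dropped, so trial accounting stays complete.
#'
#' @param ta,so Continuous sample vectors for the tibialis anterior and
#'   soleus channels (equal length).
#' @param rate Sampling rate in Hz.
#' @param marker_ms Stimulus onset times in ms from recording start.
#' @param pre_ms,post_ms Epoch extent around each marker.
#' @param participant_id,site,energy_mJ,pain_rating Metadata copied into
#'   each epoch (recycled across markers).
#' @return List of `nwr_epoch` objects, one per marker, in marker order.
#' @export
segment_epochs <- function(ta, so, rate, marker_ms,
                           pre_ms = 500, post_ms = 3000,
                           participant_id = "P01", site = "FS",
                           energy_mJ = NA_real_, pain_rating = NA_real_) {
  stopifnot(length(ta) == length(so))
  n <- length(ta)
  dt <- 1000 / rate
  energy_mJ <- rep_len(energy_mJ, length(marker_ms))
  pain_rating <- rep_len(pain_rating, length(marker_ms))
  lapply(seq_along(marker_ms), function(k) {
    m_idx <- round(marker_ms[k] / dt) + 1L  # sample at the marker
    i0 <- m_idx - round(pre_ms / dt)
    i1 <- m_idx + round(post_ms / dt)
    ok <- i0 >= 1L && i1 <= n
    if (ok) {
      sa <- ta[i0:i1]; ss <- so[i0:i1]
    } else {
      len <- i1 - i0 + 1L
      sa <- rep(NA_real_, len); ss <- sa
    }
    emg_epoch(participant_id = participant_id, trial_index = k, site = site,
              energy_mJ = energy_mJ[k], sampling_rate_Hz = rate,
              t0_offset_ms = -pre_ms, samples_TA = sa, samples_SO = ss,
              pain_rating = pain_rating[k], valid = ok,
              validate = ok)
  })
}

#' Apply the conditioning chain to epochs
#'
#' Band-pass filters both channels of each epoch (rectification is applied
#' downstream by the detector, which also needs the unrectified trace for
#' phase counting).
#'
#' @param epochs List of `nwr_epoch` objects.
#' @param config A [preprocess_config()].
#' @return List of filtered epochs.
#' @export
preprocess_epochs <- function(epochs, config = preprocess_config()) {
  lapply(epochs, function(ep) {
    if (!isTRUE(ep$valid)) return(ep)
    if (!is.null(config$target_rate_Hz) &&
        abs(ep$sampling_rate_Hz - config$target_rate_Hz) > 1e-9) {
      stop("epoch sampling rate ", ep$sampling_rate_Hz,
           " Hz does not match the configured rate ", config$target_rate_Hz,
           " Hz (resampling is not supported)")
    }
    ep$samples_TA <- bandpass(ep$samples_TA, ep$sampling_rate_Hz, config)
    ep$samples_SO <- bandpass(ep$samples_SO, ep$sampling_rate_Hz, config)
    ep
  })
}
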