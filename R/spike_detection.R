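#' Spike-detection parameters
#'
#' Collects the tunable parameters of the two-stage spike detector: an
#' amplitude-threshold detector on the band-passed trace, refined by a
#' stationary-wavelet-transform Teager-energy-operator (SWTTEO) score.
#' Only spikes found by both stages are accepted.
#'
#' @param band_low,band_high Elliptic band-pass edges in Hz (defaults 200 and
#'   3000).
#' @param filter_order Elliptic filter order (default 4; applied
#'   forward-backward, so the effective order doubles).
#' @param ripple_db Passband ripple in dB (default 0.1).
#' @param stopband_db Stopband attenuation in dB (default 40).
#' @param threshold_multiplier Detection threshold as a multiple of the noise
#'   SD estimate (default 4.5).
#' @param refractory Minimum separation between detections, seconds
#'   (default 1e-3).
#' @param match_tolerance Maximum time offset for a threshold candidate to be
#'   confirmed by an SWTTEO peak, seconds (default 1e-3).
#' @param swt_level Stationary wavelet (Haar) detail level used for the
#'   SWTTEO score (default 3: at 25 kHz the level-3 detail band,
#'   roughly 1.6-3.1 kHz, covers the sharp transient of a ~1 ms
#'   extracellular spike).
#' @param smoothing_window SWTTEO score smoothing window, seconds
#'   (default 1e-3, covering the full ~1 ms spike-energy envelope so each
#'   spike contributes a single score peak).
#' @param noise_estimator \code{"mad"} for median(|x|)/0.6745 (robust,
#'   default) or \code{"sd"} for the plain standard deviation.
#' @return A list of class \code{spike_detection_params}.
#' @export
spike_detection_params <- function(band_low = 200, band_high = 3000,
                                   filter_order = 4, ripple_db = 0.1,
                                   stopband_db = 40,
                                   threshold_multiplier = 4.5,
                                   refractory = 1e-3,
                                   match_tolerance = 1e-3,
                                   swt_level = 3L,
                                   smoothing_window = 1e-3,
                                   noise_estimator = c("mad", "sd")) {
  noise_estimator <- match.arg(noise_estimator)
  stopifnot(band_low > 0, band_high > band_low, threshold_multiplier > 0,
            refractory >= 0, match_tolerance >= 0, swt_level >= 1,
            smoothing_window > 0)
  structure(list(band_low = band_low, band_high = band_high,
                 filter_order = filter_order, ripple_db = ripple_db,
                 stopband_db = stopband_db,
                 threshold_multiplier = threshold_multiplier,
                 refractory = refractory, match_tolerance = match_tolerance,
                 swt_level = as.integer(swt_level),
                 smoothing_window = smoothing_window,
                 noise_estimator = noise_estimator),
            class = "spike_detection_params")
}

#' Zero-phase elliptic band-pass filter
#'
#' Applies an elliptic band-pass filter forward and backward
#' (\code{signal::filtfilt}) so the output is zero-phase; spike timing is
#' therefore not shifted by the filter.
#'
#' @param trace Numeric vector, one electrode's raw trace (microvolts).
#' @param fs Sampling rate in Hz.
#' @param params \code{\link{spike_detection_params}}.
#' @return Filtered trace, same length as the input.
#' @export
bandpass_filter <- function(trace, fs, params = spike_detection_params()) {
  ny <- fs / 2
  if (params$band_high >= ny)
    stop(sprintf("band_high (%g Hz) must be below the Nyquist rate (%g Hz)",
                 params$band_high, ny))
  flt <- signal::ellip(params$filter_order, params$ripple_db,
                       params$stopband_db,
                       c(params$band_low, params$band_high) / ny,
                       type = "pass")
  signal::filtfilt(flt, trace)
}

#' Robust noise standard deviation estimate
#'
#' Estimates the background-noise SD of a band-passed trace as
#' median(|x|)/0.6745, the median-absolute-deviation convention used for
#' spike thresholding; large, sparse action potentials inflate it far less
#' than the plain SD.
#'
#' @param trace Filtered trace.
#' @param estimator \code{"mad"} (default) or \code{"sd"}.
#' @return Noise SD estimate in the units of the trace.
#' @export
estimate_noise_sd <- function(trace, estimator = c("mad", "sd")) {
  estimator <- match.arg(estimator)
  if (!length(trace)) stop("empty trace")
  if (estimator == "mad") stats::median(abs(trace)) / 0.6745
  else stats::sd(trace)
}

#' Amplitude-threshold spike candidates
#'
#' Finds local extrema of the absolute filtered trace exceeding
#' \code{threshold_multiplier * sigma}, enforcing the refractory separation
#' (an extremum closer than \code{refractory} to the previously accepted one
#' is skipped).
#'
#' @param trace Filtered trace.
#' @param fs Sampling rate (Hz).
#' @param sigma Noise SD estimate (see \code{\link{estimate_noise_sd}}).
#' @param params \code{\link{spike_detection_params}}.
#' @return Numeric vector of candidate spike times in seconds (time of the
#'   extremum sample).
#' @export
threshold_detect <- function(trace, fs, sigma,
                             params = spike_detection_params()) {
  stopifnot(sigma > 0)
  thr <- params$threshold_multiplier * sigma
  a <- abs(trace)
  n <- length(a)
  if (n < 3) return(numeric(0))
  # local maxima of |x| above threshold
  core <- a[2:(n - 1)]
  is_peak <- core > thr & core >= a[1:(n - 2)] & core > a[3:n]
  idx <- which(is_peak) + 1L
  if (!length(idx)) return(numeric(0))
  ref_n <- params$refractory * fs
  keep <- logical(length(idx))
  last <- -Inf
  for (k in seq_along(idx)) {
    if (idx[k] - last >= ref_n) {
      keep[k] <- TRUE
      last <- idx[k]
    }
  }
  (idx[keep] - 1) / fs
}

# Stationary (a-trous, Haar) wavelet detail coefficients at a given level.
# Circular boundary handling; output has the same length as the input.
swt_haar_detail <- function(x, level) {
  a <- x
  d <- NULL
  for (j in seq_len(level)) {
    shift <- 2L^(j - 1L)
    lag <- c(a[(length(a) - shift + 1L):length(a)], a[1:(length(a) - shift)])
    d <- (a - lag) / sqrt(2)
    a <- (a + lag) / sqrt(2)
  }
  d
}

#' SWTTEO spike-energy score
#'
#' Computes a nonnegative spike-energy signal: the stationary-wavelet
#' (Haar) detail coefficients at \code{swt_level} are passed through the
#' Teager energy operator \eqn{\psi[x](n) = x(n)^2 - x(n-1) x(n+1)},
#' rectified and smoothed with a moving average of length
#' \code{smoothing_window}. Transient spike energy stands out sharply in this
#' score while slow components and stationary noise are suppressed.
#'
#' @param trace Filtered trace.
#' @param fs Sampling rate (Hz).
#' @param params \code{\link{spike_detection_params}}.
#' @return Score vector, same length as \code{trace}, \eqn{\ge 0}.
#' @export
swtteo_score <- function(trace, fs, params = spike_detection_params()) {
  n <- length(trace)
  if (n < 4) return(numeric(n))
  d <- swt_haar_detail(trace, params$swt_level)
  psi <- numeric(n)
  psi[2:(n - 1)] <- d[2:(n - 1)]^2 - d[1:(n - 2)] * d[3:n]
  psi[psi < 0] <- 0
  w <- max(1L, round(params$smoothing_window * fs))
  if (w > 1L) {
    kernel <- rep(1 / w, w)
    psi <- stats::filter(psi, kernel, sides = 2)
    psi[is.na(psi)] <- 0
    psi <- as.numeric(psi)
  }
  psi
}

# Peaks of a score signal separated by >= refractory, strongest first;
# ties broken by earlier time.
score_peaks <- function(score, fs, refractory) {
  n <- length(score)
  if (n < 3) return(integer(0))
  core <- score[2:(n - 1)]
  is_peak <- core > 0 & core >= score[1:(n - 2)] & core > score[3:n]
  idx <- which(is_peak) + 1L
  if (!length(idx)) return(integer(0))
  ord <- order(-score[idx], idx)
  idx <- idx[ord]
  ref_n <- refractory * fs
  chosen <- integer(0)
  for (i in idx) {
    if (!length(chosen) || all(abs(chosen - i) >= ref_n))
      chosen <- c(chosen, i)
  }
  sort(chosen)
}

#' Consensus selection of threshold candidates by the SWTTEO score
#'
#' Takes the M strongest SWTTEO score peaks, where M is the number of
#' threshold candidates, and accepts a candidate only if a selected peak lies
#' within \code{match_tolerance}. The output is always a subset of the
#' candidates: the consensus never adds spikes.
#'
#' @param candidates Sorted candidate spike times (s) from
#'   \code{\link{threshold_detect}}.
#' @param score SWTTEO score from \code{\link{swtteo_score}} on the same
#'   trace.
#' @param fs Sampling rate (Hz).
#' @param params \code{\link{spike_detection_params}}.
#' @return Accepted spike times (s), sorted.
#' @export
consensus_select <- function(candidates, score, fs,
                             params = spike_detection_params()) {
  m <- length(candidates)
  if (m == 0L) return(numeric(0))
  pk <- score_peaks(score, fs, params$refractory)
  if (!length(pk)) return(numeric(0))
  # keep the m strongest (score_peaks returns all; rank by score)
  if (length(pk) > m) {
    ord <- order(-score[pk], pk)
    pk <- sort(pk[ord[seq_len(m)]])
  }
  pk_t <- (pk - 1) / fs
  ok <- vapply(candidates, function(tc)
    any(abs(pk_t - tc) <= params$match_tolerance), logical(1))
  candidates[ok]
}

#' Detect spikes on all electrodes of a raw recording
#'
#' Runs the full two-stage detector per electrode: zero-phase elliptic
#' band-pass (200-3000 Hz by default), robust noise-SD estimation, amplitude
#' thresholding at \code{threshold_multiplier} times the noise SD, SWTTEO
#' scoring, and consensus selection.
#'
#' @param recording An \code{\link{mea_recording}}.
#' @param params \code{\link{spike_detection_params}}.
#' @param verbose Print per-electrode spike counts.
#' @return A \code{\link{spike_list}}.
#' @export
detect_spikes <- function(recording, params = spike_detection_params(),
                          verbose = FALSE) {
  stopifnot(inherits(recording, "mea_recording"))
  fs <- recording$layout$sampling_rate
  out <- list()
  for (lb in colnames(recording$traces)) {
    x <- bandpass_filter(recording$traces[, lb], fs, params)
    sigma <- estimate_noise_sd(x, params$noise_estimator)
    if (sigma <= 0) {
      out[[lb]] <- numeric(0)
      next
    }
    cand <- threshold_detect(x, fs, sigma, params)
    sc <- swtteo_score(x, fs, params)
    out[[lb]] <- consensus_select(cand, sc, fs, params)
    if (verbose)
      message(sprintf("%s: %d spikes", lb, length(out[[lb]])))
  }
  spike_list(recording$layout, out, recording$duration)
}
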