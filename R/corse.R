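#' CorSE connectivity parameters
#'
#' Parameters of the correlated-spectral-entropy (CorSE) functional
#' connectivity estimator: electrode traces are cut into windows, the
#' Shannon entropy of each window's power spectrum is computed, and
#' connectivity between two electrodes is the maximum absolute normalized
#' cross-correlation of their entropy time series.
#'
#' @param window_length Window length in seconds (default 1).
#' @param window_overlap Fractional overlap between consecutive windows in
#'   \code{[0, 1)} (default 0, i.e. non-overlapping).
#' @param n_segments Welch segments averaged within each window (default 8,
#'   50\% segment overlap, Hann taper).
#' @param max_lag_windows Maximum cross-correlation lag in windows
#'   (default 5); 0 restricts to the zero-lag correlation.
#' @return A list of class \code{corse_params}.
#' @export
corse_params <- function(window_length = 1, window_overlap = 0,
                         n_segments = 8L, max_lag_windows = 5L) {
  stopifnot(window_length > 0, window_overlap >= 0, window_overlap < 1,
            n_segments >= 1, max_lag_windows >= 0)
  structure(list(window_length = window_length,
                 window_overlap = window_overlap,
                 n_segments = as.integer(n_segments),
                 max_lag_windows = as.integer(max_lag_windows)),
            class = "corse_params")
}

# Welch-averaged power spectrum of one window: rectangular (untapered)
# mean-removed segments with 50% overlap, so a sinusoid at a bin centre
# concentrates in a single bin (the single-bin spectrum limit holds
# exactly). Segment length is rounded down to a multiple of 8 so common
# test frequencies (k * fs / 8) sit on bin centres. Returns power per
# positive-frequency bin, DC excluded.
welch_psd <- function(x, n_segments) {
  n <- length(x)
  seg_len <- max(8L, floor(2 * n / (n_segments + 1)))
  seg_len <- max(8L, 8L * (seg_len %/% 8L))
  step <- max(1L, seg_len %/% 2L)
  starts <- seq(1L, n - seg_len + 1L, by = step)
  acc <- NULL
  for (s0 in starts) {
    seg <- x[s0:(s0 + seg_len - 1L)]
    seg <- seg - mean(seg)
    p <- Mod(stats::fft(seg))^2
    half <- p[2:(floor(seg_len / 2) + 1L)]
    acc <- if (is.null(acc)) half else acc + half
  }
  acc / length(starts)
}

#' Windowed spectral-entropy time series
#'
#' Cuts the trace into windows and computes, per window, the Shannon entropy
#' of the normalized power spectrum:
#' \eqn{H = -\sum_k p_k \log p_k / \log K}, where \eqn{p_k} is the power
#' fraction in frequency bin \eqn{k} of \eqn{K} bins. \eqn{H} is 1 for a
#' flat (white) spectrum and 0 when all power sits in one bin; it is
#' invariant under amplitude scaling of the trace. All-zero windows yield
#' \code{NA}.
#'
#' @param trace Numeric trace.
#' @param fs Sampling rate (Hz).
#' @param params \code{\link{corse_params}}.
#' @return Numeric vector, one entropy value in \code{[0, 1]} per window.
#' @export
spectral_entropy_series <- function(trace, fs, params = corse_params()) {
  wlen <- round(params$window_length * fs)
  if (length(trace) < wlen) stop("trace shorter than one window")
  step <- max(1L, round(wlen * (1 - params$window_overlap)))
  starts <- seq(1L, length(trace) - wlen + 1L, by = step)
  vapply(starts, function(s0) {
    w <- trace[s0:(s0 + wlen - 1L)]
    if (all(w == 0)) return(NA_real_)
    p <- welch_psd(w, params$n_segments)
    K <- length(p)
    tot <- sum(p)
    if (tot <= 0) return(NA_real_)
    p <- p / tot
    p <- p[p > 0]
    -sum(p * log(p)) / log(K)
  }, numeric(1))
}

#' CorSE value of one electrode pair
#'
#' Maximum absolute normalized cross-correlation between two mean-removed
#' spectral-entropy series over lags up to \code{max_lag_windows}. Windows
#' undefined in either series are dropped pairwise before correlation.
#'
#' @param se_a,se_b Equal-length entropy series.
#' @param params \code{\link{corse_params}}.
#' @return Value in \code{[0, 1]}; \code{NA} when either series is constant
#'   (zero variance) or fewer than 8 defined windows remain.
#' @export
corse_pair <- function(se_a, se_b, params = corse_params()) {
  stopifnot(length(se_a) == length(se_b))
  ok <- is.finite(se_a) & is.finite(se_b)
  a <- se_a[ok]; b <- se_b[ok]
  n <- length(a)
  if (n < 8) return(NA_real_)
  a <- a - mean(a); b <- b - mean(b)
  da <- sqrt(sum(a^2)); db <- sqrt(sum(b^2))
  if (da == 0 || db == 0) return(NA_real_)
  max_lag <- min(params$max_lag_windows, n - 1L)
  best <- 0
  for (lag in -max_lag:max_lag) {
    if (lag >= 0) {
      ia <- (1 + lag):n; ib <- 1:(n - lag)
    } else {
      ia <- 1:(n + lag); ib <- (1 - lag):n
    }
    r <- abs(sum(a[ia] * b[ib])) / (da * db)
    if (r > best) best <- r
  }
  min(best, 1)
}

#' Full-platform CorSE connectivity
#'
#' Computes the spectral-entropy series of every electrode, evaluates CorSE
#' for all unordered electrode pairs, and averages within each compartment
#' (intracompartmental) and between each compartment pair
#' (intercompartmental). Deterministic for fixed input.
#'
#' @param recording An \code{\link{mea_recording}}.
#' @param params \code{\link{corse_params}}.
#' @return Object of class \code{corse_connectivity}: list with the
#'   symmetric unit-diagonal \code{matrix} (electrode x electrode),
#'   \code{intra} (named per-compartment averages), \code{inter} (named
#'   per-pair averages), \code{n_windows}, and \code{low_confidence}
#'   (TRUE when more than half the pairs are undefined).
#' @export
connectivity_matrix <- function(recording, params = corse_params()) {
  stopifnot(inherits(recording, "mea_recording"))
  fs <- recording$layout$sampling_rate
  labels <- colnames(recording$traces)
  se <- lapply(labels, function(lb)
    spectral_entropy_series(recording$traces[, lb], fs, params))
  names(se) <- labels
  k <- length(labels)
  m <- matrix(NA_real_, k, k, dimnames = list(labels, labels))
  diag(m) <- 1
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    v <- corse_pair(se[[i]], se[[j]], params)
    m[i, j] <- v; m[j, i] <- v
  }
  comp <- recording$layout$electrodes$compartment
  cps <- recording$layout$compartments
  intra <- vapply(cps, function(cp) {
    idx <- which(comp == cp)
    vals <- m[idx, idx][upper.tri(m[idx, idx])]
    mean(vals, na.rm = TRUE)
  }, numeric(1))
  pairs <- utils::combn(cps, 2)
  inter <- vapply(seq_len(ncol(pairs)), function(p) {
    vals <- m[comp == pairs[1, p], comp == pairs[2, p]]
    mean(vals, na.rm = TRUE)
  }, numeric(1))
  names(inter) <- apply(pairs, 2, paste, collapse = "")
  off <- m[upper.tri(m)]
  structure(list(matrix = m, intra = intra, inter = inter,
                 n_windows = length(se[[1]]),
                 low_confidence = mean(is.na(off)) > 0.5),
            class = "corse_connectivity")
}

#' @export
print.corse_connectivity <- function(x, ...) {
  cat(sprintf("CorSE connectivity: %d electrodes, %d windows%s\n",
              nrow(x$matrix), x$n_windows,
              if (x$low_confidence) " [low confidence]" else ""))
  cat("  intracompartmental:",
      paste(sprintf("%s=%.3f", names(x$intra), x$intra), collapse = ", "),
      "\n")
  cat("  intercompartmental:",
      paste(sprintf("%s=%.3f", names(x$inter), x$inter), collapse = ", "),
      "\n")
  invisible(x)
}

#' Percent change of connectivity averages
#'
#' @param before,after \code{corse_connectivity} results on the same layout.
#' @return Named vector of six percent changes (three intra-, three
#'   intercompartmental), \code{100 * (after - before) / before};
#'   \code{NA} where the baseline average is undefined or zero. Use
#'   \code{\link{clip_percent_change}} for the +/-50 display clipping.
#' @export
connectivity_percent_change <- function(before, after) {
  stopifnot(inherits(before, "corse_connectivity"),
            inherits(after, "corse_connectivity"),
            identical(names(before$intra), names(after$intra)))
  b <- c(before$intra, before$inter)
  a <- c(after$intra, after$inter)
  out <- 100 * (a - b) / b
  out[!is.finite(out) | is.na(b) | b == 0] <- NA_real_
  out
}
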