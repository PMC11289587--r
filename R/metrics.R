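#' The eight burst output parameters
#'
#' Computes the eight output parameters characterizing a set of detected
#' bursts (network bursts of one compartment, or circuitry bursts of the
#' whole platform): mean inter-burst interval (IBI, gap from one burst's end
#' to the next burst's start), mean burst duration, mean spike frequency in
#' bursts (per-burst spike count over duration, averaged), percentage of
#' spikes in bursts (relative to all spikes in scope), mean spikes in
#' bursts, total number of bursts, mean channels in bursts (electrodes with
#' at least one spike in the burst window) and mean dominating channels in
#' bursts (electrodes meeting the minimum individual channel contribution
#' criterion within the burst window).
#'
#' Parameters that are not defined for the data are reported as \code{NA},
#' never as silent zeros: all means when there are no bursts, the mean IBI
#' when there are fewer than two.
#'
#' @param bursts Burst table with \code{start}/\code{end} columns (an NB or
#'   CB table).
#' @param spikes A \code{\link{spike_list}}.
#' @param compartment Scope: a compartment id for NB-level parameters, or
#'   \code{NULL} for platform scope (CB level; all electrodes pooled).
#' @param params \code{\link{nb_detection_params}} supplying the
#'   contribution criterion.
#' @param frequency \code{"per_burst"} (default) averages per-burst rates;
#'   \code{"pooled"} divides total in-burst spikes by total burst time.
#' @param ibi \code{"end_to_start"} (default) or \code{"start_to_start"}.
#' @return Named numeric vector of class \code{burst_parameters} with
#'   elements \code{mean_ibi}, \code{mean_burst_duration},
#'   \code{mean_spike_frequency_in_bursts}, \code{percent_spikes_in_bursts},
#'   \code{mean_spikes_in_bursts}, \code{total_bursts},
#'   \code{mean_channels_in_bursts},
#'   \code{mean_dominating_channels_in_bursts}.
#' @export
burst_parameters <- function(bursts, spikes, compartment = NULL,
                             params = nb_detection_params(),
                             frequency = c("per_burst", "pooled"),
                             ibi = c("end_to_start", "start_to_start")) {
  frequency <- match.arg(frequency)
  ibi <- match.arg(ibi)
  stopifnot(inherits(spikes, "spike_list"))
  labels <- if (is.null(compartment)) electrode_labels(spikes$layout)
            else electrode_labels(spikes$layout, compartment)
  n <- nrow(bursts)
  out <- c(mean_ibi = NA_real_, mean_burst_duration = NA_real_,
           mean_spike_frequency_in_bursts = NA_real_,
           percent_spikes_in_bursts = NA_real_,
           mean_spikes_in_bursts = NA_real_, total_bursts = n,
           mean_channels_in_bursts = NA_real_,
           mean_dominating_channels_in_bursts = NA_real_)
  class(out) <- "burst_parameters"
  if (n == 0) return(out)
  dur <- bursts$end - bursts$start
  counts <- matrix(0, nrow = n, ncol = length(labels),
                   dimnames = list(NULL, labels))
  for (lb in labels) {
    ts <- spikes$spikes[[lb]]
    if (!length(ts)) next
    counts[, lb] <- vapply(seq_len(n), function(i)
      sum(ts >= bursts$start[i] & ts <= bursts$end[i]), numeric(1))
  }
  spikes_in <- rowSums(counts)
  total_spikes <- sum(vapply(spikes$spikes[labels], length, integer(1)))
  participating <- rowSums(counts >= 1)
  dominating <- vapply(seq_len(n), function(i) {
    denom <- if (params$contribution_denominator == "participating")
      participating[i] else length(labels)
    if (denom == 0) return(0)
    cutoff <- params$min_contribution_fraction * spikes_in[i] / denom
    sum(counts[i, ] >= cutoff & counts[i, ] >= 1)
  }, numeric(1))
  if (n >= 2) {
    out["mean_ibi"] <- if (ibi == "end_to_start")
      mean(bursts$start[-1] - bursts$end[-n])
    else mean(diff(bursts$start))
  }
  out["mean_burst_duration"] <- mean(dur)
  out["mean_spike_frequency_in_bursts"] <- if (frequency == "per_burst")
    mean(spikes_in / dur) else sum(spikes_in) / sum(dur)
  out["percent_spikes_in_bursts"] <- if (total_spikes > 0)
    100 * sum(spikes_in) / total_spikes else NA_real_
  out["mean_spikes_in_bursts"] <- mean(spikes_in)
  out["mean_channels_in_bursts"] <- mean(participating)
  out["mean_dominating_channels_in_bursts"] <- mean(dominating)
  out
}

#' @export
print.burst_parameters <- function(x, ...) {
  cat("Burst output parameters:\n")
  v <- unclass(x)
  for (nm in names(v))
    cat(sprintf("  %-36s %s\n", nm,
                ifelse(is.na(v[nm]), "undefined", format(v[nm], digits = 5))))
  invisible(x)
}

# Exact two-sided signed-rank p-value by dynamic programming over the
# distribution of the positive-midrank sum. Midranks make all achievable
# sums multiples of 0.5, so the distribution table stays tiny even with
# ties.
signed_rank_exact_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(1)
  r <- rank(abs(d))              # midranks; ties allowed
  w <- sum(r[d > 0])
  grid <- round(2 * r)           # integer half-rank units
  total <- sum(grid)
  probs <- numeric(total + 1)    # index k+1 <-> sum k (in half units)
  probs[1] <- 1
  for (g in grid) {
    shifted <- c(rep(0, g), probs[seq_len(total + 1 - g)])
    probs <- (probs + shifted) / 2
  }
  wgrid <- round(2 * w)
  # two-sided: double the smaller tail (including the observed sum)
  lower <- sum(probs[seq_len(wgrid + 1)])
  upper <- sum(probs[(wgrid + 1):(total + 1)])
  min(1, 2 * min(lower, upper))
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided Wilcoxon matched-pairs signed-rank test for before/after
#' comparisons across plates. Zero differences are dropped (the zero-drop
#' convention); for \code{n <= 25} remaining pairs the exact distribution of
#' the signed-rank sum is used (computed by convolution, so ties are handled
#' exactly); larger samples fall back to the normal approximation with
#' continuity correction via \code{stats::wilcox.test}.
#'
#' @param before,after Equal-length paired numeric vectors.
#' @return The two-sided p-value. If all differences are zero, 1 with a
#'   warning.
#' @export
paired_wilcoxon <- function(before, after) {
  stopifnot(length(before) == length(after))
  ok <- is.finite(before) & is.finite(after)
  d <- after[ok] - before[ok]
  d <- d[d != 0]
  if (!length(d)) {
    warning("all paired differences are zero; p = 1")
    return(1)
  }
  if (length(d) <= 25) {
    signed_rank_exact_p(d)
  } else {
    suppressWarnings(stats::wilcox.test(d, exact = FALSE,
                                        correct = TRUE))$p.value
  }
}

#' Bonferroni-adjusted significance level
#'
#' @param alpha Family-wise significance level (default 0.05).
#' @param m Number of hypotheses in the family (default 8, the number of
#'   burst output parameters).
#' @return \code{alpha / m}; e.g. 0.05 / 8 = 0.00625.
#' @export
bonferroni_alpha <- function(alpha = 0.05, m = 8) {
  stopifnot(alpha > 0, alpha <= 1, m >= 1)
  alpha / m
}

#' Paired before/after comparison of the eight parameters
#'
#' @param before,after Matrices or data frames, plates x parameters, with
#'   matching column names (e.g. rows of \code{\link{burst_parameters}}
#'   values per plate).
#' @param alpha Family-wise level (default 0.05); the Bonferroni-adjusted
#'   level uses the number of parameter columns as the family size.
#' @return Data frame with one row per parameter: \code{parameter},
#'   \code{p_value}, \code{adjusted_alpha}, \code{significant_raw},
#'   \code{significant_adjusted}.
#' @export
compare_parameters <- function(before, after, alpha = 0.05) {
  before <- as.matrix(before); after <- as.matrix(after)
  stopifnot(identical(colnames(before), colnames(after)),
            nrow(before) == nrow(after))
  adj <- bonferroni_alpha(alpha, ncol(before))
  p <- vapply(colnames(before), function(nm)
    paired_wilcoxon(before[, nm], after[, nm]), numeric(1))
  data.frame(parameter = colnames(before), p_value = unname(p),
             adjusted_alpha = adj,
             significant_raw = unname(p) < alpha,
             significant_adjusted = unname(p) < adj,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Per-bin burst parameters over a recording
#'
#' Segments the recording into whole bins of \code{bin_width} seconds and
#' computes the eight parameters per bin. A burst is assigned to the bin
#' containing its start; spikes for the percentage denominator are those
#' falling in the bin.
#'
#' @param bursts Burst table with \code{start}/\code{end}.
#' @param spikes A \code{\link{spike_list}}.
#' @param compartment Scope (as in \code{\link{burst_parameters}}).
#' @param bin_width Bin width in seconds (default 300, i.e. 5 min).
#' @param params \code{\link{nb_detection_params}}.
#' @return Matrix, parameters x bins; columns named by bin start time.
#' @export
binned_parameters <- function(bursts, spikes, compartment = NULL,
                              bin_width = 300,
                              params = nb_detection_params()) {
  stopifnot(bin_width > 0)
  n_bins <- floor(spikes$duration / bin_width)
  if (n_bins < 1) stop("recording shorter than one bin")
  cols <- lapply(seq_len(n_bins), function(k) {
    lo <- (k - 1) * bin_width; hi <- k * bin_width
    sel <- bursts$start >= lo & bursts$start < hi
    sub_spikes <- spikes
    sub_spikes$spikes <- lapply(spikes$spikes, function(ts)
      ts[ts >= lo & ts < hi])
    unclass(burst_parameters(bursts[sel, , drop = FALSE], sub_spikes,
                             compartment, params))
  })
  m <- do.call(cbind, cols)
  colnames(m) <- sprintf("%g", (seq_len(n_bins) - 1) * bin_width)
  m
}

#' Percent change of binned parameters against the last baseline bin
#'
#' The last bin of the baseline matrix serves as the reference; each
#' exposure bin's parameters are expressed as
#' \code{100 * (value - reference) / reference}. Values are \emph{not}
#' clipped here; \code{\link{clip_percent_change}} applies the +/-50 percent
#' display clipping used for heatmap rendering.
#'
#' @param baseline,exposure Matrices from \code{\link{binned_parameters}}
#'   (parameters x bins).
#' @return Matrix, parameters x exposure bins, of percent changes;
#'   \code{NA} where the reference is undefined or zero.
#' @export
binned_percent_change <- function(baseline, exposure) {
  stopifnot(is.matrix(baseline), is.matrix(exposure),
            identical(rownames(baseline), rownames(exposure)))
  ref <- baseline[, ncol(baseline)]
  out <- 100 * sweep(exposure, 1, ref, "-") / ref
  out[!is.finite(out)] <- NA_real_
  out[is.na(ref) | ref == 0, ] <- NA_real_
  out
}

#' Clip percent changes for heatmap display
#'
#' @param x Percent-change matrix or vector.
#' @param limit Symmetric display limit (default 50).
#' @return \code{x} clipped to \code{[-limit, limit]}.
#' @export
clip_percent_change <- function(x, limit = 50) {
  pmin(pmax(x, -limit), limit)
}
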