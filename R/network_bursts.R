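#' Network-burst detection parameters
#'
#' Parameters of the compartment-level network-burst (NB) detector: the
#' ISI_N-threshold core plus adaptive merging, optional short-burst removal,
#' and the channel-participation criteria.
#'
#' @param N Number of consecutive spikes spanned by each ISI_N value
#'   (default 20).
#' @param merging_fraction Adaptive merging fraction: two neighbouring bursts
#'   are merged when the gap between them is smaller than the duration of the
#'   longer of the two multiplied by this fraction (default 0.2).
#' @param min_duration Minimum burst duration in seconds, or \code{NULL} to
#'   disable short-burst removal (default; removal was not needed for the
#'   kind of data this tool targets).
#' @param min_channels Minimum number of dominating channels needed to
#'   constitute an NB (default 3).
#' @param min_contribution_fraction Minimum individual channel contribution,
#'   as a fraction of the mean channel contribution within the burst
#'   (default 0.15).
#' @param histogram_bins_per_decade Bins per decade of the log10 ISI_N
#'   histogram (default 40).
#' @param smoothing_sd_bins Gaussian smoothing SD of the histogram, in bins
#'   (default 2).
#' @param peak_prominence_fraction A histogram local maximum counts as a peak
#'   only if its smoothed height exceeds this fraction of the global maximum
#'   (default 0.01).
#' @param contribution_denominator \code{"participating"} (default): the mean
#'   channel contribution divides the burst spike count by the number of
#'   channels with at least one spike; \code{"all"} divides by all channels
#'   in scope.
#' @return A list of class \code{nb_detection_params}.
#' @export
nb_detection_params <- function(N = 20L, merging_fraction = 0.2,
                                min_duration = NULL, min_channels = 3L,
                                min_contribution_fraction = 0.15,
                                histogram_bins_per_decade = 40L,
                                smoothing_sd_bins = 2,
                                peak_prominence_fraction = 0.01,
                                contribution_denominator = c("participating",
                                                             "all")) {
  contribution_denominator <- match.arg(contribution_denominator)
  stopifnot(N >= 2, merging_fraction >= 0, min_channels >= 1,
            min_contribution_fraction >= 0, min_contribution_fraction <= 1,
            histogram_bins_per_decade >= 4, smoothing_sd_bins >= 0)
  if (!is.null(min_duration)) stopifnot(min_duration >= 0)
  structure(list(N = as.integer(N), merging_fraction = merging_fraction,
                 min_duration = min_duration,
                 min_channels = as.integer(min_channels),
                 min_contribution_fraction = min_contribution_fraction,
                 histogram_bins_per_decade = as.integer(histogram_bins_per_decade),
                 smoothing_sd_bins = smoothing_sd_bins,
                 peak_prominence_fraction = peak_prominence_fraction,
                 contribution_denominator = contribution_denominator),
            class = "nb_detection_params")
}

#' Pool all spikes of one compartment into a single train
#'
#' @param spikes A \code{\link{spike_list}}.
#' @param compartment Compartment id.
#' @return Sorted numeric vector: the multiset union of the compartment's
#'   electrode trains.
#' @export
pool_compartment_spikes <- function(spikes, compartment) {
  stopifnot(inherits(spikes, "spike_list"))
  lb <- electrode_labels(spikes$layout, compartment)
  sort(unlist(spikes$spikes[lb], use.names = FALSE))
}

#' ISI_N values of a pooled spike train
#'
#' Value \code{i} is the time span covered by \code{N} consecutive spikes,
#' \code{t[i + N - 1] - t[i]}.
#'
#' @param train Sorted spike-time vector.
#' @param N Spike span.
#' @return Numeric vector of length \code{length(train) - N + 1} (empty when
#'   the train is shorter than \code{N}).
#' @export
isi_n_values <- function(train, N) {
  N <- as.integer(N)
  stopifnot(N >= 2)
  n <- length(train)
  if (n < N) return(numeric(0))
  train[N:n] - train[1:(n - N + 1L)]
}

# Gaussian-smoothed histogram of log10(values); returns list(mids, counts).
log_isi_histogram <- function(values, bins_per_decade, smoothing_sd_bins) {
  lv <- log10(values[values > 0])
  bw <- 1 / bins_per_decade
  lo <- floor(min(lv) / bw) * bw - bw / 2
  nb <- ceiling((max(lv) - lo) / bw) + 1L
  breaks <- lo + bw * (0:nb)
  counts <- tabulate(findInterval(lv, breaks, rightmost.closed = TRUE),
                     nbins = nb)
  if (smoothing_sd_bins > 0) {
    half <- ceiling(4 * smoothing_sd_bins)
    k <- stats::dnorm(-half:half, sd = smoothing_sd_bins)
    k <- k / sum(k)
    padded <- c(rep(0, half), counts, rep(0, half))
    sm <- stats::filter(padded, k, sides = 2)
    counts <- as.numeric(sm[(half + 1):(half + nb)])
  }
  list(mids = lo + bw * (seq_len(nb) - 0.5), counts = counts)
}

#' ISI_N threshold from the bimodal log-histogram
#'
#' Builds the histogram of \code{log10(ISI_N)}, smooths it with a Gaussian
#' kernel, locates the two highest local maxima (assumed to represent
#' in-burst and out-of-burst firing regimes), and returns the abscissa of the
#' minimum strictly between them, converted back to seconds. If fewer than
#' two peaks are found the train is treated as unimodal: \code{NA} is
#' returned with attribute \code{unimodal = TRUE}.
#'
#' @param values ISI_N values (seconds) from \code{\link{isi_n_values}}.
#' @param params \code{\link{nb_detection_params}}.
#' @return Threshold in seconds, or \code{NA} with attribute
#'   \code{unimodal = TRUE}.
#' @export
isi_n_threshold <- function(values, params = nb_detection_params()) {
  if (!length(values)) stop("insufficient spikes: no ISI_N values")
  h <- log_isi_histogram(values, params$histogram_bins_per_decade,
                         params$smoothing_sd_bins)
  cnt <- h$counts
  nb <- length(cnt)
  if (nb < 3) return(structure(NA_real_, unimodal = TRUE))
  ext <- c(0, cnt, 0)  # treat range ends as valleys
  is_max <- cnt >= ext[1:nb] & cnt > ext[3:(nb + 2)] &
    cnt > params$peak_prominence_fraction * max(cnt)
  peaks <- which(is_max)
  if (length(peaks) < 2) return(structure(NA_real_, unimodal = TRUE))
  top2 <- peaks[order(-cnt[peaks])][1:2]
  lo <- min(top2); hi <- max(top2)
  if (hi - lo < 2) return(structure(NA_real_, unimodal = TRUE))
  between <- (lo + 1):(hi - 1)
  valley <- between[which.min(cnt[between])]
  10^h$mids[valley]
}

#' Initial NB detection from the ISI_N threshold (STEP 1)
#'
#' Maximal runs of window start indices \code{i} with
#' \code{t[i + N - 1] - t[i] <= threshold} form bursts; a burst starts at the
#' first spike of its first qualifying window and ends at the last spike of
#' its last qualifying window.
#'
#' @param train Sorted pooled spike train (s).
#' @param N Spike span.
#' @param threshold ISI_N threshold (s).
#' @return Data frame with columns \code{start}, \code{end}; disjoint and
#'   time-ordered.
#' @export
detect_nb_initial <- function(train, N, threshold) {
  stopifnot(is.finite(threshold), threshold > 0)
  v <- isi_n_values(train, N)
  ok <- which(v <= threshold)
  if (!length(ok))
    return(data.frame(start = numeric(0), end = numeric(0)))
  run_break <- which(diff(ok) > 1L)
  first <- ok[c(1L, run_break + 1L)]
  last <- ok[c(run_break, length(ok))]
  data.frame(start = train[first], end = train[last + N - 1L])
}

#' Adaptive merging of neighbouring bursts (STEP 2)
#'
#' Two consecutive bursts are merged when the inter-burst gap (end of the
#' first to start of the next) is smaller than \code{merging_fraction} times
#' the duration of the longer of the two; the procedure repeats until no
#' further merge applies.
#'
#' @param bursts Data frame with \code{start}, \code{end}, disjoint and
#'   ordered.
#' @param merging_fraction Merging fraction (default 0.2).
#' @return Merged burst data frame, disjoint and ordered.
#' @export
merge_adjacent_bursts <- function(bursts, merging_fraction = 0.2) {
  if (nrow(bursts) < 2 || merging_fraction <= 0) return(bursts)
  repeat {
    s <- bursts$start; e <- bursts$end
    n <- length(s)
    gap <- s[-1] - e[-n]
    dmax <- pmax(e[-n] - s[-n], e[-1] - s[-1])
    hit <- which(gap < merging_fraction * dmax)
    if (!length(hit)) return(bursts)
    i <- hit[1]
    bursts <- data.frame(
      start = c(s[seq_len(i - 1)], s[i], s[-seq_len(i + 1)]),
      end = c(e[seq_len(i - 1)], e[i + 1], e[-seq_len(i + 1)])
    )
  }
}

#' Remove very short bursts (STEP 3)
#'
#' @param bursts Data frame with \code{start}, \code{end}.
#' @param min_duration Minimum duration (s); \code{NULL} (default) disables
#'   removal.
#' @return Filtered burst data frame.
#' @export
remove_short_bursts <- function(bursts, min_duration = NULL) {
  if (is.null(min_duration) || min_duration <= 0) return(bursts)
  bursts[bursts$end - bursts$start >= min_duration, , drop = FALSE]
}

#' Channel participation and contribution criteria (STEPS 4-5)
#'
#' For each candidate burst, counts spikes per electrode inside
#' \code{[start, end]}; electrodes with at least one spike participate. The
#' mean channel contribution is the burst spike count divided by the number
#' of participating channels (configurable to all channels in scope).
#' Electrodes whose count reaches \code{min_contribution_fraction} times the
#' mean contribution dominate the burst; bursts with fewer than
#' \code{min_channels} dominating channels are rejected.
#'
#' @param bursts Data frame with \code{start}, \code{end}.
#' @param spikes A \code{\link{spike_list}}.
#' @param compartment Compartment id giving the electrode scope, or
#'   \code{NULL} to use all electrodes of the layout (platform scope).
#' @param params \code{\link{nb_detection_params}}.
#' @return A \code{network_bursts} data frame with columns
#'   \code{compartment}, \code{start}, \code{end}, \code{spike_count},
#'   \code{n_participating}, \code{n_dominating}, plus list columns
#'   \code{per_channel_counts}, \code{participating}, \code{dominating}.
#' @export
apply_channel_criteria <- function(bursts, spikes, compartment,
                                   params = nb_detection_params()) {
  stopifnot(inherits(spikes, "spike_list"))
  labels <- if (is.null(compartment)) electrode_labels(spikes$layout)
            else electrode_labels(spikes$layout, compartment)
  out <- vector("list", nrow(bursts))
  keep <- logical(nrow(bursts))
  for (i in seq_len(nrow(bursts))) {
    s <- bursts$start[i]; e <- bursts$end[i]
    cnt <- vapply(spikes$spikes[labels], function(ts)
      sum(ts >= s & ts <= e), numeric(1))
    participating <- names(cnt)[cnt >= 1]
    denom <- if (params$contribution_denominator == "participating")
      length(participating) else length(labels)
    mean_contrib <- if (denom > 0) sum(cnt) / denom else 0
    cutoff <- params$min_contribution_fraction * mean_contrib
    dominating <- names(cnt)[cnt >= cutoff & cnt >= 1]
    keep[i] <- length(dominating) >= params$min_channels
    out[[i]] <- list(counts = cnt, participating = participating,
                     dominating = dominating)
  }
  res <- data.frame(
    compartment = rep(if (is.null(compartment)) NA_character_ else compartment,
                      sum(keep)),
    start = bursts$start[keep], end = bursts$end[keep],
    spike_count = vapply(out[keep], function(z) sum(z$counts), numeric(1)),
    n_participating = vapply(out[keep], function(z)
      length(z$participating), integer(1)),
    n_dominating = vapply(out[keep], function(z)
      length(z$dominating), integer(1)),
    stringsAsFactors = FALSE
  )
  res$per_channel_counts <- lapply(out[keep], `[[`, "counts")
  res$participating <- lapply(out[keep], `[[`, "participating")
  res$dominating <- lapply(out[keep], `[[`, "dominating")
  class(res) <- c("network_bursts", "data.frame")
  res
}

#' Detect network bursts in one compartment (STEPS 1-5)
#'
#' Pools the compartment's spikes, derives the ISI_N threshold from the
#' bimodal log-histogram, detects initial bursts, merges adjacent ones,
#' optionally removes very short ones, and applies the channel criteria. If
#' the ISI_N histogram is unimodal no bursts are reported for the
#' compartment and a diagnostic message is emitted (no silent fixed
#' threshold is substituted).
#'
#' @param spikes A \code{\link{spike_list}}.
#' @param compartment Compartment id.
#' @param params \code{\link{nb_detection_params}}.
#' @return A \code{network_bursts} data frame (possibly zero rows), with the
#'   derived threshold in attribute \code{isi_n_threshold}.
#' @export
detect_network_bursts <- function(spikes, compartment,
                                  params = nb_detection_params()) {
  train <- pool_compartment_spikes(spikes, compartment)
  empty <- apply_channel_criteria(
    data.frame(start = numeric(0), end = numeric(0)), spikes, compartment,
    params)
  if (length(train) < params$N) {
    attr(empty, "isi_n_threshold") <- NA_real_
    return(empty)
  }
  thr <- isi_n_threshold(isi_n_values(train, params$N), params)
  if (is.na(thr)) {
    message(sprintf(
      "compartment %s: unimodal ISI_N histogram, no network bursts reported",
      compartment))
    attr(empty, "isi_n_threshold") <- NA_real_
    return(empty)
  }
  b <- detect_nb_initial(train, params$N, thr)
  b <- merge_adjacent_bursts(b, params$merging_fraction)
  b <- remove_short_bursts(b, params$min_duration)
  res <- apply_channel_criteria(b, spikes, compartment, params)
  attr(res, "isi_n_threshold") <- thr
  res
}

#' @export
print.network_bursts <- function(x, ...) {
  cat(sprintf("Network bursts: %d events%s\n", nrow(x),
              if (nrow(x) && !is.na(x$compartment[1]))
                paste0(" in compartment ", x$compartment[1]) else ""))
  if (nrow(x)) {
    cat(sprintf("  mean duration %.3f s, mean spikes %.1f, mean channels %.1f\n",
                mean(x$end - x$start), mean(x$spike_count),
                mean(x$n_participating)))
    thr <- attr(x, "isi_n_threshold")
    if (!is.null(thr) && !is.na(thr))
      cat(sprintf("  ISI_N threshold: %.4f s\n", thr))
  }
  invisible(x)
}
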