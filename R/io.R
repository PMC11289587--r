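#' Write a raw recording to HDF5
#'
#' The container schema is defined by this package: datasets \code{/traces}
#' (samples x channels, microvolts, 64-bit float), \code{/electrodes}
#' (channel labels in column order) and \code{/sampling_rate} (Hz), plus a
#' root attribute \code{units = "uV"}. \code{\link{read_raw_h5}} accepts this
#' schema and, through its \code{channel_map} argument, containers from other
#' dialects whose dataset names differ.
#'
#' @param recording An \code{\link{mea_recording}}.
#' @param path Output file path; overwritten if present.
#' @return \code{path}, invisibly.
#' @export
write_raw_h5 <- function(recording, path) {
  stopifnot(inherits(recording, "mea_recording"))
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  rhdf5::h5write(recording$traces, path, "traces")
  rhdf5::h5write(colnames(recording$traces), path, "electrodes")
  rhdf5::h5write(recording$layout$sampling_rate, path, "sampling_rate")
  fid <- rhdf5::H5Fopen(path)
  rhdf5::h5writeAttribute("uV", fid, "units")
  rhdf5::H5Fclose(fid)
  invisible(path)
}

#' Read a raw recording from HDF5
#'
#' @param path HDF5 file written by \code{\link{write_raw_h5}} or a compatible
#'   container.
#' @param layout The \code{\link{platform_layout}} the file must match; the
#'   channel-to-electrode assignment is taken from the file's electrode-label
#'   dataset and checked against the layout.
#' @param channel_map Optional named list overriding the dataset names, with
#'   elements \code{traces}, \code{electrodes}, \code{sampling_rate}.
#' @return An \code{\link{mea_recording}}.
#' @export
read_raw_h5 <- function(path, layout,
                        channel_map = list(traces = "traces",
                                           electrodes = "electrodes",
                                           sampling_rate = "sampling_rate")) {
  stopifnot(inherits(layout, "mea_layout"))
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  traces <- rhdf5::h5read(path, channel_map$traces)
  labels <- as.character(rhdf5::h5read(path, channel_map$electrodes))
  fs <- as.numeric(rhdf5::h5read(path, channel_map$sampling_rate))
  if (!isTRUE(all.equal(fs, layout$sampling_rate)))
    stop(sprintf("sampling rate mismatch: file %g Hz, layout %g Hz",
                 fs, layout$sampling_rate))
  expected <- layout$electrodes$label
  missing <- setdiff(expected, labels)
  if (length(missing))
    stop(sprintf("missing electrode channel(s): %s",
                 paste(missing, collapse = ", ")))
  extra <- setdiff(labels, expected)
  if (length(extra))
    stop(sprintf("unexpected electrode channel(s): %s",
                 paste(extra, collapse = ", ")))
  traces <- as.matrix(traces)
  if (ncol(traces) != length(labels))
    stop("trace matrix does not match electrode label count")
  colnames(traces) <- labels
  mea_recording(layout, traces[, expected, drop = FALSE])
}

#' Read a spike-list CSV
#'
#' Expects a UTF-8 CSV with header \code{electrode,timestamp_s}; each row is
#' one detected spike. Rows are grouped by electrode and sorted in time;
#' exact duplicate timestamps within an electrode are removed with a warning.
#'
#' @param path CSV file path.
#' @param layout The \code{\link{platform_layout}}; rows with labels outside
#'   the layout are rejected.
#' @param duration Recording duration in seconds. If \code{NULL}, taken as
#'   the latest timestamp (or 0-spike files are rejected since the duration
#'   is then undefined).
#' @return A \code{\link{spike_list}}.
#' @export
read_spike_csv <- function(path, layout, duration = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c("character", "numeric"))
  if (!identical(names(df), c("electrode", "timestamp_s")))
    stop("expected CSV header 'electrode,timestamp_s'")
  bad <- which(!is.finite(df$timestamp_s))
  if (length(bad))
    stop(sprintf("unparseable timestamp at data row %d", bad[1]))
  if (is.null(duration)) {
    if (!nrow(df))
      stop("cannot infer duration from an empty spike list; pass duration=")
    duration <- max(df$timestamp_s)
  }
  spikes <- split(df$timestamp_s, df$electrode)
  spike_list(layout, spikes, duration)
}

#' Write a spike-list CSV
#'
#' @param spikes A \code{\link{spike_list}}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_spike_csv <- function(spikes, path) {
  stopifnot(inherits(spikes, "spike_list"))
  n <- vapply(spikes$spikes, length, integer(1))
  df <- data.frame(
    electrode = rep(names(spikes$spikes), times = n),
    timestamp_s = unlist(spikes$spikes, use.names = FALSE),
    stringsAsFactors = FALSE
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Flag intervals of suspiciously intense platform-wide firing
#'
#' Recordings with prolonged stretches of excessive spiking spreading over
#' most electrodes at once are usually of non-biological origin. This check
#' bins each electrode's spike train, normalizes counts to rates, and flags
#' bins in which the rate exceeds \code{rate_limit} on more than
#' \code{min_channels_fraction} of the electrodes simultaneously. Flagged
#' recordings are surfaced for review, never dropped automatically.
#'
#' @param spikes A \code{\link{spike_list}}.
#' @param bin_width Bin width in seconds (default 1).
#' @param rate_limit Per-electrode firing-rate limit in Hz (default 40).
#' @param min_channels_fraction Fraction of electrodes that must exceed the
#'   limit simultaneously for a bin to be flagged (default 0.75).
#' @return Data frame of flagged bins with columns \code{start}, \code{end},
#'   \code{n_channels_over} and \code{fraction_over}; zero rows means clean.
#' @export
flag_noisy_bins <- function(spikes, bin_width = 1, rate_limit = 40,
                            min_channels_fraction = 0.75) {
  stopifnot(inherits(spikes, "spike_list"), bin_width > 0)
  n_bins <- max(1L, ceiling(spikes$duration / bin_width))
  breaks <- seq(0, n_bins * bin_width, by = bin_width)
  n_el <- length(spikes$spikes)
  over <- integer(n_bins)
  for (ts in spikes$spikes) {
    if (!length(ts)) next
    cnt <- tabulate(findInterval(ts, breaks, rightmost.closed = TRUE,
                                 left.open = TRUE) + (ts == 0), nbins = n_bins)
    over <- over + as.integer(cnt / bin_width > rate_limit)
  }
  hit <- which(over / n_el > min_channels_fraction)
  data.frame(start = breaks[hit], end = pmin(breaks[hit] + bin_width,
                                             spikes$duration),
             n_channels_over = over[hit],
             fraction_over = over[hit] / n_el)
}
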