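#' Describe a compartmentalized MEA platform
#'
#' Builds the data model for a multi-compartment MEA platform: an ordered set
#' of compartments, each carrying the same number of electrodes, recorded at a
#' common sampling rate. The default corresponds to a circular tripartite
#' platform with three compartments (A, B, C) of 24 electrodes each sampled at
#' 25 kHz. Electrode labels are the compartment letter followed by the
#' zero-padded electrode index, e.g. \code{"A07"}.
#'
#' @param compartments Character vector of compartment identifiers (single
#'   letters by convention).
#' @param electrodes_per_compartment Number of electrodes in each compartment.
#' @param sampling_rate Sampling rate of the raw acquisition, in Hz.
#' @param plate_id Optional plate/platform identification code (e.g. "N2698").
#'
#' @return An object of class \code{mea_layout}: a list with elements
#'   \code{compartments}, \code{electrodes_per_compartment},
#'   \code{sampling_rate}, \code{plate_id} and an \code{electrodes} data frame
#'   (columns \code{label}, \code{compartment}, \code{index}).
#' @examples
#' lay <- platform_layout()
#' lay$electrodes$label[1:3]
#' @export
platform_layout <- function(compartments = c("A", "B", "C"),
                            electrodes_per_compartment = 24L,
                            sampling_rate = 25000,
                            plate_id = NA_character_) {
  compartments <- as.character(compartments)
  if (anyDuplicated(compartments))
    stop("compartment identifiers must be unique")
  electrodes_per_compartment <- as.integer(electrodes_per_compartment)
  if (electrodes_per_compartment < 1L)
    stop("electrodes_per_compartment must be >= 1")
  if (!is.numeric(sampling_rate) || sampling_rate <= 0)
    stop("sampling_rate must be a positive number (Hz)")
  idx <- seq_len(electrodes_per_compartment) - 1L
  electrodes <- data.frame(
    label = as.vector(vapply(compartments, function(cp)
      sprintf("%s%02d", cp, idx), character(electrodes_per_compartment))),
    compartment = rep(compartments, each = electrodes_per_compartment),
    index = rep(idx, times = length(compartments)),
    stringsAsFactors = FALSE
  )
  structure(
    list(compartments = compartments,
         electrodes_per_compartment = electrodes_per_compartment,
         sampling_rate = sampling_rate,
         plate_id = plate_id,
         electrodes = electrodes),
    class = "mea_layout"
  )
}

#' @export
print.mea_layout <- function(x, ...) {
  cat(sprintf("MEA platform layout%s\n",
              if (is.na(x$plate_id)) "" else paste0(" [", x$plate_id, "]")))
  cat(sprintf("  compartments: %s (%d electrodes each, %d total)\n",
              paste(x$compartments, collapse = ", "),
              x$electrodes_per_compartment, nrow(x$electrodes)))
  cat(sprintf("  sampling rate: %g Hz\n", x$sampling_rate))
  invisible(x)
}

#' Electrode labels of a layout
#'
#' @param layout An \code{mea_layout}.
#' @param compartment Optional compartment id; restrict labels to it.
#' @return Character vector of electrode labels.
#' @export
electrode_labels <- function(layout, compartment = NULL) {
  stopifnot(inherits(layout, "mea_layout"))
  if (is.null(compartment)) return(layout$electrodes$label)
  if (!compartment %in% layout$compartments)
    stop(sprintf("unknown compartment '%s'", compartment))
  layout$electrodes$label[layout$electrodes$compartment == compartment]
}

#' Decode an electrode label into compartment and index
#'
#' @param label Character vector of labels such as "A07".
#' @param layout An \code{mea_layout} used to validate the labels.
#' @return Data frame with columns \code{label}, \code{compartment},
#'   \code{index}.
#' @export
decode_electrode <- function(label, layout) {
  stopifnot(inherits(layout, "mea_layout"))
  m <- match(label, layout$electrodes$label)
  if (anyNA(m))
    stop(sprintf("unknown electrode label(s): %s",
                 paste(unique(label[is.na(m)]), collapse = ", ")))
  layout$electrodes[m, , drop = FALSE]
}

#' Construct a per-electrode spike list set
#'
#' The central currency of the pipeline: sorted spike timestamps (seconds from
#' recording start) for every electrode of a layout.
#'
#' @param layout An \code{mea_layout}.
#' @param spikes Named list mapping electrode labels to numeric timestamp
#'   vectors; electrodes absent from the list are taken as silent. Timestamps
#'   are sorted; exact duplicates within an electrode are dropped with a
#'   warning.
#' @param duration Recording duration in seconds; every timestamp must lie in
#'   \code{[0, duration]}.
#' @return An object of class \code{spike_list}.
#' @export
spike_list <- function(layout, spikes = list(), duration) {
  stopifnot(inherits(layout, "mea_layout"))
  if (!is.numeric(duration) || length(duration) != 1L || duration <= 0)
    stop("duration must be a single positive number (seconds)")
  labels <- layout$electrodes$label
  unknown <- setdiff(names(spikes), labels)
  if (length(unknown))
    stop(sprintf("unknown electrode label(s): %s",
                 paste(unknown, collapse = ", ")))
  out <- stats::setNames(vector("list", length(labels)), labels)
  for (lb in labels) {
    ts <- as.numeric(spikes[[lb]])
    if (length(ts)) {
      if (any(!is.finite(ts)) || any(ts < 0) || any(ts > duration))
        stop(sprintf("electrode %s: timestamps must be finite and within [0, %g]",
                     lb, duration))
      ts <- sort(ts)
      if (anyDuplicated(ts)) {
        warning(sprintf("electrode %s: duplicate timestamps removed", lb))
        ts <- unique(ts)
      }
    }
    out[[lb]] <- ts
  }
  structure(list(layout = layout, spikes = out, duration = duration),
            class = "spike_list")
}

#' @export
print.spike_list <- function(x, ...) {
  n <- vapply(x$spikes, length, integer(1))
  cat(sprintf("Spike list set: %d electrodes, %d spikes, %.1f s\n",
              length(n), sum(n), x$duration))
  for (cp in x$layout$compartments) {
    lb <- electrode_labels(x$layout, cp)
    cat(sprintf("  %s: %d spikes (%.2f Hz/electrode)\n", cp,
                sum(n[lb]), sum(n[lb]) / length(lb) / x$duration))
  }
  invisible(x)
}

#' @export
summary.spike_list <- function(object, ...) {
  n <- vapply(object$spikes, length, integer(1))
  data.frame(label = names(n),
             compartment = object$layout$electrodes$compartment,
             n_spikes = as.integer(n),
             rate_hz = n / object$duration,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Construct a raw multichannel recording
#'
#' @param layout An \code{mea_layout}.
#' @param traces Numeric matrix, samples x electrodes, in microvolts; column
#'   order must follow \code{electrode_labels(layout)}.
#' @return An object of class \code{mea_recording} with elements
#'   \code{layout}, \code{traces} and \code{duration} (= samples /
#'   sampling_rate).
#' @export
mea_recording <- function(layout, traces) {
  stopifnot(inherits(layout, "mea_layout"))
  traces <- as.matrix(traces)
  if (ncol(traces) != nrow(layout$electrodes))
    stop(sprintf("expected %d channels, got %d",
                 nrow(layout$electrodes), ncol(traces)))
  colnames(traces) <- layout$electrodes$label
  structure(list(layout = layout, traces = traces,
                 duration = nrow(traces) / layout$sampling_rate),
            class = "mea_recording")
}

#' @export
print.mea_recording <- function(x, ...) {
  cat(sprintf("Raw MEA recording: %d channels, %d samples (%.2f s at %g Hz)\n",
              ncol(x$traces), nrow(x$traces), x$duration,
              x$layout$sampling_rate))
  invisible(x)
}
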