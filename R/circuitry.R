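# Interval utilities. Intervals are closed [start, end] at spike-time
# resolution; all sets are kept disjoint and ordered.

# Maximal intervals where >= depth of the given interval sets overlap.
# sets: list of data.frames with start/end columns (each disjoint, ordered).
interval_depth_regions <- function(sets, depth) {
  pts <- sort(unique(unlist(lapply(sets, function(b) c(b$start, b$end)))))
  if (length(pts) < 2)
    return(data.frame(start = numeric(0), end = numeric(0)))
  mids <- (pts[-1] + pts[-length(pts)]) / 2
  cover <- rep(0L, length(mids))
  for (b in sets) {
    if (!nrow(b)) next
    i <- findInterval(mids, b$start)
    cover <- cover + as.integer(i >= 1 & mids <= b$end[pmax(i, 1L)])
  }
  on <- cover >= depth
  if (!any(on)) return(data.frame(start = numeric(0), end = numeric(0)))
  r <- rle(on)
  stops <- cumsum(r$lengths)
  starts <- c(1L, stops[-length(stops)] + 1L)
  sel <- which(r$values)
  out <- data.frame(start = pts[starts[sel]], end = pts[stops[sel] + 1L])
  out[out$end > out$start, , drop = FALSE]
}

# TRUE for each row of x overlapping (positive measure) any row of y.
overlaps_any <- function(x, y) {
  if (!nrow(x)) return(logical(0))
  if (!nrow(y)) return(rep(FALSE, nrow(x)))
  vapply(seq_len(nrow(x)), function(i)
    any(pmin(x$end[i], y$end) - pmax(x$start[i], y$start) > 0), logical(1))
}

#' Detect circuitry bursts (STEP 6): full three-compartment intersection
#'
#' A circuitry burst (CB) is a maximal time segment during which every
#' compartment has an ongoing network burst; it is the full temporal
#' intersection of the three compartments' NB intervals. Intersections of
#' measure zero (point contact) are not events.
#'
#' @param nbs_by_compartment Named list (one element per compartment) of
#'   burst tables with \code{start}/\code{end} columns, each disjoint and
#'   ordered (e.g. from \code{\link{detect_network_bursts}}).
#' @param lag_tolerance Symmetric tolerance in seconds: each NB interval is
#'   dilated by this amount before intersection. Default 0 (zero delay is
#'   assumed between compartments connected by many microtunnels).
#' @return A \code{circuitry_events} data frame with columns \code{kind}
#'   ("CB"), \code{compartments} (e.g. "ABC"), \code{start}, \code{end}, and
#'   a list column \code{member_nbs} giving, per event and compartment, the
#'   row indices of the member NBs.
#' @export
detect_cb <- function(nbs_by_compartment, lag_tolerance = 0) {
  stopifnot(is.list(nbs_by_compartment), length(nbs_by_compartment) >= 2)
  sets <- lapply(nbs_by_compartment, dilate_intervals, lag_tolerance)
  inter <- interval_depth_regions(sets, depth = length(sets))
  make_circuitry_events(inter, kind = "CB",
                        compartments = paste(names(nbs_by_compartment),
                                             collapse = ""),
                        nbs_by_compartment = nbs_by_compartment)
}

dilate_intervals <- function(b, tol) {
  if (tol > 0 && nrow(b)) {
    b$start <- b$start - tol
    b$end <- b$end + tol
  }
  b
}

make_circuitry_events <- function(inter, kind, compartments,
                                  nbs_by_compartment) {
  n <- nrow(inter)
  ev <- data.frame(kind = rep(kind, n),
                   compartments = rep(compartments, n),
                   start = inter$start, end = inter$end,
                   stringsAsFactors = FALSE)
  ev$member_nbs <- lapply(seq_len(n), function(i) {
    lapply(nbs_by_compartment, function(b) {
      if (!nrow(b)) return(integer(0))
      which(pmin(ev$end[i], b$end) - pmax(ev$start[i], b$start) > 0)
    })
  })
  class(ev) <- c("circuitry_events", "data.frame")
  ev
}

#' Detect intermediate circuitry bursts: two-compartment intersections
#'
#' For every compartment pair, computes the maximal pairwise NB
#' intersections and discards any intersection that temporally overlaps a CB
#' (such intersections are associated with the CB and are not counted as
#' ICBs). Remaining intersections are ICBs labelled by the pair (e.g. "AB").
#'
#' @param nbs_by_compartment Named list of per-compartment burst tables (as
#'   in \code{\link{detect_cb}}).
#' @param cbs Output of \code{\link{detect_cb}} on the same input.
#' @param lag_tolerance As in \code{\link{detect_cb}}.
#' @param cb_exclusion \code{"full"} (default) drops an ICB candidate that
#'   overlaps any CB entirely; \code{"trim"} keeps its non-overlapping
#'   remainder instead.
#' @return A \code{circuitry_events} data frame of kind "ICB".
#' @export
detect_icb <- function(nbs_by_compartment, cbs, lag_tolerance = 0,
                       cb_exclusion = c("full", "trim")) {
  cb_exclusion <- match.arg(cb_exclusion)
  cps <- names(nbs_by_compartment)
  out <- list()
  for (i in seq_along(cps)) for (j in seq_along(cps)) {
    if (i >= j) next
    pair <- c(cps[i], cps[j])
    sets <- lapply(nbs_by_compartment[pair], dilate_intervals, lag_tolerance)
    inter <- interval_depth_regions(sets, depth = 2)
    if (cb_exclusion == "full") {
      inter <- inter[!overlaps_any(inter, cbs), , drop = FALSE]
    } else if (nrow(cbs)) {
      inter <- subtract_intervals(inter, cbs)
    }
    out[[paste(pair, collapse = "")]] <- make_circuitry_events(
      inter, kind = "ICB", compartments = paste(pair, collapse = ""),
      nbs_by_compartment = nbs_by_compartment[pair])
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("circuitry_events", "data.frame")
  res
}

# Set difference x \ y on interval tables (positive-measure remainders).
subtract_intervals <- function(x, y) {
  if (!nrow(x) || !nrow(y)) return(x)
  pieces <- list()
  for (i in seq_len(nrow(x))) {
    segs <- data.frame(start = x$start[i], end = x$end[i])
    for (j in seq_len(nrow(y))) {
      keep <- list()
      for (k in seq_len(nrow(segs))) {
        s <- segs$start[k]; e <- segs$end[k]
        ys <- y$start[j]; ye <- y$end[j]
        if (ye <= s || ys >= e) {
          keep[[length(keep) + 1L]] <- c(s, e)
        } else {
          if (ys > s) keep[[length(keep) + 1L]] <- c(s, ys)
          if (ye < e) keep[[length(keep) + 1L]] <- c(ye, e)
        }
      }
      segs <- if (length(keep))
        as.data.frame(do.call(rbind, keep)) else
        data.frame(V1 = numeric(0), V2 = numeric(0))
      names(segs) <- c("start", "end")
      if (!nrow(segs)) break
    }
    pieces[[i]] <- segs
  }
  out <- do.call(rbind, pieces)
  out[out$end > out$start, , drop = FALSE]
}

#' @export
print.circuitry_events <- function(x, ...) {
  if (!nrow(x)) {
    cat("Circuitry events: none\n")
    return(invisible(x))
  }
  for (k in unique(x$kind)) {
    sub <- x[x$kind == k, ]
    cat(sprintf("%s: %d events, cumulative duration %.2f s\n", k, nrow(sub),
                sum(sub$end - sub$start)))
    if (k == "ICB")
      for (p in unique(sub$compartments))
        cat(sprintf("  %s: %d\n", p, sum(sub$compartments == p)))
  }
  invisible(x)
}

#' Classify a plate's synchrony pattern
#'
#' A plate shows \emph{full synchrony} when every network burst in every
#' compartment participates in (temporally overlaps) some circuitry burst;
#' it is \emph{no-ICB} when no intermediate circuitry bursts were detected.
#' The two labels are not exclusive; plates with unmatched NBs and ICBs are
#' \emph{mixed}.
#'
#' @param nbs_by_compartment Named list of per-compartment burst tables.
#' @param cbs,icbs \code{circuitry_events} from \code{\link{detect_cb}} and
#'   \code{\link{detect_icb}}.
#' @return List with logicals \code{full_synchrony}, \code{no_icb}, the
#'   count table \code{counts}, and \code{labels} (character vector drawn
#'   from "full synchrony", "no-ICB", "mixed").
#' @export
classify_synchrony <- function(nbs_by_compartment, cbs, icbs) {
  full <- all(vapply(nbs_by_compartment, function(b)
    all(overlaps_any(b, cbs)), logical(1)))
  no_icb <- nrow(icbs) == 0
  labels <- c(if (full) "full synchrony", if (no_icb) "no-ICB")
  if (is.null(labels)) labels <- "mixed"
  counts <- c(vapply(nbs_by_compartment, nrow, integer(1)),
              ICB = nrow(icbs), CB = nrow(cbs))
  names(counts)[seq_along(nbs_by_compartment)] <-
    paste0("NB_", names(nbs_by_compartment))
  list(full_synchrony = full, no_icb = no_icb, counts = counts,
       labels = labels)
}

#' Detect circuitry-level events from per-compartment network bursts
#'
#' Convenience wrapper running \code{\link{detect_cb}},
#' \code{\link{detect_icb}} and \code{\link{classify_synchrony}}.
#'
#' @inheritParams detect_cb
#' @inheritParams detect_icb
#' @return List with elements \code{cb}, \code{icb} and
#'   \code{classification}.
#' @export
detect_circuitry_bursts <- function(nbs_by_compartment, lag_tolerance = 0,
                                    cb_exclusion = "full") {
  cbs <- detect_cb(nbs_by_compartment, lag_tolerance)
  icbs <- detect_icb(nbs_by_compartment, cbs, lag_tolerance, cb_exclusion)
  list(cb = cbs, icb = icbs,
       classification = classify_synchrony(nbs_by_compartment, cbs, icbs))
}
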