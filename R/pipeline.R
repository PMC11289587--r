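#' Default pipeline configuration
#'
#' Nested list of every stage's parameters with their documented defaults:
#' ISI_N span N = 20, merging fraction 0.2, minimum channels 3, minimum
#' individual channel contribution 0.15, detection threshold 4.5x noise SD,
#' 200-3000 Hz elliptic band, 5000 surrogate simulations with shifts in
#' [-20, 20] s, 5 min (300 s) bins, alpha = 0.05 over a family of eight
#' hypotheses, and the 40 Hz noise-rejection rate limit.
#'
#' @return Named nested list with blocks \code{layout}, \code{qc},
#'   \code{spike_detection}, \code{network_bursts}, \code{circuitry},
#'   \code{metrics}, \code{surrogate}, \code{connectivity},
#'   \code{simulation}.
#' @export
pipeline_config <- function() {
  list(
    layout = list(compartments = c("A", "B", "C"),
                  electrodes_per_compartment = 24L,
                  sampling_rate = 25000),
    qc = list(bin_width = 1, rate_limit = 40, min_channels_fraction = 0.75),
    spike_detection = unclass(spike_detection_params()),
    network_bursts = unclass(nb_detection_params()),
    circuitry = list(lag_tolerance = 0, cb_exclusion = "full"),
    metrics = list(bin_width = 300, alpha = 0.05, family_size = 8L,
                   frequency = "per_burst", ibi = "end_to_start"),
    surrogate = unclass(surrogate_params()),
    connectivity = unclass(corse_params()),
    simulation = unclass(simulation_params())
  )
}

# Recursively merge user values into defaults, rejecting unknown keys.
merge_config <- function(defaults, user, path = "") {
  for (nm in names(user)) {
    full <- if (nzchar(path)) paste0(path, ".", nm) else nm
    if (!nm %in% names(defaults))
      stop(sprintf("unknown configuration key: %s", full))
    if (is.list(defaults[[nm]]) && is.list(user[[nm]]))
      defaults[[nm]] <- merge_config(defaults[[nm]], user[[nm]], full)
    else defaults[[nm]] <- user[[nm]]
  }
  defaults
}

#' Read and validate a YAML pipeline configuration
#'
#' Loads a YAML file, merges it over \code{\link{pipeline_config}} defaults
#' and rejects unknown keys. Note that the ISI-span key of the
#' \code{network_bursts} block must be written quoted (\code{"N": 20}) in
#' YAML, since a bare \code{N} parses as the boolean false.
#'
#' @param path YAML file path, or \code{NULL} for pure defaults.
#' @return Validated configuration list.
#' @export
read_pipeline_config <- function(path = NULL) {
  cfg <- pipeline_config()
  if (is.null(path)) return(cfg)
  user <- yaml::read_yaml(path)
  merge_config(cfg, user)
}

config_layout <- function(config) {
  platform_layout(config$layout$compartments,
                  config$layout$electrodes_per_compartment,
                  config$layout$sampling_rate)
}

config_params <- function(config) {
  list(
    spike = do.call(spike_detection_params, config$spike_detection),
    nb = do.call(nb_detection_params, config$network_bursts),
    surrogate = do.call(surrogate_params,
                        config$surrogate[c("n_simulations", "delta_range",
                                           "seed", "tie_breaking")]),
    corse = do.call(corse_params, config$connectivity)
  )
}

#' Run the full analysis pipeline
#'
#' Executes every stage in order on one recording: quality-control flags,
#' per-compartment network-burst detection, circuitry-level burst
#' classification, the eight output parameters per compartment and at the
#' circuitry level, and the surrogate alignment test. When a raw recording
#' is supplied, spike detection runs first and CorSE connectivity is
#' computed as well.
#'
#' @param spikes A \code{\link{spike_list}}, or \code{NULL} when
#'   \code{recording} is given.
#' @param recording Optional \code{\link{mea_recording}} with raw traces.
#' @param config Configuration list from \code{\link{pipeline_config}} /
#'   \code{\link{read_pipeline_config}}.
#' @param out_dir Optional directory: intermediate artifacts (spike CSV,
#'   burst/circuitry/report JSON) are written there.
#' @return Object of class \code{circuit_report}: list with elements
#'   \code{qc_flags}, \code{nbs} (per compartment), \code{circuitry},
#'   \code{parameters} (per scope), \code{surrogate}, optionally
#'   \code{connectivity}, and \code{config}.
#' @export
run_pipeline <- function(spikes = NULL, recording = NULL,
                         config = pipeline_config(), out_dir = NULL) {
  pars <- config_params(config)
  if (is.null(spikes)) {
    if (is.null(recording)) stop("either spikes or recording must be given")
    spikes <- detect_spikes(recording, pars$spike)
  }
  layout <- spikes$layout
  qc <- flag_noisy_bins(spikes, config$qc$bin_width, config$qc$rate_limit,
                        config$qc$min_channels_fraction)
  nbs <- lapply(layout$compartments, function(cp)
    detect_network_bursts(spikes, cp, pars$nb))
  names(nbs) <- layout$compartments
  circ <- detect_circuitry_bursts(nbs, config$circuitry$lag_tolerance,
                                  config$circuitry$cb_exclusion)
  parameters <- lapply(layout$compartments, function(cp)
    burst_parameters(nbs[[cp]], spikes, cp, pars$nb,
                     config$metrics$frequency, config$metrics$ibi))
  names(parameters) <- paste0("NB_", layout$compartments)
  parameters$CB <- burst_parameters(circ$cb, spikes, NULL, pars$nb,
                                    config$metrics$frequency,
                                    config$metrics$ibi)
  surrogate <- if (any(vapply(nbs, nrow, integer(1)) > 0))
    surrogate_alignment_test(nbs, spikes$duration, pars$surrogate)
  else NULL
  connectivity <- if (!is.null(recording))
    connectivity_matrix(recording, pars$corse) else NULL
  report <- structure(
    list(qc_flags = qc, nbs = nbs, circuitry = circ,
         parameters = parameters, surrogate = surrogate,
         connectivity = connectivity, config = config),
    class = "circuit_report")
  if (!is.null(out_dir)) write_report(report, spikes, out_dir)
  report
}

write_report <- function(report, spikes, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_spike_csv(spikes, file.path(out_dir, "spikes.csv"))
  nb_json <- lapply(report$nbs, function(b)
    b[, c("compartment", "start", "end", "spike_count",
          "n_participating", "n_dominating")])
  jsonlite::write_json(nb_json, file.path(out_dir, "bursts.json"),
                       auto_unbox = TRUE, digits = NA)
  circ_json <- list(
    cb = report$circuitry$cb[, c("kind", "compartments", "start", "end")],
    icb = report$circuitry$icb[, c("kind", "compartments", "start", "end")],
    classification = report$circuitry$classification[
      c("full_synchrony", "no_icb", "labels")])
  jsonlite::write_json(circ_json, file.path(out_dir, "circuitry.json"),
                       auto_unbox = TRUE, digits = NA)
  summary_json <- list(
    parameters = lapply(report$parameters, function(p)
      as.list(unclass(p))),
    surrogate = if (!is.null(report$surrogate))
      report$surrogate[c("observed_metric", "u_observed", "p",
                         "nonrandom")],
    qc_flagged_bins = nrow(report$qc_flags),
    connectivity = if (!is.null(report$connectivity))
      list(intra = as.list(report$connectivity$intra),
           inter = as.list(report$connectivity$inter)))
  jsonlite::write_json(summary_json, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(out_dir)
}

#' @export
print.circuit_report <- function(x, ...) {
  cat("Circuit analysis report\n")
  cat(sprintf("  QC: %d flagged bin(s)\n", nrow(x$qc_flags)))
  for (cp in names(x$nbs))
    cat(sprintf("  NB %s: %d bursts\n", cp, nrow(x$nbs[[cp]])))
  cl <- x$circuitry$classification
  cat(sprintf("  CB: %d, ICB: %d [%s]\n", nrow(x$circuitry$cb),
              nrow(x$circuitry$icb), paste(cl$labels, collapse = ", ")))
  if (!is.null(x$surrogate))
    cat(sprintf("  surrogate test: p = %.4g (%s)\n", x$surrogate$p,
                if (x$surrogate$nonrandom) "non-random" else "random"))
  if (!is.null(x$connectivity))
    cat(sprintf("  connectivity: mean intra %.3f, mean inter %.3f\n",
                mean(x$connectivity$intra), mean(x$connectivity$inter)))
  invisible(x)
}
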