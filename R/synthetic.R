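#' Simulation parameters for synthetic platform recordings
#'
#' Defines the study conditions emulated by the synthetic-data generator:
#' 30 min three-compartment recordings with homogeneous Poisson background
#' firing, planted network-burst epochs of ~1 s at elevated within-burst
#' rates, and tunable cross-compartment coupling. Defaults follow the
#' platform's recording protocol (30 min sessions; tens to ~180 bursts per
#' compartment per session) and sparse background firing typical of
#' hPSC-derived cortical cultures on MEA.
#'
#' @param duration Recording duration, seconds (default 1800).
#' @param background_rate Background firing rate per electrode, Hz
#'   (default 0.2).
#' @param nb_rate Within-burst firing rate per active electrode, Hz
#'   (default 20).
#' @param nb_duration_mean,nb_duration_sd Mean and SD of planted burst
#'   epoch durations, seconds (defaults 1 and 0.2).
#' @param nb_count Number of burst epochs planted over the recording
#'   (default 100).
#' @param active_channel_fraction Fraction of a compartment's electrodes
#'   that fire during an epoch (default 0.5).
#' @param cb_coupling Probability that an epoch is shared by all three
#'   compartments (default 0.8).
#' @param icb_coupling Probability that an epoch is shared by exactly two
#'   compartments (default 0.1); the remainder are single-compartment
#'   epochs. \code{cb_coupling + icb_coupling} must not exceed 1.
#' @param spike_amplitude_snr Peak spike-template amplitude as a multiple of
#'   the noise SD in raw-trace synthesis (default 8).
#' @param noise_sd Raw-trace Gaussian noise SD, microvolts (default 5).
#' @param envelope_coupling Strength in \code{[0, 1]} of the shared slow
#'   power-modulation envelope across electrodes in raw-trace synthesis
#'   (default 0; used for connectivity validation).
#' @param seed RNG seed (default 1).
#' @return A list of class \code{simulation_params}.
#' @export
simulation_params <- function(duration = 1800, background_rate = 0.2,
                              nb_rate = 20, nb_duration_mean = 1,
                              nb_duration_sd = 0.2, nb_count = 100L,
                              active_channel_fraction = 0.5,
                              cb_coupling = 0.8, icb_coupling = 0.1,
                              spike_amplitude_snr = 8, noise_sd = 5,
                              envelope_coupling = 0, seed = 1L) {
  stopifnot(duration > 0, background_rate >= 0, nb_rate >= 0,
            nb_duration_mean > 0, nb_duration_sd >= 0, nb_count >= 0,
            active_channel_fraction > 0, active_channel_fraction <= 1,
            cb_coupling >= 0, icb_coupling >= 0,
            cb_coupling + icb_coupling <= 1,
            spike_amplitude_snr >= 0, noise_sd > 0,
            envelope_coupling >= 0, envelope_coupling <= 1)
  structure(list(duration = duration, background_rate = background_rate,
                 nb_rate = nb_rate, nb_duration_mean = nb_duration_mean,
                 nb_duration_sd = nb_duration_sd,
                 nb_count = as.integer(nb_count),
                 active_channel_fraction = active_channel_fraction,
                 cb_coupling = cb_coupling, icb_coupling = icb_coupling,
                 spike_amplitude_snr = spike_amplitude_snr,
                 noise_sd = noise_sd,
                 envelope_coupling = envelope_coupling,
                 seed = as.integer(seed)),
            class = "simulation_params")
}

#' Generate ground-truth-annotated synthetic spike lists
#'
#' Plants \code{nb_count} non-overlapping burst epochs on the recording
#' timeline (minimum inter-epoch gap of twice the mean epoch duration, so
#' planted bursts stay unambiguous), assigns each epoch to all three
#' compartments with probability \code{cb_coupling}, to a random pair with
#' probability \code{icb_coupling}, and to a single random compartment
#' otherwise. Background spiking is homogeneous Poisson per electrode;
#' within an epoch, a sampled \code{active_channel_fraction} of the member
#' compartment's electrodes fire as Poisson at \code{nb_rate} (rectangular
#' rate profile). Fully reproducible from \code{seed}.
#'
#' @param params A \code{\link{simulation_params}}.
#' @param layout A \code{\link{platform_layout}} (default: three
#'   compartments of 24 electrodes at 25 kHz).
#' @return List with elements \code{spikes} (a \code{\link{spike_list}})
#'   and \code{truth}: a list holding \code{epochs} (data frame with
#'   \code{start}, \code{end}, \code{membership} as e.g. "ABC"/"AB"/"C") and
#'   per-compartment interval tables in \code{by_compartment}.
#' @export
simulate_spike_lists <- function(params = simulation_params(),
                                 layout = platform_layout()) {
  stopifnot(inherits(params, "simulation_params"),
            inherits(layout, "mea_layout"))
  set.seed(params$seed)
  gap <- 2 * params$nb_duration_mean
  slot <- params$duration / max(1L, params$nb_count)
  if (params$nb_count > 0 && slot < params$nb_duration_mean + gap)
    stop("nb_count too high for the duration: epochs cannot be placed ",
         "with the required inter-epoch gap")
  cps <- layout$compartments
  epochs <- data.frame(start = numeric(0), end = numeric(0),
                       membership = character(0))
  if (params$nb_count > 0) {
    dur <- pmax(0.05, stats::rnorm(params$nb_count,
                                   params$nb_duration_mean,
                                   params$nb_duration_sd))
    dur <- pmin(dur, slot - gap)
    jitter <- stats::runif(params$nb_count, 0, pmax(0, slot - gap - dur))
    start <- (seq_len(params$nb_count) - 1) * slot + gap / 2 + jitter
    kind <- sample(c("cb", "icb", "nb"), params$nb_count, replace = TRUE,
                   prob = c(params$cb_coupling, params$icb_coupling,
                            1 - params$cb_coupling - params$icb_coupling))
    membership <- vapply(kind, function(k) {
      if (k == "cb") paste(cps, collapse = "")
      else if (k == "icb") paste(sort(sample(cps, 2)), collapse = "")
      else sample(cps, 1)
    }, character(1))
    epochs <- data.frame(start = start, end = start + dur,
                         membership = membership,
                         stringsAsFactors = FALSE)
  }
  spikes <- list()
  n_el <- layout$electrodes_per_compartment
  n_active <- max(1L, round(params$active_channel_fraction * n_el))
  for (cp in cps) {
    lbs <- electrode_labels(layout, cp)
    tr <- stats::setNames(vector("list", n_el), lbs)
    for (lb in lbs) {
      n_bg <- stats::rpois(1, params$background_rate * params$duration)
      tr[[lb]] <- stats::runif(n_bg, 0, params$duration)
    }
    member <- which(grepl(cp, epochs$membership, fixed = TRUE))
    for (i in member) {
      active <- sample(lbs, n_active)
      len <- epochs$end[i] - epochs$start[i]
      for (lb in active) {
        n_sp <- stats::rpois(1, params$nb_rate * len)
        tr[[lb]] <- c(tr[[lb]],
                      stats::runif(n_sp, epochs$start[i], epochs$end[i]))
      }
    }
    spikes <- c(spikes, lapply(tr, sort))
  }
  by_compartment <- lapply(cps, function(cp) {
    sel <- grepl(cp, epochs$membership, fixed = TRUE)
    data.frame(start = epochs$start[sel], end = epochs$end[sel])
  })
  names(by_compartment) <- cps
  list(spikes = spike_list(layout, spikes, params$duration),
       truth = list(epochs = epochs, by_compartment = by_compartment))
}

# Biphasic extracellular spike template: ~1 ms, unit peak amplitude.
spike_template <- function(fs) {
  t <- seq(0, 1e-3, by = 1 / fs)
  w <- -sin(2 * pi * t / 1e-3) * exp(-t / 4e-4)
  w / max(abs(w))
}

# Slow smooth random envelope in [0, 1], one value per sample, varying on
# the ~seconds scale so it modulates windowed spectra.
slow_envelope <- function(n, fs, scale_s = 2) {
  n_knots <- max(4L, ceiling(n / fs / scale_s) + 2L)
  knots <- stats::runif(n_knots)
  idx <- seq(0, 1, length.out = n)
  env <- stats::spline(seq(0, 1, length.out = n_knots), knots,
                       xout = idx)$y
  env <- env - min(env)
  if (max(env) > 0) env <- env / max(env)
  env
}

#' Synthesize raw traces from a spike list
#'
#' Builds 25 kHz (or the layout's rate) voltage traces: Gaussian noise at
#' \code{noise_sd}, a fixed ~1 ms biphasic spike template of amplitude
#' \code{spike_amplitude_snr * noise_sd} inserted at each spike time, and an
#' optional slow narrowband (10 Hz) component whose power follows a shared
#' envelope across electrodes at strength \code{envelope_coupling} (each
#' electrode mixes the shared envelope with its own independent envelope;
#' coupling 1 means identical spectral modulation, 0 means independent).
#' The narrowband component emulates LFP-like slow oscillations so that the
#' spectral content, not just the amplitude, varies over time.
#'
#' @param spikes A \code{\link{spike_list}}.
#' @param params A \code{\link{simulation_params}}.
#' @param lfp_amplitude Amplitude of the narrowband component relative to
#'   the noise SD (default 2); 0 disables it.
#' @return An \code{\link{mea_recording}}.
#' @export
simulate_raw <- function(spikes, params = simulation_params(),
                         lfp_amplitude = 2) {
  stopifnot(inherits(spikes, "spike_list"))
  set.seed(params$seed + 1L)
  fs <- spikes$layout$sampling_rate
  n <- round(spikes$duration * fs)
  tmpl <- spike_template(fs)
  amp <- params$spike_amplitude_snr * params$noise_sd
  labels <- names(spikes$spikes)
  traces <- matrix(0, nrow = n, ncol = length(labels),
                   dimnames = list(NULL, labels))
  shared_env <- slow_envelope(n, fs)
  carrier <- sin(2 * pi * 10 * seq_len(n) / fs)
  for (j in seq_along(labels)) {
    x <- stats::rnorm(n, 0, params$noise_sd)
    if (lfp_amplitude > 0) {
      own_env <- slow_envelope(n, fs)
      env <- params$envelope_coupling * shared_env +
        (1 - params$envelope_coupling) * own_env
      x <- x + lfp_amplitude * params$noise_sd * env * carrier
    }
    if (amp > 0) {
      for (ts in spikes$spikes[[labels[j]]]) {
        i0 <- round(ts * fs) + 1L
        i1 <- min(n, i0 + length(tmpl) - 1L)
        if (i0 <= n)
          x[i0:i1] <- x[i0:i1] + amp * tmpl[seq_len(i1 - i0 + 1L)]
      }
    }
    traces[, j] <- x
  }
  mea_recording(spikes$layout, traces)
}
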