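# Shared fixtures: small layouts and constructed spike/burst sets built in
# code at test time.

tiny_layout <- function(n_el = 4L, fs = 25000) {
  platform_layout(compartments = c("A", "B", "C"),
                  electrodes_per_compartment = n_el, sampling_rate = fs)
}

# Disjoint random bursts on a lattice: n intervals in [0, dur], start/end
# multiples of `grid` seconds, duration >= grid.
random_lattice_bursts <- function(n, dur, grid = 0.01, max_len = 1) {
  slot <- dur / n
  # integer grid units throughout so equal boundaries across compartments
  # are bit-identical (point contacts stay exactly zero-width)
  starts_i <- round(((seq_len(n) - 1) * slot +
                       stats::runif(n, 0, slot * 0.5)) / grid)
  lens_i <- pmax(1, round(stats::runif(n, grid, min(max_len, slot * 0.4)) /
                            grid))
  data.frame(start = starts_i * grid, end = (starts_i + lens_i) * grid)
}

# Brute-force exact two-sided signed-rank p: enumerate all 2^n sign
# assignments of the midranks (independent oracle for paired_wilcoxon).
brute_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(1)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- signs %*% r
  lower <- mean(w_all <= w_obs + 1e-9)
  upper <- mean(w_all >= w_obs - 1e-9)
  min(1, 2 * min(lower, upper))
}

# Stationary renewal burst process: exponential gaps, fixed burst length.
# No periodic structure, so independently drawn compartments are a proper
# null for the alignment test.
renewal_bursts <- function(n_target, dur, len = 1) {
  gaps <- stats::rexp(2 * n_target, rate = n_target / dur)
  starts <- cumsum(gaps + len) - len
  starts <- starts[starts + len < dur]
  data.frame(start = starts, end = starts + len)
}

# Brute-force boolean-AND oracle on a 1 ms grid: intervals where all listed
# burst tables are simultaneously active.
grid_intersection_oracle <- function(nbs_list, dur, step = 1e-3) {
  mids <- seq(step / 2, dur - step / 2, by = step)
  on <- rep(TRUE, length(mids))
  for (b in nbs_list) {
    active <- rep(FALSE, length(mids))
    for (i in seq_len(nrow(b)))
      active <- active | (mids > b$start[i] & mids < b$end[i])
    on <- on & active
  }
  if (!any(on)) return(data.frame(start = numeric(0), end = numeric(0)))
  r <- rle(on)
  stop_i <- cumsum(r$lengths)
  start_i <- c(1L, stop_i[-length(stop_i)] + 1L)
  sel <- which(r$values)
  data.frame(start = mids[start_i[sel]] - step / 2,
             end = mids[stop_i[sel]] + step / 2)
}

# Raw trace with planted biphasic spikes at the given times.
planted_trace <- function(times, fs, dur_s, noise_sd = 5, snr = 8,
                          seed = 1) {
  set.seed(seed)
  n <- round(dur_s * fs)
  x <- stats::rnorm(n, 0, noise_sd)
  t <- seq(0, 1e-3, by = 1 / fs)
  tmpl <- -sin(2 * pi * t / 1e-3) * exp(-t / 4e-4)
  tmpl <- tmpl / max(abs(tmpl))
  for (ts in times) {
    i0 <- round(ts * fs) + 1L
    i1 <- min(n, i0 + length(tmpl) - 1L)
    if (i0 <= n) x[i0:i1] <- x[i0:i1] + snr * noise_sd * tmpl[seq_len(i1 - i0 + 1L)]
  }
  x
}

# Match detections to truth times: a truth spike is hit when a detection
# falls within tol (spike template peak sits ~0.25 ms after onset).
match_spikes <- function(detected, truth, tol = 1.5e-3, peak_offset = 2.5e-4) {
  hits <- vapply(truth, function(t0)
    any(abs(detected - t0 - peak_offset) <= tol), logical(1))
  fp <- vapply(detected, function(td)
    all(abs(truth + peak_offset - td) > tol), logical(1))
  list(tp = sum(hits), fn = sum(!hits), fp = sum(fp))
}
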