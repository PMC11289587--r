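fs <- 2000
cpar <- corse_params()

test_that("spectral entropy separates tones from white noise and ignores scale", {
  t <- seq_len(fs * 10) / fs
  tone <- sin(2 * pi * 250 * t)          # fs/8: a bin centre by construction
  se_tone <- spectral_entropy_series(tone, fs, cpar)
  expect_lt(mean(se_tone), 0.05)
  set.seed(44)
  noise <- rnorm(fs * 10)
  se_noise <- spectral_entropy_series(noise, fs, cpar)
  expect_gt(mean(se_noise), 0.9)
  expect_true(all(se_noise >= 0 & se_noise <= 1))
  # amplitude scaling leaves entropy untouched
  expect_equal(spectral_entropy_series(17.3 * noise, fs, cpar), se_noise,
               tolerance = 1e-12)
  # an all-zero window is undefined, not zero
  gap <- noise
  gap[(2 * fs + 1):(3 * fs)] <- 0
  se_gap <- spectral_entropy_series(gap, fs, cpar)
  expect_true(is.na(se_gap[3]))
  expect_false(anyNA(se_gap[-3]))
})

test_that("corse_pair is 1 on itself and undefined for constant series", {
  set.seed(45)
  x <- runif(40)
  expect_equal(corse_pair(x, x), 1)
  expect_true(is.na(corse_pair(rep(0.5, 40), x)))
  expect_true(is.na(corse_pair(x[1:5], x[1:5])))  # too few windows
  # amplitude rescaling of the underlying trace cannot change CorSE
  # (entropy is scale-free), and neither can rescaling the series itself
  y <- runif(40)
  expect_equal(corse_pair(x, y), corse_pair(x, 3 * y - 0.2))
})

test_that("independent entropy series score low, shared envelopes high", {
  lay <- platform_layout(compartments = c("A", "B", "C"),
                         electrodes_per_compartment = 2,
                         sampling_rate = fs)
  sl <- spike_list(lay, list(), 120)
  mean_corse <- vapply(c(0, 0.5, 1), function(cc) {
    rec <- simulate_raw(sl, simulation_params(duration = 120,
                                              envelope_coupling = cc,
                                              seed = 46))
    cm <- connectivity_matrix(rec, cpar)
    mean(cm$matrix[upper.tri(cm$matrix)], na.rm = TRUE)
  }, numeric(1))
  expect_lt(mean_corse[1], 0.55)
  expect_gt(mean_corse[3], 0.9)
  expect_true(all(diff(mean_corse) > 0))
  # pure independent noise (no slow component at all): near-null values
  rec0 <- simulate_raw(sl, simulation_params(duration = 120, seed = 47),
                       lfp_amplitude = 0)
  cm0 <- connectivity_matrix(rec0, cpar)
  expect_lt(mean(cm0$matrix[upper.tri(cm0$matrix)], na.rm = TRUE), 0.3)
})

test_that("the connectivity matrix is symmetric with unit diagonal", {
  lay <- platform_layout(compartments = c("A", "B"),
                         electrodes_per_compartment = 3,
                         sampling_rate = fs)
  set.seed(48)
  rec <- mea_recording(lay, matrix(rnorm(fs * 30 * 6), ncol = 6))
  cm <- connectivity_matrix(rec, cpar)
  expect_equal(cm$matrix, t(cm$matrix))
  expect_equal(unname(diag(cm$matrix)), rep(1, 6))
  expect_named(cm$intra, c("A", "B"))
  expect_named(cm$inter, "AB")
  expect_false(cm$low_confidence)
})

test_that("identical traces give all-1 connectivity everywhere", {
  lay <- platform_layout(compartments = c("A", "B", "C"),
                         electrodes_per_compartment = 2,
                         sampling_rate = fs)
  set.seed(49)
  base <- rnorm(fs * 20) + 2 * sin(2 * pi * 7 * seq_len(fs * 20) / fs) *
    rep(runif(20), each = fs)
  rec <- mea_recording(lay, matrix(base, nrow = fs * 20, ncol = 6))
  cm <- connectivity_matrix(rec, cpar)
  expect_equal(unname(cm$matrix), matrix(1, 6, 6))
  expect_equal(unname(c(cm$intra, cm$inter)), rep(1, 6))
})

test_that("coupling planted only within one compartment shows up in the averages", {
  lay <- platform_layout(compartments = c("A", "B", "C"),
                         electrodes_per_compartment = 2,
                         sampling_rate = fs)
  set.seed(50)
  n <- fs * 60
  carrier <- sin(2 * pi * 10 * seq_len(n) / fs)
  shared <- rep(runif(60), each = fs)
  traces <- vapply(1:6, function(j) {
    x <- rnorm(n)
    if (j <= 2) x + 3 * shared * carrier             # compartment A coupled
    else x + 3 * rep(runif(60), each = fs) * carrier # independent envelopes
  }, numeric(n))
  cm <- connectivity_matrix(mea_recording(lay, traces), cpar)
  expect_gt(cm$intra["A"], max(cm$intra[c("B", "C")], cm$inter))
})

test_that("connectivity percent change clips only for display", {
  lay <- platform_layout(compartments = c("A", "B", "C"),
                         electrodes_per_compartment = 2,
                         sampling_rate = fs)
  sl <- spike_list(lay, list(), 60)
  before <- connectivity_matrix(
    simulate_raw(sl, simulation_params(duration = 60, envelope_coupling = 1,
                                       seed = 51)), cpar)
  after <- before
  after$intra <- before$intra * c(2, 1, 0.5)
  after$inter <- before$inter * c(1, 0.25, 1)
  pc <- connectivity_percent_change(before, after)
  expect_equal(unname(pc), c(100, 0, -50, 0, -75, 0))
  expect_equal(unname(clip_percent_change(pc)), c(50, 0, -50, 0, -50, 0))
  before$intra["A"] <- NA
  expect_true(is.na(connectivity_percent_change(before, after)["A"]))
})
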