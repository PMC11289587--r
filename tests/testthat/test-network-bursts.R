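test_that("compartment pooling merges and conserves electrode trains", {
  lay <- tiny_layout()
  sl <- spike_list(lay, list(A00 = 0.1, A01 = c(0.05, 0.2), B00 = 0.5), 1)
  expect_equal(pool_compartment_spikes(sl, "A"), c(0.05, 0.1, 0.2))
  expect_equal(pool_compartment_spikes(sl, "C"), numeric(0))
  set.seed(14)
  spk <- lapply(setNames(nm = electrode_labels(lay, "B")), function(lb)
    sort(runif(rpois(1, 30), 0, 10)))
  sl2 <- spike_list(lay, spk, 10)
  expect_equal(length(pool_compartment_spikes(sl2, "B")),
               sum(lengths(spk)))
})

test_that("ISI_N values span N consecutive spikes", {
  expect_equal(isi_n_values(c(0, 1, 2, 3), 2), c(1, 1, 1))
  expect_equal(isi_n_values(c(0, 1, 2, 3), 4), 3)
  expect_equal(isi_n_values(c(0, 1), 4), numeric(0))
  uniform <- seq(0, 100, by = 0.1)  # 10 Hz
  expect_equal(unique(round(isi_n_values(uniform, 20), 10)), 1.9)
})

test_that("bimodal ISI_N histograms give a threshold between the modes", {
  set.seed(15)
  # in-burst spans ~0.1 s, out-of-burst spans ~10 s
  values <- c(exp(rnorm(2000, log(0.1), 0.3)),
              exp(rnorm(500, log(10), 0.3)))
  thr <- isi_n_threshold(values)
  expect_gt(thr, 0.3)
  expect_lt(thr, 3)
  # multiplying all spans shifts the threshold multiplicatively
  thr5 <- isi_n_threshold(values * 5)
  expect_equal(thr5 / thr, 5, tolerance = 0.1)
})

test_that("unimodal trains yield the NA sentinel, not a made-up threshold", {
  set.seed(16)
  train <- sort(runif(3000, 0, 600))  # homogeneous Poisson-like
  thr <- isi_n_threshold(isi_n_values(train, 20))
  expect_true(is.na(thr))
  expect_true(attr(thr, "unimodal"))
  expect_error(isi_n_threshold(numeric(0)), "insufficient")
})

test_that("initial detection finds maximal qualifying runs (STEP 1)", {
  train <- c(0, 0.01, 0.02, 0.03, 0.04, 5, 5.01, 5.02, 5.03, 5.04)
  b <- detect_nb_initial(train, 5, 0.1)
  expect_equal(b$start, c(0, 5))
  expect_equal(b$end, c(0.04, 5.04))
  expect_equal(nrow(detect_nb_initial(train, 5, 0.01)), 0L)
  dense <- seq(0, 1, by = 0.01)
  one <- detect_nb_initial(dense, 5, 0.1)
  expect_equal(nrow(one), 1L)
  expect_equal(c(one$start, one$end), c(0, 1))
})

test_that("adaptive merging follows the longest-burst fraction rule (STEP 2)", {
  b <- data.frame(start = c(0, 1.1), end = c(1.0, 1.5))
  m <- merge_adjacent_bursts(b, 0.2)  # gap 0.1 < 0.2 * 1.0
  expect_equal(nrow(m), 1L)
  expect_equal(c(m$start, m$end), c(0, 1.5))
  b2 <- data.frame(start = c(0, 1.3), end = c(1.0, 1.5))
  expect_equal(merge_adjacent_bursts(b2, 0.2), b2)  # gap 0.3 >= 0.2
  expect_equal(merge_adjacent_bursts(b, 0), b)      # fraction 0: vacuous
})

test_that("merging is idempotent at fixpoint and never shrinks coverage", {
  set.seed(17)
  for (rep in 1:20) {
    s <- sort(runif(12, 0, 60))
    b <- data.frame(start = s, end = s + runif(12, 0.05, 2))
    b$end <- pmin(b$end, c(b$start[-1] - 1e-3, Inf))  # keep disjoint
    b <- b[b$end > b$start, ]
    m <- merge_adjacent_bursts(b, 0.2)
    expect_equal(merge_adjacent_bursts(m, 0.2), m)
    expect_gte(sum(m$end - m$start) + 1e-12, sum(b$end - b$start))
    expect_true(all(diff(m$start) > 0) && all(m$end[-nrow(m)] < m$start[-1]))
  }
})

test_that("short-burst removal is off by default and filters by duration", {
  b <- data.frame(start = c(0, 1), end = c(0.05, 3))
  expect_equal(remove_short_bursts(b), b)
  expect_equal(remove_short_bursts(b, 0), b)
  expect_equal(nrow(remove_short_bursts(b, 0.1)), 1L)
  expect_equal(remove_short_bursts(b, 0.1)$end, 3)
})

test_that("channel criteria match hand-computed contribution cutoffs (STEPS 4-5)", {
  lay <- tiny_layout()
  # counts (10, 10, 10, 1): mean contribution 31/4 = 7.75, cutoff 1.1625
  sl <- spike_list(lay, list(
    A00 = seq(0.1, 0.9, length.out = 10),
    A01 = seq(0.1, 0.9, length.out = 10),
    A02 = seq(0.1, 0.9, length.out = 10),
    A03 = 0.5), 2)
  b <- data.frame(start = 0, end = 1)
  nb <- apply_channel_criteria(b, sl, "A")
  expect_equal(nrow(nb), 1L)
  expect_equal(nb$spike_count, 31)
  expect_equal(nb$n_participating, 4L)
  expect_equal(nb$n_dominating, 3L)
  expect_setequal(nb$dominating[[1]], c("A00", "A01", "A02"))
  # counts (30, 1, 1): mean 32/3, cutoff 1.6 -> only one dominating channel
  sl2 <- spike_list(lay, list(
    A00 = seq(0.1, 0.9, length.out = 30), A01 = 0.4, A02 = 0.6), 2)
  nb2 <- apply_channel_criteria(b, sl2, "A")
  expect_equal(nrow(nb2), 0L)  # rejected: 1 dominating < 3 required
  # with the contribution criterion disabled every participant dominates
  p0 <- nb_detection_params(min_contribution_fraction = 0)
  nb3 <- apply_channel_criteria(b, sl2, "A", p0)
  expect_equal(nb3$n_dominating, nb3$n_participating)
})

test_that("raising the contribution fraction never adds dominating channels", {
  lay <- tiny_layout(n_el = 8L)
  set.seed(18)
  spk <- lapply(setNames(nm = electrode_labels(lay, "A")), function(lb)
    sort(runif(sample(0:20, 1), 0, 1)))
  sl <- spike_list(lay, spk, 1)
  b <- data.frame(start = 0, end = 1)
  doms <- vapply(c(0, 0.1, 0.2, 0.5, 1), function(f) {
    p <- nb_detection_params(min_contribution_fraction = f, min_channels = 1)
    nb <- apply_channel_criteria(b, sl, "A", p)
    if (nrow(nb)) nb$n_dominating else 0L
  }, integer(1))
  expect_true(all(diff(doms) <= 0))
})

test_that("full NB pipeline recovers planted bursts with clean structure", {
  p <- simulation_params(duration = 600, background_rate = 0.2,
                         nb_rate = 20, nb_duration_mean = 1,
                         nb_duration_sd = 0.2, nb_count = 40,
                         cb_coupling = 1, icb_coupling = 0, seed = 23)
  sim <- simulate_spike_lists(p)
  nb <- detect_network_bursts(sim$spikes, "A")
  truth <- sim$truth$by_compartment$A
  # disjoint, ordered; spike_count consistent with per-channel counts
  expect_true(all(nb$start < nb$end))
  expect_true(all(nb$end[-nrow(nb)] < nb$start[-1]))
  expect_equal(nb$spike_count,
               vapply(nb$per_channel_counts, sum, numeric(1)))
  expect_true(all(vapply(seq_len(nrow(nb)), function(i)
    all(nb$dominating[[i]] %in% nb$participating[[i]]), logical(1))))
  # every planted burst is hit by exactly one detection
  hits <- vapply(seq_len(nrow(truth)), function(i)
    sum(pmin(nb$end, truth$end[i]) - pmax(nb$start, truth$start[i]) > 0),
    numeric(1))
  expect_gte(mean(hits == 1), 0.9)
  # no spurious bursts outside planted epochs
  false_nb <- vapply(seq_len(nrow(nb)), function(j)
    all(pmin(nb$end[j], truth$end) - pmax(nb$start[j], truth$start) <= 0),
    logical(1))
  expect_lte(sum(false_nb) / nrow(truth), 0.05)
})

test_that("a silent or unimodal compartment reports zero bursts gracefully", {
  lay <- tiny_layout()
  sl <- spike_list(lay, list(A00 = c(0.1, 0.5)), 10)
  nb <- detect_network_bursts(sl, "A")
  expect_equal(nrow(nb), 0L)
  set.seed(25)
  spk <- lapply(setNames(nm = electrode_labels(lay, "B")), function(lb)
    sort(runif(500, 0, 600)))
  sl2 <- spike_list(lay, spk, 600)
  expect_message(nb2 <- detect_network_bursts(sl2, "B"), "unimodal")
  expect_equal(nrow(nb2), 0L)
})
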