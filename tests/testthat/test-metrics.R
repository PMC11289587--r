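test_that("the eight parameters match hand-computed fixtures", {
  lay <- tiny_layout()
  # two bursts [0,1] with 10 spikes and [2,3] with 20, plus 10 spikes
  # outside bursts: 40 total
  sl <- spike_list(lay, list(
    A00 = seq(0.05, 0.95, length.out = 10),
    A01 = seq(2.05, 2.95, length.out = 20),
    A02 = seq(4.1, 5.9, length.out = 10)), 6)
  b <- data.frame(start = c(0, 2), end = c(1, 3))
  p <- burst_parameters(b, sl, "A")
  expect_equal(unname(p["mean_ibi"]), 1)
  expect_equal(unname(p["mean_burst_duration"]), 1)
  expect_equal(unname(p["mean_spike_frequency_in_bursts"]), 15)
  expect_equal(unname(p["percent_spikes_in_bursts"]), 75)
  expect_equal(unname(p["mean_spikes_in_bursts"]), 15)
  expect_equal(unname(p["total_bursts"]), 2)
  expect_equal(unname(p["mean_channels_in_bursts"]), 1)
  expect_equal(unname(p["mean_dominating_channels_in_bursts"]), 1)
})

test_that("parameter edge cases are undefined, never silent zeros", {
  lay <- tiny_layout()
  sl <- spike_list(lay, list(A00 = c(0.2, 0.4)), 2)
  one <- burst_parameters(data.frame(start = 0.1, end = 0.5), sl, "A")
  expect_true(is.na(one["mean_ibi"]))
  expect_equal(unname(one["total_bursts"]), 1)
  expect_equal(unname(one["percent_spikes_in_bursts"]), 100)
  none <- burst_parameters(data.frame(start = numeric(0), end = numeric(0)),
                           sl, "A")
  expect_equal(unname(none["total_bursts"]), 0)
  expect_true(all(is.na(unclass(none)[names(none) != "total_bursts"])))
})

test_that("hand fixtures hold across scopes, translation and more shapes", {
  lay <- tiny_layout()
  mk <- function(shift = 0) spike_list(lay, list(
    A00 = shift + c(0.1, 0.2, 0.3, 1.5),
    A01 = shift + c(0.15, 0.25),
    B00 = shift + c(0.12, 0.22, 3.0)), 10 + shift)
  b <- data.frame(start = 0.05, end = 0.35)
  # compartment scope counts only A spikes: 5 of 6 A spikes in burst
  pA <- burst_parameters(b, mk(), "A")
  expect_equal(unname(pA["percent_spikes_in_bursts"]), 100 * 5 / 6)
  expect_equal(unname(pA["mean_spikes_in_bursts"]), 5)
  expect_equal(unname(pA["mean_channels_in_bursts"]), 2)
  # platform scope pools B as well: 7 of 9 spikes
  pAll <- burst_parameters(b, mk(), NULL)
  expect_equal(unname(pAll["percent_spikes_in_bursts"]), 100 * 7 / 9)
  expect_equal(unname(pAll["mean_channels_in_bursts"]), 3)
  # time translation leaves the percentage invariant
  b2 <- data.frame(start = 5.05, end = 5.35)
  pT <- burst_parameters(b2, mk(5), "A")
  expect_equal(unname(pT["percent_spikes_in_bursts"]),
               unname(pA["percent_spikes_in_bursts"]))
  # three-burst fixture with unequal rates
  sl3 <- spike_list(lay, list(
    A00 = c(seq(0.0, 0.5, length.out = 6), seq(2, 2.25, length.out = 3),
            seq(4, 4.5, length.out = 2))), 6)
  b3 <- data.frame(start = c(0, 2, 4), end = c(0.5, 2.25, 4.5))
  p3 <- burst_parameters(b3, sl3, "A")
  expect_equal(unname(p3["mean_ibi"]), mean(c(2 - 0.5, 4 - 2.25)))
  expect_equal(unname(p3["mean_spike_frequency_in_bursts"]),
               mean(c(6 / 0.5, 3 / 0.25, 2 / 0.5)))
  expect_equal(unname(p3["percent_spikes_in_bursts"]), 100)
})

test_that("exact Wilcoxon p matches 2^n enumeration and the n=11 closed form", {
  # all-increase, distinct ranks, n = 11: p = 2 / 2^11
  before <- 1:11
  after <- before + seq(0.5, 5.5, by = 0.5)
  expect_equal(paired_wilcoxon(before, after), 2 / 2^11)
  expect_warning(p_zero <- paired_wilcoxon(1:5, 1:5), "zero")
  expect_equal(p_zero, 1)
  # random instances with ties and zeros, n <= 12, against brute force
  set.seed(28)
  for (rep in 1:60) {
    n <- sample(2:10, 1)
    d <- sample(c(-3, -2, -1, 0, 1, 2, 3), n, replace = TRUE) / 2
    p_pkg <- suppressWarnings(paired_wilcoxon(rep(0, n), d))
    p_brute <- brute_signed_rank_p(d)
    expect_equal(p_pkg, p_brute, tolerance = 1e-12)
  }
})

test_that("exact Wilcoxon p agrees with stats::wilcox.test on tie-free data", {
  set.seed(29)
  for (rep in 1:25) {
    n <- sample(4:20, 1)
    before <- rnorm(n)
    after <- before + rnorm(n)
    p_pkg <- paired_wilcoxon(before, after)
    p_ref <- stats::wilcox.test(after, before, paired = TRUE,
                                exact = TRUE)$p.value
    expect_equal(p_pkg, p_ref, tolerance = 1e-12)
  }
})

test_that("Bonferroni level is alpha over the family size", {
  expect_identical(bonferroni_alpha(0.05, 8), 0.00625)
  expect_identical(bonferroni_alpha(0.05, 1), 0.05)
  expect_identical(bonferroni_alpha(0.10, 4), 0.025)
})

test_that("compare_parameters flags significance at both levels", {
  set.seed(30)
  before <- matrix(rnorm(11 * 8, 10), ncol = 8,
                   dimnames = list(NULL, paste0("p", 1:8)))
  after <- before
  after[, 1] <- after[, 1] + 5        # strong shift: beats 0.00625
  after[, 2] <- after[, 2] + c(rep(0.8, 8), -0.4, -0.2, -0.1)
  cmp <- suppressWarnings(compare_parameters(before, after))
  expect_equal(cmp$adjusted_alpha, rep(0.00625, 8))
  expect_true(cmp$significant_adjusted[1])
  expect_false(cmp$significant_adjusted[2] && !cmp$significant_raw[2])
  expect_equal(cmp$p_value[1], 2 / 2^11)
})

test_that("binned percent change normalizes to the last baseline bin", {
  base <- matrix(c(10, 4, 10, 5), nrow = 2,
                 dimnames = list(c("a", "b"), NULL))
  expo <- matrix(c(10, 10, 20, 5, 7, 2.5), nrow = 2,
                 dimnames = list(c("a", "b"), NULL))
  pc <- binned_percent_change(base, expo)
  expect_equal(unname(pc["a", ]), c(0, 100, -30))
  expect_equal(unname(pc["b", ]), c(100, 0, -50))
  # clipping only caps the display copy
  expect_equal(unname(clip_percent_change(pc)["a", ]), c(0, 50, -30))
  # undefined reference propagates as NA
  base_na <- base; base_na["a", 2] <- NA
  expect_true(all(is.na(binned_percent_change(base_na, expo)["a", ])))
})

test_that("binned parameters segment a recording into 5 min bins", {
  lay <- tiny_layout()
  spk <- list(A00 = c(seq(10, 11, length.out = 30),
                      seq(310, 311, length.out = 30),
                      seq(610, 611.5, length.out = 30)))
  sl <- spike_list(lay, spk, 900)
  b <- data.frame(start = c(10, 310, 610), end = c(11, 311, 611.5))
  m <- binned_parameters(b, sl, "A", bin_width = 300)
  expect_equal(dim(m), c(8L, 3L))
  expect_equal(unname(m["total_bursts", ]), c(1, 1, 1))
  expect_equal(unname(m["mean_burst_duration", ]), c(1, 1, 1.5))
  expect_true(all(is.na(m["mean_ibi", ])))
})
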