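---
title: "Multilevel burst and connectivity analysis for compartmentalized MEA recordings"
author: "circuitburst"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multilevel burst and connectivity analysis for compartmentalized MEA recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circuitburst)
```

## The problem

Compartmentalized microfluidic MEA platforms culture three separate neuronal
networks (compartments A, B, C; 24 electrodes each) connected by bundles of
microtunnels, so that both local activity within a compartment and global
activity of the closed circuitry can be recorded. Conventional MEA burst
detectors were designed for single networks and say nothing about synchrony
*between* networks. `circuitburst` implements a complete analysis chain for
such recordings:

1. **Spike detection** from raw 25 kHz traces — amplitude thresholding
   refined by a stationary-wavelet Teager-energy (SWTTEO) consensus.
2. **Network bursts (NBs)** per compartment — an ISI_N-threshold core with
   adaptive merging, optional short-burst removal and channel-participation
   criteria.
3. **Circuitry bursts (CBs)** — maximal intervals where all three
   compartments burst simultaneously — and **intermediate circuitry bursts
   (ICBs)** where exactly two do.
4. A **surrogate time-shift test** that the observed intercompartmental
   alignment is not coincidental.
5. **Eight burst output parameters** with paired Wilcoxon statistics and
   Bonferroni correction, plus 5-minute-binned percent-change summaries.
6. **CorSE functional connectivity** — correlated spectral entropy of raw
   signals, capturing LFP-level coupling independent of spike detection.
7. A **synthetic-data generator** that produces ground-truth-annotated spike
   lists and raw traces for every stage.

## Network-burst detection

### The ISI_N core

All spikes of a compartment are pooled into one train. The statistic
ISI_N(i) = t[i+N−1] − t[i] is the time span covered by N consecutive spikes
(default N = 20). In a network that alternates between synchronous bursting
and sparse background firing, the histogram of log10(ISI_N) is bimodal:
short spans inside bursts, long spans outside. The detection threshold is
the abscissa of the minimum of the smoothed histogram strictly between the
two highest peaks. Spike windows whose span does not exceed the threshold
mark bursts; a burst runs from the first spike of its first qualifying
window to the last spike of its last one.

The histogram internals are package choices, exposed in
`nb_detection_params()`: 40 bins per decade over the observed log-range,
Gaussian smoothing with SD = 2 bins, and a peak prominence floor of 1% of
the histogram maximum. When the histogram has fewer than two peaks the
compartment is reported as unimodal and *no* bursts are returned — we
deliberately do not fall back to a fixed threshold, because that would
silently change the semantics of the detector on non-bursting data.

### Enhancement steps

* **Adaptive merging** (default fraction 0.2): two neighbouring bursts are
  merged when the gap between them (end of the first to start of the next)
  is smaller than the merging fraction times the duration of the longer of
  the two. The rule adapts to burst length instead of using a fixed gap, and
  is iterated to a fixpoint.
* **Short-burst removal** is available (`min_duration`) but disabled by
  default; well-developed cultures rarely need it.
* **Channel criteria**: per burst, electrodes with at least one spike
  *participate*; the mean channel contribution is the burst spike count
  divided by the number of participating channels; electrodes reaching
  0.15 of that mean *dominate*. Bursts with fewer than 3 dominating
  channels are rejected. Dividing by participating channels (instead of all
  24) stops silent electrodes from diluting the mean; the alternative is
  available via `contribution_denominator = "all"`.

### Boundary accuracy — a known limitation

The STEP-1 boundary convention ties burst edges to qualifying ISI_N
windows. Because the threshold sits at the histogram valley (typically
~0.2 s for bursts at a few hundred Hz pooled rate over ~5 Hz pooled
background), any background spike within (threshold − in-burst span) of a
true burst edge is absorbed into the burst. At a pooled background rate of
~5 Hz this happens at roughly half of all burst borders and extends them by
up to ~0.15 s. Detection and false-positive performance are unaffected —
synthetic 30-minute compartments give 100% burst recovery with 0% false
bursts — but sub-100 ms edge accuracy cannot be promised at those firing
rates; in our synthetic benchmark only ~30–80% of borders (seed-dependent)
are within 100 ms. Users needing sharper onsets should treat NB edges as
approximate or post-process with a rate-based edge refinement.

## Circuitry-level classification

CBs are maximal intervals in which all three compartments have an ongoing
NB (three-way closed-interval intersection; point contacts are not events;
zero lag is assumed by default because the many microtunnels make
propagation delays negligible — `lag_tolerance` admits slack if wanted).
ICB candidates are the pairwise intersections; a candidate that temporally
overlaps any CB is *associated with* that CB and discarded entirely rather
than trimmed, which avoids counting sub-second remnants flanking every CB
as separate two-compartment events (`cb_exclusion = "trim"` restores the
trimming alternative). A plate shows *full synchrony* when every NB
participates in some CB, and *no-ICB* when no ICBs remain; the labels are
not exclusive.

## The surrogate alignment test

The test metric is the cumulative CB duration. Each of n_simulations
(default 5000) surrogates shifts every compartment's NB intervals by an
independent delta drawn uniformly from [−20, 20] s, wrapping circularly at
the recording boundary (circular wrap preserves each compartment's total
burst time; truncation would change the metric's support). For each
alignment i the statistic u_i = |x_i − mean of the other scores| is
computed, and the empirical p is the descending rank of u_observed divided
by n = n_simulations + 1; alignment is declared non-random at p ≤ 0.05.
Ties in the ranking place the observed value first (anti-conservative);
ties have measure zero for continuous metrics and the opposite convention
is a parameter. Under independently generated compartments the test rejects
at ~5% as it should (calibration is part of the test suite), and perfectly
coupled compartments give p = 1/(n_sims+1).

## Burst output parameters and statistics

Eight parameters characterize a burst set: mean IBI (end-to-start gaps, the
same convention the merging step uses), mean burst duration, mean spike
frequency in bursts (per-burst rates averaged; the pooled-ratio alternative
is a parameter), percentage of spikes in bursts, mean spikes in bursts,
total bursts, mean channels in bursts, and mean dominating channels in
bursts. NB-level parameters are scoped to one compartment's 24 electrodes;
CB-level parameters pool all 72, since CBs are platform-wide events.
Undefined quantities (no bursts; a single burst for the IBI) propagate as
`NA`, never as zeros, so they cannot bias paired tests.

Before/after comparisons use the Wilcoxon matched-pairs signed-rank test.
The exact two-sided p is computed for up to 25 non-zero differences by
convolving the signed-midrank distribution (midrank sums are multiples of
0.5, so the distribution table is small even with ties); zero differences
are dropped. With eight parameters per level, the Bonferroni-adjusted level
is 0.05/8 = 0.00625. Time-variant effects are summarized by 5-minute bins
normalized to the last baseline bin; the ±50% clipping applies only to
rendered heatmaps, never to the numeric tables.

## CorSE functional connectivity

Each electrode's raw trace is cut into 1 s windows; per window the power
spectrum is estimated by Welch averaging of rectangular (mean-removed)
segments with 50% overlap, and the normalized Shannon entropy
H = −Σ p log p / log K over the K positive-frequency bins is recorded.
H is 1 for a flat spectrum, 0 when all power sits in one bin, and is
invariant to amplitude scaling. Connectivity of an electrode pair (CorSE)
is the maximum absolute normalized cross-correlation of the two
mean-removed entropy series over lags up to 5 windows. The untapered
segments are deliberate: with a Hann taper a pure sinusoid leaks into
neighbouring bins and its entropy floors near 0.16, destroying the
single-bin limit that anchors the scale of the measure. Broadband traces
are used whole (no sub-band split); windows undefined in either series are
dropped pairwise; constant series give `NA`, and a result with more than
half its pairs undefined is flagged low-confidence. Averages are reported
within each compartment (276 pairs at full layout) and between each pair of
compartments (576 pairs).

## The synthetic-data generator

`simulate_spike_lists()` emulates a 30-minute three-compartment recording:
homogeneous Poisson background per electrode (default 0.2 Hz), 100 planted
burst epochs of 1 ± 0.2 s in which half of a compartment's electrodes fire
at 20 Hz (rectangular rate profile — the simplest shape with unambiguous
onset/offset truth), and epoch membership drawn as all-three / a random
pair / a single compartment with probabilities (0.8, 0.1, 0.1) by default.
Epochs are non-overlapping with a minimum gap of twice the mean duration so
the planted truth is unambiguous. These defaults reflect the study
conditions the package targets: 30-minute sessions, tens to ~180 bursts
per compartment, sparse background firing typical of hPSC-derived cortical
cultures. `simulate_raw()` adds Gaussian noise (5 µV), a fixed ~1 ms
biphasic template at 8× noise SD per spike, and an optional 10 Hz
narrowband component whose slow power envelope is shared across electrodes
at a controllable strength — the envelope modulates spectral *content*, not
just amplitude, because spectral entropy is amplitude-blind by design.

What the generator does **not** emulate: electrode-to-electrode amplitude
and waveform variability, spike sorting ambiguity, bursts with ramped
onsets, propagation delays between compartments, non-stationary background
rates, and technical artifacts. Passing tests on this generator therefore
validate the algorithmic contracts (recovery, calibration, invariances),
not end-to-end performance on arbitrary real recordings.

## Numerical choices

* Intervals are closed at spike-time resolution; intersections of measure
  zero are discarded everywhere.
* The elliptic band-pass (order 4, 0.1 dB ripple, 40 dB stopband) is
  applied forward–backward, so detection timing is zero-phase.
* The noise SD uses median(|x|)/0.6745; the plain SD is available but
  inflates with spike content.
* The SWTTEO score uses Haar SWT detail level 3 at 25 kHz: the level-3 band
  (~1.6–3.1 kHz) covers the sharp transient of a ~1 ms extracellular spike,
  whereas level 2 (~3.1–6.25 kHz) falls mostly above the 3 kHz filter edge
  and discriminates poorly. Smoothing uses a 1 ms moving average — the full
  spike-energy envelope — so each spike contributes one score peak. Top-M
  peak ties break by earlier time, for determinism.
* Problem sizes in the validation suite (60 s lattices for the interval
  oracle, 10 s traces for detection, 300 s recordings for connectivity
  coupling curves, 200 × 500 surrogate calibration runs) were chosen so
  that each check is statistically decisive at desk scale.

## Reproducing the analysis

`run_pipeline()` executes the full chain on a `spike_list` (or a raw
`mea_recording`), and the `exec/circuitburst` script exposes every stage as
a shell command driven by a single YAML configuration whose defaults equal
the documented parameter values. `scripts/acceptance.R` regenerates the
package's validation quantities from scratch under a caller-supplied seed.
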