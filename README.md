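# circuitburst

Multilevel synchronous-burst and functional-connectivity analysis for
compartmentalized microelectrode-array (MEA) recordings.

## The problem

Brain-on-a-chip platforms increasingly separate neuronal cultures into
several microfluidically isolated compartments connected by microtunnels,
with an embedded MEA recording each compartment (here: three compartments
A, B, C with 24 electrodes each, sampled at 25 kHz). Classic MEA burst
detectors describe a single network; they cannot say when *the whole
circuitry* fires together, nor whether the apparent intercompartmental
synchrony could be a coincidence. `circuitburst` provides the full analysis
chain for such data:

- **Spike detection**: zero-phase elliptic band-pass (200–3000 Hz),
  amplitude threshold at 4.5× a robust noise-SD estimate, refined by a
  stationary-wavelet Teager-energy (SWTTEO) score; only spikes found by
  both detectors are kept.
- **Network bursts (NBs)** per compartment via the ISI_N statistic
  (N = 20): the span t[i+N−1] − t[i] of N consecutive pooled spikes has a
  bimodal log-histogram in bursting networks, and the valley between the
  two modes gives an adaptive detection threshold. Enhancements: adaptive
  merging (fraction 0.2), optional short-burst removal, minimum 3
  dominating channels with a 0.15 minimum individual channel contribution.
- **Circuitry bursts (CBs)**: maximal intervals where all three
  compartments burst simultaneously; **intermediate circuitry bursts
  (ICBs)**: two-compartment intersections not associated with any CB.
- **Surrogate time-shift test**: each compartment's NBs are circularly
  shifted by independent random deltas in [−20, 20] s (5000 surrogates);
  the cumulative CB duration x yields u_i = |x_i − mean of the others|,
  and the empirical p is the descending rank of u_observed over n;
  alignment is non-random at p ≤ 0.05.
- **Eight burst output parameters** (mean IBI, mean duration, mean in-burst
  spike frequency, % spikes in bursts, mean spikes per burst, burst count,
  mean channels, mean dominating channels) with exact paired Wilcoxon
  signed-rank tests and the Bonferroni level 0.05/8 = 0.00625, plus
  5-minute-binned percent changes against the last baseline bin.
- **CorSE connectivity**: windowed power-spectrum Shannon entropy per
  electrode, maximum-lag cross-correlation per electrode pair, averaged
  within and between compartments.
- **Synthetic data**: ground-truth-annotated spike lists and raw traces
  (Poisson background, planted multi-compartment burst epochs, spike
  templates, coupled slow spectral envelopes) for validating every stage.

## Worked example

```r
library(circuitburst)

# a 15 min synthetic platform recording: 40 planted burst epochs, 80%
# shared by all three compartments, 10% by a random pair
p <- simulation_params(duration = 900, nb_count = 40,
                       cb_coupling = 0.8, icb_coupling = 0.1, seed = 7)
sim <- simulate_spike_lists(p)

cfg <- pipeline_config()
cfg$surrogate$n_simulations <- 1000L
rep <- run_pipeline(sim$spikes, config = cfg)
print(rep)
#> Circuit analysis report
#>   QC: 0 flagged bin(s)
#>   NB A: 34 bursts
#>   NB B: 36 bursts
#>   NB C: 36 bursts
#>   CB: 30, ICB: 6 [mixed]
#>   surrogate test: p = 0.000999 (non-random)
```

The generator planted 30 three-compartment epochs and 6 pair epochs; the
pipeline recovers 30 CBs and 6 ICBs and rejects the coincidental-alignment
null at p = 1/1001 (the observed cumulative CB duration, 31.5 s, is far
outside the shifted ensemble, whose mean is 0.07 s). Per-compartment
parameters:

```r
print(rep$parameters$NB_A)
#> Burst output parameters:
#>   mean_ibi                             24.399
#>   mean_burst_duration                  1.1025
#>   mean_spike_frequency_in_bursts       238.97
#>   percent_spikes_in_bursts             67.86
#>   mean_spikes_in_bursts                261.94
#>   total_bursts                         34
#>   mean_channels_in_bursts              14.588
#>   mean_dominating_channels_in_bursts   12.059
```

Here `mean_spike_frequency_in_bursts` is the pooled in-burst firing rate of
the compartment (~12 active electrodes × 20 Hz ≈ 240 Hz), and two thirds of
all spikes fall inside bursts. A command-line front-end wraps every stage
(`simulate`, `detect-spikes`, `detect-bursts`, `detect-circuitry`,
`metrics`, `surrogate-test`, `connectivity`, `pipeline`):

```sh
Rscript exec/circuitburst simulate --seed 3 --out-prefix run
Rscript exec/circuitburst detect-bursts --spikes run_spikes.csv --duration 1800 --out bursts.json
Rscript exec/circuitburst surrogate-test --bursts bursts.json --duration 1800 --n 5000 --seed 1
```

## Package layout

- `R/layout.R`, `R/io.R` — platform layout, HDF5/CSV I/O, noise QC
- `R/spike_detection.R` — filtering, thresholding, SWTTEO consensus
- `R/network_bursts.R` — ISI_N core and enhancement steps
- `R/circuitry.R` — CB/ICB intersection and synchrony labels
- `R/metrics.R` — the eight parameters, Wilcoxon/Bonferroni, binning
- `R/surrogate.R` — time-shift surrogate test
- `R/corse.R` — spectral-entropy connectivity
- `R/synthetic.R` — synthetic spike lists and raw traces
- `R/pipeline.R` — configuration and end-to-end orchestration
- `vignettes/circuitburst-methods.Rmd` — the methods account, including
  known limitations (NB border accuracy at high background rates)
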