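Package: circuitburst
Title: Multilevel Synchronous Burst and Connectivity Analysis for
    Compartmentalized MEA Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of extracellular recordings from compartmentalized
    microelectrode-array (MEA) platforms in which three separated neuronal
    networks (compartments A, B, C; 24 electrodes each) are interconnected
    through microtunnels. Provides spike detection combining an amplitude
    threshold with a stationary-wavelet-transform Teager-energy-operator
    (SWTTEO) refinement; adaptive network-burst detection built on the
    ISI_N-threshold core with adaptive merging, short-burst removal and
    channel-participation criteria; circuitry-level burst classification by
    temporal intersection of per-compartment network bursts (three-compartment
    circuitry bursts and two-compartment intermediate circuitry bursts); a
    surrogate time-shift test for non-random intercompartmental alignment;
    eight burst output parameters with paired Wilcoxon statistics and
    Bonferroni correction; spectral-entropy cross-correlation (CorSE)
    functional connectivity; and a synthetic-data generator producing
    ground-truth-annotated spike lists and raw traces for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    rhdf5,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
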