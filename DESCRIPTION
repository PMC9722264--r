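Package: cortexwaves
Title: Simulation and Analysis of Cortical Slow-Wave and Persistent-Activity Dynamics
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for studying the two dominant mesoscale cortical activity
    states in rodent sensory cortex: slow wave activity (SWA, large propagating
    waves separated by silent periods) and persistent activity (PA, continuous
    small-amplitude fluctuations). Provides a ground-truth synthetic data
    generator (fiber-photometry calcium traces, LFP-like signals, and
    wide-field calcium movies with refractory-gated, stimulus-evoked
    propagating waves), df/f normalization and Gaussian low-pass filtering,
    threshold-based slow-wave event detection, stimulus-locked latency
    estimation with shuffled-onset controls, cross-correlation and
    inter-regional delay analysis, pixel-wise response-time maps and
    gradient-based propagation velocity fields, activation-probability
    distributions with permutation testing, multitaper spectrograms from DPSS
    tapers, band-limited log fold-change quantification, power-threshold
    slow-wave onset detection, refractory-period estimation from binned
    stimulus success rates, and weighted circular statistics with a
    permutation two-sample Kuiper test.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    signal,
    jsonlite,
    yaml,
    tiff
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'geometry.R'
    'simconfig.R'
    'synth-stimuli.R'
    'synth-events.R'
    'synth-render.R'
    'photometry.R'
    'widefield.R'
    'spectral.R'
    'refractory.R'
    'circstats.R'
    'io.R'
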