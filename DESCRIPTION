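Package: fanotune
Title: State-Dependent Tuning of Spike-Count Variability and Its Impact on
    Population Decoding
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing direction tuning of spike-count variability
    in visual cortical neurons across behavioural states. Implements Fano
    factor tuning indices and mean-matched comparisons, a doubly-stochastic
    multiplicative-gain model of count variance with population and
    per-neuron fitting procedures, spike-count autocorrelation time-constant
    estimation, mutual information with quadratic-extrapolation bias
    correction, and linear Fisher information decoding of model populations
    with information-limiting correlations. Includes a seeded synthetic-data
    generator that reproduces the statistical structure these analyses
    assume, so the full pipeline is testable without recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    MASS,
    minpack.lm,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'autocorr.R'
    'decoding.R'
    'direction-stats.R'
    'fanotune-package.R'
    'gain-fit.R'
    'latency.R'
    'mean-match.R'
    'mutual-info.R'
    'pipeline.R'
    'synthetic-counts.R'
    'synthetic-population.R'
    'synthetic-trains.R'
    'tuning.R'
    'utils.R'
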