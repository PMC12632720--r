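Package: fncBrainAge
Title: Brain-Age Modelling from Static and Dynamic Functional Network Connectivity
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: End-to-end pipeline for brain-age analysis of independent-component
    fMRI time courses. Computes static functional network connectivity (sFNC) and
    tapered sliding-window dynamic connectivity (dFNC), trains wide-brain and
    per-network brain-age regressors (ridge baseline, bidirectional LSTM sequence
    model, connectome graph-convolution model), derives brain-age gaps (BAG), and
    tests their association with cognitive scores in covariate-adjusted linear
    models with Benjamini-Hochberg FDR control. Includes a synthetic cohort
    generator with age-dependent, slowly drifting connectivity so that every
    stage is testable without access-controlled imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    signal,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'utils-internal.R'
    'partition.R'
    'taper.R'
    'correlation.R'
    'clean.R'
    'fnc.R'
    'synthcohort.R'
    'cohort-io.R'
    'nnet-core.R'
    'brainage.R'
    'bagstats.R'
    'pipeline.R'
    'show-methods.R'
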