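Package: optomap
Title: Optogenetic Circuit Mapping and Quantal Analysis of Synaptic Inputs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for optogenetic and photostimulation mapping of
    synaptic input strength onto individually recorded neurons. Converts raw
    voltage-clamp sweeps into evoked-response amplitudes (windowed peak or mean
    measures of averaged EPSCs), classifies and subtracts direct
    photostimulation responses by double-exponential fitting, detects quantal
    events from strontium-desynchronized release and partitions them into
    spontaneous and evoked windows, assembles soma- or barrel-aligned
    two-dimensional input maps with conservative masking and bilinear
    interpolation, and applies normality-gated paired statistics,
    coefficient-of-variation and interaction ANOVA analyses to paired-neuron
    (double-patch) designs. Includes a synthetic-experiment generator with
    known ground truth emulating grid photostimulation, binomial quantal
    release and asynchronous release, so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    data.table,
    minpack.lm,
    nortest,
    emmeans
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'accessors.R'
    'utils.R'
    'events.R'
    'io.R'
    'maps.R'
    'pipeline.R'
    'stats.R'
    'synthgen.R'
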