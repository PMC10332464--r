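Package: daquant
Title: Quantification of Dopaminergic Neurodegeneration in Drosophila
    Whole-Brain Fluorescence Microscopy
Version: 0.1.0
Authors@R:
    person("Drosophila", "Neurotools", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to quantify dopaminergic (DAergic) neurodegeneration in
    whole-mount Drosophila brains from fluorescence-microscopy z-stacks:
    per-neuron region-of-interest (ROI) intensity quantification across an
    11-slice z-window, aggregation to cluster and whole-brain fluorescence
    intensity (FI), difference-of-Gaussian neuron detection and counting
    against a cluster atlas, and maximum-intensity projections for
    presentation.  Companion quantifications cover HPLC-ECD catecholamine
    measurement (peak integration, retention-time identification, spiking
    confirmation, and the V1-V8 normalization chain with dopamine turnover),
    whole-protein-normalized western-blot densitometry, and negative-geotaxis
    climbing metrics.  A synthetic-data module generates ground-truthed
    brain volumes, chromatograms, densitometry tables and mobility records
    so that every stage of the pipeline can be validated without microscope
    or instrument access.  Group comparisons use SEM, unpaired t-tests,
    one-way ANOVA and the Newman-Keuls studentized-range procedure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
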