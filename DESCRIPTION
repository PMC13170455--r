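Package: TcellFlux
Title: Transcriptome-Constrained Metabolic Modelling of T Cell Subsets
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Constraint-based metabolic modelling toolkit for comparing T cell
    subsets in silico. Builds context-specific genome-scale metabolic models by
    combining flux-consistency testing and fastcore extraction with
    expression-derived reaction scores and eFlux bound scaling, then
    interrogates the models with flux balance analysis, flux variability
    analysis, artificial-centering hit-and-run flux sampling, an in silico
    enzyme-inhibitor panel, a mitochondrial superoxide-production challenge
    with superoxide-fate accounting, and metabolite production-capacity
    analyses (ATP, NADPH, lactate). Reads and writes SBML Level 3 (fbc) and
    COBRA-style JSON models. Ships a fully synthetic test bed: a hand-authored
    three-compartment toy network of central T cell metabolism and three
    cell-type expression archetypes (an activated glycolytic/glutaminolytic
    subset, a metabolically flexible effector subset, and a resting oxidative
    subset), so the entire pipeline runs without any download.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    xml2,
    jsonlite,
    rlang
Suggests:
    testthat (>= 3.0.0),
    boot
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllGenerics.R'
    'AllClasses.R'
    'consistency.R'
    'expression.R'
    'fba.R'
    'gpr.R'
    'lp.R'
    'model-io.R'
    'perturbation.R'
    'pipeline.R'
    'ros.R'
    'sampling.R'
    'synthetic.R'
    'utils.R'
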