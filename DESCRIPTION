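Package: nativeTDP
Title: Native Top-Down Identification of Protein Complexoforms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An engine for identifying protein complexoforms -- oligomeric
    assemblies of specific proteoforms plus metal cofactors -- from native
    multistage mass spectrometry (MS1/MS2/MS3) data. Provides exact mass
    chemistry (elemental compositions, modification and metal-adduct deltas,
    isotope distributions), a proteoform/complexoform data model with a
    ProForma-inspired text notation, centroided spectrum input/output with
    MS1-MS2-MS3 precursor linkage, native charge-state deconvolution,
    intact-mass complexoform search at a configurable (default 1 Da)
    tolerance, HCD b/y fragment matching with a Poisson P-score, PTM
    localization by bracketing fragments, holo/apo metal binding-site
    inference, isotopic-distribution validation, and a ground-truthed
    synthetic spectrum simulator so that every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mzR,
    Biostrings,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'constants.R'
    'composition.R'
    'AllClasses.R'
    'modifications.R'
    'proteoform.R'
    'complexoform.R'
    'searchspace.R'
    'spectrum-io.R'
    'mzml.R'
    'deconvolve.R'
    'search.R'
    'fragments.R'
    'pscore.R'
    'localize.R'
    'isotope-fit.R'
    'simulate.R'
    'fixtures.R'
    'pipeline.R'
    'report.R'
    'nativeTDP-package.R'
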