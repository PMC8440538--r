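Package: xenoID
Title: Enzyme-Based Identification of Xenobiotic Metabolites from
    High-Resolution Mass Spectrometry Feature Tables
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for identifying xenobiotic metabolites in untargeted
    liquid chromatography high-resolution mass spectrometry (LC-HRMS)
    data using libraries of enzymatically generated (liver S9 fraction)
    metabolites. Provides elemental-formula and monoisotopic-mass
    arithmetic with stable-isotope labels, rule-based biotransformation
    enumeration, discovery of enzyme-generated metabolites from
    incubation time courses, stable-isotope pairing of labeled and
    unlabeled experiments, library matching with an orthogonal-criteria
    confidence-level scheme, co-occurrence analysis across samples and
    biofluids, mass-shift biotransformation networks, and a synthetic
    feature-table generator with ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mixOmics
Config/testthat/edition: 3
RoxygenNote: 7.3.3
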