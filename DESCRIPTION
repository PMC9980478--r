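Package: bbbaxis
Title: Blood-Brain Barrier Permeability Imaging and Metabolite Compartment Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantification of blood-brain barrier (BBB) integrity in the
    developing mouse brain from variable-repetition-time relaxometry and
    time-of-flight angiography, together with curation and compartment
    analysis of untargeted LC-MS metabolomics. Provides saturation-recovery
    T1 map fitting, vessel segmentation and volumetry, a contrast-based
    permeability index (delta-T1 per unit vessel volume), a five-step
    feature-curation cascade (solvent-blank filter, internal-standard
    normalization, method-blank filter, pooled-QC percent-CV filter,
    contaminant removal) with a full audit trail, per-feature one-way ANOVA
    with Benjamini-Hochberg control, serum/brain significant-pool
    partitioning, and presence-based classification of metabolites that
    newly cross the BBB under a treatment. A synthetic-data module generates
    MRI phantoms and feature tables with known ground truth so every stage
    is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
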