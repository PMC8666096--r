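Package: scdproteome
Title: Plasma Proteomic Discovery and Immunoassay Verification of
    Brain-Injury Biomarkers in Sickle Cell Disease
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A label-free spectral-counting workflow for discovering
    brain-derived proteins in plasma of children with sickle cell disease
    and verifying a candidate by sandwich immunoassay. Implements
    peptide-spectrum-match acceptance filtering, greedy sequence-identity
    (CD-HIT style) redundancy collapsing, group-wise presence/absence and
    spectral-count fold-change screening, brain-enrichment scoring from
    microarray/EST/SAGE tissue compendia, and immunoassay processing
    (four-parameter logistic calibration, duplicate QC, limit-of-
    quantification censoring, nonparametric group comparison). A
    synthetic-data module generates every input with planted ground truth
    so the full pipeline is testable without access to raw data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
biocViews: Proteomics, MassSpectrometry, BiomedicalInformatics, Software
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
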