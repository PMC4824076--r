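Package: qpid
Title: Quantitative Protein-DNA Interaction Affinity Analysis
Version: 0.1.0
Authors@R:
    person("QPID", "Maintainers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for quantitative microfluidic protein-DNA
    binding measurements: a seeded simulator of chamber-level chip scans,
    fluorescence calibration and occupancy quantification, equilibrium
    dissociation-constant (Kd) estimation by nonlinear least squares with
    censoring at the assay sensitivity limits, pentamer-table DNA shape
    prediction with normalized shape-distance statistics, design of genomic
    CRE / CRE half-site measurement libraries from ChIP-seq and DNase-seq
    peaks, and multiple-linear-regression models of binding affinity and
    affinity differences on flanking DNA shape features.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
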