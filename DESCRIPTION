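Package: NAPbind
Title: Biophysical and Transcriptomic Analysis of DNA-Bridging
    Nucleoid-Associated Proteins
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to quantify the DNA-binding and gene-silencing activity
    of bacterial nucleoid-associated proteins such as Bacillus subtilis Rok.
    Implements Gaussian-mixture analysis of tethered particle motion (TPM)
    bead excursions with Hill-model occupancy fitting, recovery
    quantification for radiolabeled DNA bridging pull-down assays,
    McGhee-von Hippel lattice-binding isotherm fitting of microscale
    thermophoresis (MST) titrations, an empirical logistic-null
    differential-expression caller with Storey q-values and three-set Venn
    partitioning, protein length-based Rok/sRok classification with
    alignment information-content profiles, and seeded synthetic-data
    generators that emulate each assay for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    Biostrings,
    minpack.lm,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    fitdistrplus,
    mclust,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: Software, Transcriptomics, DifferentialExpression,
    Sequencing
Collate: 
    'AllGenerics.R'
    'AllClasses.R'
    'bridging.R'
    'deg.R'
    'io.R'
    'mst.R'
    'seq.R'
    'simulate.R'
    'tpm.R'
    'utils.R'
    'venn.R'
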