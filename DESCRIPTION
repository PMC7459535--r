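Package: uroCpG
Title: Discovery and Urine-Based Evaluation of Urothelial-Cancer-Specific
    DNA Methylation Markers
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: End-to-end analysis pipeline for identifying CpG methylation
    biomarkers that distinguish urothelial cancer from prostate and renal
    cancer and from non-malignant urological cells. Implements beta/M-value
    handling for 450K-style methylation arrays, per-site moderated linear
    modelling with empirical-Bayes variance shrinkage, a two-stage
    urothelial-specificity selection with in-vitro/in-vivo concordance
    filtering, in-silico simulation of MassARRAY EpiTYPER base-specific
    cleavage (fragment masses, CpG units, mass-collision detection), and
    diagnostic evaluation of urine cohorts (nonparametric group tests,
    ROC/AUC, sensitivity at preset specificity). Ships a seeded synthetic
    data generator that plants ground-truth differential sites and emulates
    tumor-fraction dilution in urine, so the whole pipeline is testable
    against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    GenomicRanges,
    IRanges,
    SummarizedExperiment,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    limma,
    pROC
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: DNAMethylation, DifferentialMethylation, Epigenetics,
    BiomedicalInformatics, Software
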