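Package: fivepsol
Title: Solubility and Co-Translational Decay Analysis of 5'P Degradome Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of 5'P degradome sequencing (5'P-Seq) together with
    matched RNA-Seq of soluble and total mRNA pools. Provides spike-in
    normalized relative degradation and within-sample solubility log fold
    changes with negative-binomial Wald contrasts, a ratio-of-ratios
    interaction test and solubility-category classification, per-codon
    ribosome dwelling occupancy from 5' ends 17 nt upstream of the A-site,
    anchored and CDS-scaled metagene profiles, reading-frame periodicity,
    windowed CDS read proportions, PAR-CLIP T-to-C cross-linking density,
    and ChEC promoter-window signal with free-MNase control and
    mode-centering. A seeded synthetic-data generator emulates the full
    multi-condition fractionation experiment with known ground truth so
    every estimator can be validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    SummarizedExperiment,
    Rsamtools,
    rtracklayer,
    MASS,
    methods,
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    jsonlite,
    knitr,
    rmarkdown,
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
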