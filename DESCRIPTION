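Package: armCompare
Title: Comparative Expression, DNA Methylation and Chromatin Accessibility
    of Homologous Chromosome Arms Across Ploidy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for comparing homologous chromosome arms between a diploid
    progenitor and a polyploid derivative, as in wheat chromosome 3DL versus
    the 3L arm of Aegilops tauschii. Classifies syntenic gene pairs into
    proportionately reduced versus differentially expressed classes with
    cross-ploidy median-ratio TPM normalization; computes context-resolved
    (CpG/CHG/CHH) weighted methylation levels, TSS metaprofiles, filtered
    region aggregates and differentially methylated regions; post-processes
    ATAC-seq output (Tn5 read shifting, replicate-reproducible peaks, peak
    merging, strand-aware region annotation, TSS-distance distributions,
    fragment-length periodicity, per-gene differential accessibility); and
    provides the integration statistics linking the three layers. A seeded
    synthetic-data module emulates the statistical structure of all inputs so
    every stage is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    Biostrings,
    rtracklayer,
    GenomeInfoDb,
    data.table,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: Epigenetics, GeneExpression, DifferentialExpression,
    DNAMethylation, ATACSeq, Software
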