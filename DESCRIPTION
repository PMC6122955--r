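Package: tfTargetScreen
Title: Nomination of Transcription-Factor Target Genes and Their Survival
    Associations from Nascent RNA, ChIP Peaks and Patient Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An integrated screen for direct transcription-factor target
    genes and their clinical relevance. Selects differentially transcribed
    genes from nascent-RNA knockdown contrasts and intersects them across
    cell lines, assigns ChIP-seq peaks to the closest expressed gene's
    transcription start site with a reciprocal-closest rule and classifies
    genes as proximally or distally bound by replicate consensus, scores
    over-representation of an IUPAC consensus or weight-matrix motif in
    promoter windows with a binomial z-score, and links gene sets to patient
    survival through per-gene univariate Cox proportional-hazards models,
    FDR thresholding and a gene-set permutation test against an expressed
    background. A synthetic-data generator with planted ground truth
    (bound genes, knockdown effects, motif insertions, hazard genes) makes
    every stage testable end-to-end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    BiocGenerics,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    survival
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
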