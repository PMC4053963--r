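Package: vlincscan
Title: Calling and Characterizing Very Long Intergenic Non-Coding RNAs from
    RNA-Seq Coverage
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Identifies very long (>= 50 kb) intergenic non-coding RNA
    (vlincRNA) regions from strand-specific RNA-seq coverage contigs or from
    non-strand-specific per-base density tracks, associates the called regions
    with chromatin-state promoters (Active/Weak/Poised) and LTR retroviral
    repeats, and tests the associations with genomic-null binomial
    overlap-enrichment statistics built on an explicit eligible-space model.
    Also provides depth- and length-normalized expression quantification from
    coverage contigs, tissue- and cell-line-specificity indices, stratified
    expression-ratio summaries, and a synthetic-genome generator with planted
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    jsonlite,
    yaml,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
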