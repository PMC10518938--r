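Package: darchip
Title: Transcription Factor Enrichment in Differentially Accessible Chromatin
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects differentially accessible regions (DARs) between
    chemically exposed and control ATAC-seq peak sets, scores transcription
    factors for differential binding in opened versus closed DARs using a
    library of ChIP-seq peak sets (two-tailed Fisher's exact test with
    Benjamini-Hochberg correction), joins enriched factors with
    factor-disease annotations into chemical-disease association scores,
    and evaluates predictions against a curated standard with per-condition
    and global AUROC/AUPR. Includes a deterministic simulator of toy
    genomes, replicate peak sets, and planted-enrichment peak libraries for
    validation without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    GenomicRanges,
    IRanges,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    pROC,
    rtracklayer,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
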