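Package: cnasig
Title: Copy-Number Alteration Signatures, Cross-Cohort Consistency and
    Metabolic Phenotype Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for pan-cancer and cross-species analysis of somatic DNA
    copy-number alteration (CNA) signatures from segmented copy-number
    profiles. Extracts orientation-stable PCA signatures from gene-level CNA
    matrices, summarises them as normalized signal-to-noise or loading
    signatures, scores cross-cohort agreement with the signed absolute
    minimum consistency score (SAMCS), calls conserved amplification and
    deletion regions, restricts them across species through one-to-one
    ortholog maps, runs permutation-based gene-set enrichment with isoenzyme
    collapsing, predicts continuous metabolic phenotypes by weighted gene
    voting, and computes per-sample genomic-instability scores (integrated
    CNA, breakpoint counts, senescence score). A seeded synthetic-cohort
    generator emulates the two-signature structure the analysis assumes so
    that every stage can be exercised and validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
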