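Package: ripuse
Title: Canonical and Noncanonical microRNA Target Identification from
    AGO2-RIP-seq and RNA-seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Identifies microRNA targets by integrating AGO2
    RNA-immunoprecipitation sequencing (RIP-seq) with RNA-seq after miRNA
    overexpression. Transcripts are ranked by AGO2 enrichment and by
    post-overexpression repression; an unbiased 6-8mer word-enrichment
    landscape (signed hypergeometric scores along rank cutoffs) recovers
    seed and non-seed interaction motifs; cumulative-distribution analysis
    validates repression by seed-site class (8mer, 7mer-m8, 7mer-1A, 6mer);
    direct targets are called as the overlap of the top AGO2-loaded and top
    down-regulated sets with an exact hypergeometric test. Includes a
    genome-wide seed-count census against a random-word null and a
    synthetic-data generator with planted, class-stratified effects for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
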