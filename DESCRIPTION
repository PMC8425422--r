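Package: hlaqc
Title: Study-Wide HLA Typing and Sample-Identity Quality Control for RNA-seq
Version: 0.1.0
Authors@R: person("Iris", "Chambers", email = "iris.chambers@example.org",
    role = c("aut", "cre"))
Description: Four-digit HLA genotyping directly from raw RNA-seq FASTQ files
    and study-wide comparison of the resulting allele profiles. Reads are
    aligned ungapped to a cDNA reference of HLA class I and II alleles
    (HLA-A, -B, -C, -DPB1, -DQB1, -DRB1), collapsed to four-digit allele
    groups, and up to two alleles per locus are called with an outlier-based
    confidence p-value and an RPKM expression estimate. Confidently typed
    alleles are cross-compared between all samples of a study into a squared
    identity matrix, samples are grouped by an identity threshold, and
    declared sample-to-subject labels can be evaluated by an F1-maximizing
    threshold sweep to flag mislabeled or swapped samples. A built-in
    population-frequency-driven cohort simulator (Hardy-Weinberg genotype
    sampling, wgsim-style substitution-only reads) makes the whole pipeline
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    parallel,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
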