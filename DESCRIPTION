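Package: plasmasig
Title: Somatic Mutational Signature Inference from Low-Coverage Plasma
    Whole-Genome Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Reference-free inference of somatic mutational signatures from
    low-coverage whole-genome sequencing of plasma cell-free DNA. Candidate
    somatic mismatches are reconstructed from the MD and CIGAR tags of
    aligned read pairs, reduced to a high-confidence set by read-pair
    overlap consensus, quality, germline and fragment-size filters, and
    classified into COSMIC SBS96/DBS78/ID83 channels. Signature exposures
    are refit by non-negative least squares, sequencing-artefact signatures
    removed and weights renormalised, and per-signature detection
    thresholds derived from a panel of healthy plasma controls via
    trimmed beta moment-matching. A built-in read simulator generates
    error-only reads, signature-faithful variant spike-ins, depth
    downsampling and tumour-purity admixtures for limit-of-detection
    studies.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    GenomicRanges,
    generics,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    fitdistrplus,
    pracma,
    Rsamtools,
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
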