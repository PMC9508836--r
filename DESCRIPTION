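Package: trioDNM
Title: De Novo Mutation Calling in Sequencing Trios via Pileup-Image
    Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Calls de novo mutations (DNMs) from child-father-mother
    sequencing trios. Candidate sites are obtained by allele-aware
    subtraction of parental variants from the child's VCF, the read
    pileup around each candidate is encoded as a quality-scaled one-hot
    RGB image (one colour channel per trio member), and each candidate
    is classified as de novo versus inherited either by a per-variant-type
    convolutional neural network (trained with the package's own
    CPU-based engine) or by a deterministic rule-based caller built on
    parental coverage and variant allele fraction thresholds. Includes a
    seeded trio read simulator that writes valid BAM/VCF/FASTA fixtures,
    hard-filter quality control, and benchmarking utilities
    (confusion-table metrics, per-variant-type breakdowns).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite,
    png,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Rsamtools,
    SummarizedExperiment,
    VariantAnnotation
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
SystemRequirements: bcftools (optional; used only as an independent
    cross-check in the test suite)
Config/testthat/edition: 3
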