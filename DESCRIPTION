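Package: donorwatch
Title: Empirical Prediction of Variant-Activated Cryptic Splice Donors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Toolkit for studying and predicting cryptic splice-donor
    activation. Enumerates annotated donors and nearby decoy donors (GT/GC
    dinucleotides) from a genome and transcript annotation, scores donor
    strength with a positional 9-mer frequency measure (Donor Frequency),
    classifies donor-region variants into annotated-modified and
    cryptic-modified categories, quantifies decoy depletion against
    dinucleotide-preserving (Euler) shuffles, builds a ranked mis-splicing
    event database from population-scale splice-junction files, applies the
    top-k and delta-score prediction rules with sensitivity/specificity
    evaluation, computes in-silico saturation-mutagenesis importance tracks,
    and simulates synthetic genomes, variants and junction samples with
    planted ground truth for end-to-end testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
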