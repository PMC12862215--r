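Package: orfcall
Title: Neural Labeling of Translation Initiation and Termination Sites with
    Integrated ORF Scoring
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Annotates full-length transcript sequences with translation
    initiation (TIS) and termination (TTS) sites.  A dilated-residual
    convolutional network labels every nucleotide with TIS/TTS/none
    probabilities; an integrated scoring system combines those probabilities
    with Kozak context, codon adaptation index and GC content to select a
    single best open reading frame per transcript or call it non-coding.
    Includes ORF-level evaluation metrics, a sequence-perturbation harness
    and a synthetic transcriptome generator for desk-scale experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    withr,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    optparse
Config/testthat/edition: 3
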