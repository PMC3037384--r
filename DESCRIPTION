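Package: posmotif
Title: Discriminative De Novo Motif Discovery with Positional Preferences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: De novo discovery of transcription factor binding motifs that are
    differentially abundant between a target (foreground) and a control
    (background) set of equal-length, TSS-anchored promoter sequences. The
    foreground class is a zero-or-one-occurrence-per-sequence (ZOOPS) mixture
    of a position weight matrix, an order-0 flanking model and a positional
    prior (mixture of a discretized skew normal and a uniform); the control
    class is a homogeneous Markov model. Parameters are learned by numerically
    maximizing the supervised posterior, with multi-start optimization and a
    heuristic that shifts, truncates or expands the motif window to adjust the
    motif length. Includes binding-site calling with control-derived empirical
    p-values, nucleotide-level precision-recall evaluation, PWM comparison by
    normalized Euclidean distance, IUPAC consensus scanning with enrichment
    statistics, and a benchmark generator that implants annotated sites into
    promoter pools.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    Rcpp,
    jsonlite,
    rtracklayer,
    stats,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
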