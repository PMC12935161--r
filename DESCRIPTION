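Package: isoscope
Title: Isoform-Level Differential Expression, Usage and Structure Analysis for Long-Read RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-group transcriptome comparison at isoform resolution from
    long-read RNA-seq counts: GENCODE-dialect GTF gene models with
    genome/transcript/protein coordinate transforms and intron-compressed
    display axes; ORF prediction for novel transcripts with a coding-potential
    scorer (ORF length and coverage, Fickett TESTCODE, hexamer log-odds,
    logistic combiner) plus uORF and nonsense-mediated-decay attributes;
    transcript-level differential expression with TMM normalization, grid-based
    negative-binomial dispersion estimation and a moderated quasi-likelihood
    F test; differential isoform usage with a Dirichlet-multinomial likelihood
    ratio test and two-stage (screening/confirmation) FDR control; projection
    of user-supplied positional and non-positional functional features; and
    deterministic gene-model figures (DE, usage and feature panels) built on a
    structured drawing model with SVG output. A seeded simulator generates
    annotation, genome, counts and feature fixtures with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    limma,
    readr,
    rlang,
    stats,
    tibble,
    tools
Suggests:
    edgeR,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
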