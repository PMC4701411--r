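Package: asmarbiter
Title: Quality Metrics and Error Taxonomy for De Novo Transcriptome Assemblies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Reference-dependent and reference-independent quality metrics for
    de novo transcriptome assemblies. Computes coverage breadth of reference
    cDNAs, normalized bit score (BS) versus sequenced fragments per base pair
    (SFB) quality-depth tables, the Type I (fragmentation) and Type II
    (annotation-ambiguity) assembly error taxonomy with genome-alignment
    chimera adjudication, conserved-ortholog recovery, N50 length statistics
    with short-sequence cutoff sweeps, read-titration (gene accumulation)
    curves with a closed-form hypergeometric expectation, and a composite
    superior-assembly checklist. A synthetic fixture generator builds toy
    reference transcriptomes, expression profiles and deliberately corrupted
    assemblies with ground-truth labels so every metric and classifier can be
    exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
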