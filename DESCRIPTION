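Package: xscnd
Title: Cross-Species Array-CGH Detection of Gene Copy-Number Divergence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects gene copy-number divergence between a reference species
    and heterologous relatives from cross-species comparative genomic
    hybridization (array-CGH) on short-oligonucleotide arrays. Probe-target
    sequence mismatches attenuate heterologous hybridization signal; the
    package models mismatch counts over 25-mer probes as a binomial
    distribution, estimates per-mismatch incremental correction factors from
    a curated reference dataset, and combines them into a species-specific
    global scaling factor applied to heterologous intensities. Scaled signals
    are tested probe-wise with a moderated linear model and genes are
    classified as copy-number expanded or reduced by log2-ratio and FDR
    thresholds. Also provides validation metrics against truth sets,
    Fisher's-exact functional over-representation analysis, a sliding-window
    scan for large copy-number divergent segments, two previously published
    baseline callers for comparison, and a fully seeded synthetic-data
    generator with planted copy-number states.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml,
    IRanges
Suggests:
    testthat (>= 3.0.0),
    limma,
    Biostrings,
    rtracklayer,
    optparse,
    knitr
Config/testthat/edition: 3
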