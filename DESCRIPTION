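Package: crispriscreen
Title: Analysis and Simulation of Pooled Genome-Wide CRISPRi Screens in Bacteria
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for pooled CRISPR-dCas9 (CRISPRi) screens in bacteria:
    protospacer enumeration and PAM-proximal off-target matching, guide
    quality control (bad-seed, off-target, multi-target and read-count
    filters), control-guide-normalized log2 fold-change estimation with
    negative-binomial significance tests, gene-level essentiality and
    phage-resistance scoring with operon-aware polar-effect classification,
    a per-gene nested linear model separating capsid-production defects
    from growth effects, and a seeded synthetic-screen simulator for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
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
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    DESeq2,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
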