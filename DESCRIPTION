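Package: mtcn
Title: Mitochondrial DNA Copy Number from qPCR and Low-Pass Whole-Genome
    Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimates relative mitochondrial DNA copy number (mtDNAcn) by
    two complementary routes: a dual-gene paired delta-Ct qPCR method (with a
    commercial-style geometric-mean variant) applied to replicate Ct plate
    tables, and a coverage-ratio method applied to aligned low-pass
    whole-genome sequencing reads. Includes replicate and no-template-control
    quality control, cross-method Pearson concordance analysis, a simplified
    k-mer mitochondrial haplogroup and region caller, and a synthetic-data
    generator that produces matched ground-truth cohorts, Ct plates, and toy
    alignments so the whole pipeline runs end-to-end offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomicAlignments,
    Rsamtools,
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
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
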