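Package: sodkit
Title: Promoter Motif Scanning, Gene Architecture and Immune-Priming
    Expression Analysis for Cu,Zn Superoxide Dismutase Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native toolkit for characterising Cu,Zn superoxide
    dismutase (SOD) genes and their response to immune priming in insects.
    Scans promoter regions for degenerate IUPAC consensus cis-elements
    (antioxidant and xenobiotic responsive elements) on both strands,
    summarises gene architecture (ORF, UTRs, exon/intron layout,
    polyadenylation signals, deduced protein mass), quantifies relative
    gene expression with the 2^-ddCt method including standard-curve
    primer-efficiency QC, computes SOD enzyme units from nitro blue
    tetrazolium (NBT) inhibition curves with Lowry protein normalisation,
    and compares treatment groups with one-way ANOVA followed by a
    Student-Newman-Keuls post hoc built on a numerically integrated
    studentized-range distribution, plus pairwise Wilcoxon tests for
    survival proportions. Ships a fully deterministic synthetic-data
    generator that emits every input format together with a ground-truth
    ledger, so the whole pipeline can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
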