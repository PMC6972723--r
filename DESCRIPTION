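Package: crl4score
Title: Severity Scoring and Burden Analysis of Regulatory Variants in the
    CRL4-Cereblon Gene Panel
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Aggregates normalized in-silico functional predictions for
    regulatory variants into a per-variant severity score (1-20) and heatmap,
    computes per-individual variant burden (counts and score sums) and compares
    it between phenotype subgroups and a reference panel, and provides the
    sequence-level analyses that support such a screen: CpG-island detection
    and variant impact, synonymous codon-usage shifts, position-weight-matrix
    motif disruption, bisulfite methylation simulation and calling, and a
    pairwise Nei-Gojobori dN/dS screen. A seeded synthetic-cohort generator
    emulating a thalidomide-embryopathy gene-panel study (five genes, a
    35-individual cohort with limb-defect subgroups, a 99-individual reference
    panel) makes every stage testable without confidential patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    rlang,
    ggplot2,
    generics,
    stats,
    tools,
    utils,
    jsonlite,
    Biostrings,
    GenomicRanges,
    SummarizedExperiment,
    VariantAnnotation
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
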