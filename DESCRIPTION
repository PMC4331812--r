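Package: seedfill
Title: Time-Course Multi-Omics Analysis of Seed Filling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical pipeline for joint transcriptomic and metabolomic
    profiling of developing seeds sampled across a developmental time course.
    Provides detection filtering and ln/median-centring normalisation,
    per-feature time-course F-tests with Storey q-value FDR control,
    K-medoids (PAM) clustering of standardized temporal profiles with
    Krzanowski-Lai selection of the cluster number, category-level statistics
    (multiresponse permutation procedure, Fisher exact over-representation,
    chemical-class by cluster contingency tests), volcano comparisons and
    metabolite-transcript correlation co-analysis, IUPAC promoter motif
    scanning with per-cluster enrichment, and a synthetic-data generator
    with known ground truth that emulates the structure of a seed-fill
    profiling study so every stage can be exercised end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    cluster,
    vegan,
    mclust
Config/testthat/edition: 3
RoxygenNote: 7.3.3
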