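Package: pgsihet
Title: Genomic Prediction of Hybrid Heterosis from Windowed Parental
    Genetic Similarity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts high-parent and mid-parent heterosis of F1 hybrids
    from paired parental genome sequences. Computes a windowed parental
    genetic similarity index (PGSI) from biallelic SNP genotypes of inbred
    parents, integrates multi-environment phenotypes into best linear
    unbiased estimates (BLUEs), fits GBLUP (additive and
    additive-plus-dominance kinships, REML variance components) and LASSO
    models with ordinary-least-squares re-estimation of selected windows,
    extracts and names heterosis QTLs (h-QTLs) from window coefficients,
    and estimates predictability by replicated k-fold cross-validation.
    Includes a seeded simulator of inbred cross populations with planted
    window-level heterosis effects so the whole pipeline is testable
    without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    vcfR,
    glmnet,
    jsonlite,
    yaml,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    lme4,
    optparse,
    withr
Config/testthat/edition: 3
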