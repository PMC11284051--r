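Package: mrcascade
Title: Integrative Drug-Target Discovery with Single-Cell DEGs, Mendelian
    Randomization, Colocalization and PheWAS
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end target-prioritization cascade for case-control
    disease genetics: single-cell RNA-seq quality control, normalization,
    clustering and per-cell-type differential expression; selection and LD
    clumping of eQTL/pQTL genetic instruments; two-sample Mendelian
    randomization (Wald ratio, inverse-variance weighted, MR-Egger, weighted
    median, Cochran's Q); approximate-Bayes-factor colocalization under the
    five-hypothesis model; and a phenome-wide pleiotropy screen. Ships a
    seeded synthetic-data generator that emulates LD-correlated genotype
    panels, QTL and case-control GWAS summary statistics, negative-binomial
    single-cell counts with planted cell types and differentially expressed
    genes, and multi-trait association tables, so the whole cascade can be
    exercised against known ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    jsonlite,
    yaml,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
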