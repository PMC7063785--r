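Package: treespp
Title: Filter-Chain Decision Trees for Variant Pathogenicity Triage
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies non-synonymous variants of uncertain significance as
    neutral or pathogenic with a linear filter-chain decision tree: a
    SIFT/PolyPhen/PROVEAN consensus at the root, followed by ExAC allele
    frequency, a nine-predictor damage-call count, and a 1000 Genomes
    common-variant frequency. Each level either exits a variant as neutral or
    passes it deeper; survivors of all levels are called pathogenic. Includes
    readers for annotated variant tables (TSV or VCF in the dbNSFP annotation
    style) with ClinVar clinical-significance harmonization, binary feature
    discretization, greedy level-wise tree induction with an exhaustive-search
    oracle, topology enumeration under root restrictions, a confusion-based
    evaluation suite (class-conditional rates, stratified 10-fold
    cross-validation, Monte Carlo subsampling, phi correlations, pairwise
    feature-distribution tables, per-level reports), and a class-conditional
    synthetic variant generator with closed-form expected confusion rates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    vcfR
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
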