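Package: zincmap
Title: Quantitative Genetics of High-Throughput Zinc-Response Phenotypes in C. elegans
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for mapping natural variation in Caenorhabditis
    elegans zinc responses from large-particle-sorter phenotype data.
    Processes per-animal sorter records into per-well traits through
    assay regression, outlier pruning, control regression and unit
    normalization; estimates broad-sense heritability with a strain
    random-effects model; performs correlation-LOD linkage mapping on
    recombinant inbred panels with permutation genome-wide error rates,
    iterative forward search with marker cofactors, 1.5-LOD-drop
    confidence intervals and a two-dimensional epistasis scan; screens
    expression traits for mediation of QTL effects by the
    product-of-coefficients method with bootstrap inference; runs
    mixed-model genome-wide association on wild-isolate panels with an
    additive kinship matrix and an eigenvalue-based effective number of
    tests; and computes sliding-window Tajima's D and neighbor-joining
    strain trees over genomic intervals. Includes seeded synthetic-data
    generators for every input class so each stage can be validated
    against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    ape,
    phangorn
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    vcfR
Config/testthat/edition: 3
RoxygenNote: 7.3.3
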