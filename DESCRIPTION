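Package: phenodiv
Title: Phenotypic Divergence Analysis for Replicated Genotype Trials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Complete phenotypic-divergence analysis for balanced completely
    randomized genotype trials, as used in plant genetic-resource studies:
    per-trait one-way analysis of variance, Scott-Knott clustering of
    genotype means, variance components with broad-sense heritability and
    the CVg/CVe ratio, generalized Mahalanobis distances between genotypes,
    Singh's decomposition of total divergence into per-trait contributions,
    and a UPGMA dendrogram cut by Mojena's criterion. Includes Maguire's
    emergence speed index and the Edmond-Drapala mean emergence time for
    seed-vigor assays, and a synthetic-cohort generator with known variance
    components for validating every stage of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    ape
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
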