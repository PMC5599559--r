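Package: epiharmony
Title: Niche Harmony Search for High-Order SNP Interaction Detection
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Two-stage detection of high-order (k-way) SNP combinations
    associated with case/control disease status. A niche harmony-search
    screening stage explores the combination space under three complementary
    objectives (Bayesian K2 score, Gini impurity, joint genotype entropy),
    with stagnation-triggered niche identification and taboo regions to
    avoid repeated local search; a modified G-test with a sparse-genotype
    degree-of-freedom correction and Hardy-Weinberg expected counts verifies
    the resulting candidate set under Bonferroni control. Includes a
    penetrance-table epistasis simulator (marginal-effect and
    no-marginal-effect disease models) and replicate-level evaluation
    metrics (Power, MEs, TPR, SPC, ACC, FDR), so the whole system is
    testable without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
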