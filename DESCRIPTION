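Package: phenomkl
Title: Phenotypic Multi-Task Multi-Kernel Learning for Ion-Channel Variant Effects
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Predicts the net functional effect (gain- versus loss-of-function)
    of ion-channel missense variants by combining clinical phenotypes, a channel
    taxonomy and sequence/structure features in a kernel support-vector machine.
    Provides ontology parsing and term-set propagation, information-content and
    semantic-similarity kernels (Jaccard, Resnik, Lin) with spectrum clip/flip/
    shift corrections for indefinite similarity matrices, taxonomy-based
    multi-task kernels, uniform/global/hierarchical-decomposition multiple
    kernel learning, nested cross-validated evaluation, phenotype sparsity and
    noise perturbation experiments, histogram-of-projections confidence
    analysis, and a synthetic cohort generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    kernlab,
    methods,
    stats,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
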