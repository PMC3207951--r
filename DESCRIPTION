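Package: dandelion
Title: Interspecies Disease-Network Learning with Conditional Gaussian
    Bayesian Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Learns disease gene networks within one species by
    cross-validated Bayesian network structure search (simulated
    annealing maximising the Bayesian Information Criterion over
    conditional linear Gaussian models with a discrete disease-state
    class node), collapses the learned transcript-level structures to
    gene-level network maps, translates the maps to other species
    through ortholog groups, re-optimises them on the target species'
    data, and integrates the resulting fold-networks into
    confidence-scored consensus networks from which the Markov-blanket
    disease domain of the class node is extracted.  Both a naive
    variant (transcript profiles averaged per gene before learning)
    and an exhaustive variant (model-driven transcript selection during
    translation) are provided, together with a ground-truth synthetic
    multi-species data generator, evaluation metrics (per-node sum of
    squared error, sensitivity/specificity of disease-state
    prediction, translatability and robustness profiles) and a small
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    limma,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
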