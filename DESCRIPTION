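Package: pglscan
Title: Phylogenetic Generalized Least Squares Scans for Multi-Omics
    Lifespan Association in Yeast Natural Isolates
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Links strain-level multi-omics phenotype matrices
    (transcripts, peptides/proteins, metabolites, morphology) to
    replicative lifespan across yeast natural isolates by phylogenetic
    generalized least squares. Fits four trait-evolution covariance
    models (Null, Brownian motion, Pagel's lambda, Ornstein-Uhlenbeck
    with fixed root), estimates model parameters by maximum likelihood,
    selects the best-fitting model, tests regression slopes, and checks
    leave-one-out robustness. Includes the paper-style preprocessing
    rules (per-feature standardization, metabolite missing-value
    filtering, k-nearest-neighbour imputation, peptide-to-gene
    aggregation, PCA top-contributor export), a relative mitochondrial
    DNA coverage statistic from per-base depth tracks, a synthetic-data
    generator for trees, traits, feature matrices and depth profiles,
    and an end-to-end scan pipeline with a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
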