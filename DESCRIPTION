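Package: phenoscreen
Title: Zebrafish Larva Behavioural Phenotyping and Phosphoproteomic Hub
    Analysis for Antidepressant/Anxiolytic Drug Screens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A two-armed analysis pipeline for phenotypic drug screening.
    The behavioural arm extracts six stereotypic movement features
    (distance, relative turning, pausing, spurt velocity, and thigmotaxis
    by time and by distance) from zebrafish larva tracking time series
    recorded around an acoustic/light startle battery, normalizes them to
    same-plate controls, and classifies treatments as
    antidepressant/anxiolytic ("AA") versus "other" with penalized
    logistic regression, polynomial-kernel support vector machines and
    random forests scored through a paired-control ROC scheme.  The
    phosphoproteomics arm merges and filters phosphopeptide intensity
    tables, calls genotype-differential entries with a two-class
    rank-product permutation test, and identifies signalling hubs in a
    weighted physical-interaction network against a random
    background-network null with hypergeometric and empirical
    significance.  A synthetic-data module generates every input with
    planted ground truth so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    glmnet,
    e1071,
    randomForest,
    multcomp,
    yaml,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE, load = "source")
RoxygenNote: 7.3.3
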