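Package: microgcn
Title: Graph Convolutional Disease-Status Classification for Gut Microbiome Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Semi-supervised classification of host disease status from
    species-level relative-abundance profiles. Combines a fully connected
    feature learner regularized by multi-kernel maximum mean discrepancy
    (MK-MMD) to reduce cohort-level distribution shift, a k-nearest-neighbour
    inter-host similarity graph built in the learned latent space, and a
    graph convolutional network trained on labelled nodes only. Includes
    single-species AUC biomarker ranking, abundance-perturbation contribution
    scores, stratified cross-validation and leave-one-study-out evaluation,
    and a multi-cohort compositional data simulator with planted
    disease-associated taxa and study-level batch effects.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
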