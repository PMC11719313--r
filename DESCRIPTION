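Package: malnutMap
Title: Stacked Ensemble Distribution Modelling of Neighborhood BMI Classes
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Maps neighborhood-level (1 ha) probabilities of body-mass-index
    classes (underweight, normal, overweight-obese) of older adults from
    gridded environmental covariates and geo-located survey points, using
    the species-distribution-modelling toolkit: target-group background
    sampling, area-of-applicability masking via a dissimilarity index,
    pairwise variable decorrelation, five tuned base learners (two
    MaxEnt-style penalized logistic models, random forest, gradient
    boosting, neural network) combined by a random-forest meta-learner
    (stacked generalization), five-fold cross-validated AUC and TSS,
    jack-knife and permutation variable importance with response curves,
    and probability-threshold hotspot delineation summarized over
    administrative units. A seeded synthetic-landscape generator provides
    ground-truth test beds.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    glmnet,
    randomForest,
    xgboost,
    nnet,
    pracma,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'utils.R'
    'sampling.R'
    'synthetic-landscape.R'
    'benchmark.R'
    'covariates.R'
    'evaluation.R'
    'learners.R'
    'ensemble.R'
    'hotspots.R'
    'interpretation.R'
    'io.R'
    'malnutMap-package.R'
    'pipeline.R'
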