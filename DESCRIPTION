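Package: nutrimorph
Title: Nutritional Status and 3D Facial Shape Morphometrics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline linking nutritional status (food-frequency
    questionnaire nutrient estimation, eating-behavior scales, body
    composition indices) to three-dimensional facial shape. Implements
    generalized Procrustes analysis with centroid size, shape principal
    components with a Kaiser/90 percent retention rule, sexual shape
    dimorphism scores by projection onto a male-female axis with
    allometric decomposition, and the inferential chain of stepwise
    selection, MANCOVA (Wilks lambda), canonical correlation analysis,
    k-means dietary-pattern clustering with elbow selection, ANOVA with
    Tukey-Kramer post-hoc tests and Benjamini-Hochberg correction.
    Includes a synthetic-cohort generator with planted dietary patterns,
    allometry and shape dimorphism so the whole chain is testable without
    access to restricted cohort data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    pracma,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vegan,
    mclust,
    car,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
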