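Package: gazegeom
Title: Conceptual Geometry from Spontaneous Eye Movements in Verbal Fluency
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for linking spontaneous gaze displacement during verbal
    fluency tasks to the representational geometry of conceptual spaces such
    as the one-dimensional mental number line, the two-dimensional color
    wheel, and lexical-frequency axes. Provides a seeded synthetic session
    generator with a known embedded geometry, gaze preprocessing (pre-onset
    window medians, trial-to-trial displacement series), conceptual distance
    models (signed numeric change, subject-specific multidimensional scaling
    of similarity judgments, word-embedding cosine distance, semantic cluster
    jumps, first-principal-component and word-frequency distances),
    subject-level rank correlations with Fisher-z group inference and JZS
    Bayes factors, geometry recovery via classical multidimensional scaling,
    representational similarity analysis and Procrustes alignment, and
    balanced leave-one-trial-out linear discriminant decoding with
    permutation significance.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    vegan,
    yaml,
    jsonlite,
    graphics
Suggests:
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
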