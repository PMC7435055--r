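Package: restifit
Title: Dynamic Modeling and Machine Learning for Gastric Organoid Restitution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts single-cell time-course measurements of gastric organoid
    wound repair (actin fluorescence, damaged area, dead-cell distance) into
    per-organoid kinetic feature vectors using piecewise hybrid ordinary
    differential equation models fitted by evolutionary least squares, then
    analyses the resulting feature tables with treatment-versus-control
    percent-change (chord edge) summaries, principal component analysis and
    random-forest variable importance. Includes a seeded synthetic-cohort
    generator with retained ground truth so the whole pipeline can be
    exercised and validated by parameter-recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    deSolve,
    randomForest,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
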