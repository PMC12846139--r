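Package: neckforce
Title: Personalized Cervical Muscle-Force Estimation from Head Kinematics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A self-contained pipeline for personalized cervical
    biomechanics: samples anthropometrically diverse head-neck models from
    published population statistics, resolves muscle redundancy along
    synthesized neck motions with inverse dynamics and an enhanced static
    optimization (depth-weighted activation, metabolic and force-rate
    penalties, bilateral symmetry), trains one small feedforward network
    per muscle mapping head-marker kinematics plus anthropometry to muscle
    force, and assesses functional deficits by comparing subject motion
    envelopes against an idealized envelope library with a volumetric
    intersection-over-union score, Hill-type activation inversion and
    surface-EMG envelope processing for pattern-level validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    pracma,
    signal,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
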