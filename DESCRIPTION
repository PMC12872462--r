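Package: condensateph
Title: Electrochemical Profiling of Biomolecular Condensates and
    pH-Dependent Phase Behaviour
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Sequence-based electrochemistry of biomolecular condensates:
    Henderson-Hasselbalch site models for protein and RNA net charge and
    isoelectric points, charge profiles of multi-component mixtures and
    condensate proteomes, randomized proteome generation, analysis of
    combinatorial microdroplet phase-diagram datasets (phase fraction maps,
    dilute-phase contour slopes, energy dominance), ratiometric SNARF-type
    pH imaging readouts, and a minimal three-charge-state polymer model
    whose spinodal is located from the Hessian determinant of the free
    energy. Includes seeded synthetic-data generators for droplet
    experiments, two-channel pH images and composition-controlled
    proteomes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    grDevices,
    utils,
    jsonlite,
    yaml,
    tiff,
    Biostrings
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
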