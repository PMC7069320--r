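Package: camoquant
Title: Quantifying Camouflage and Background Matching from Calibrated Digital Photographs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Image-based quantification of animal background matching along an
    environmental gradient. Calibrates digital photographs against an in-frame
    gray standard (inverse-gamma linearization and per-channel equalization),
    extracts region colors by seeded random-point sampling inside polygon ROIs,
    computes RGB chromaticity, saturation, hue, and achromatic and chromatic
    animal-versus-background contrast indices, classifies dorsal pattern types,
    scores sectioned vegetation cover, and runs the population-level inferential
    layer (scaled mass index, AICc model ranking of linear mixed models, rank
    tests, and Tukey-adjusted pairwise contrasts). Includes a synthetic scene
    and population generator with known ground truth so every stage is testable
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    lme4,
    multcomp,
    png,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
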