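Package: streambounce
Title: Reverse Correlation and Motion-Energy Modeling of the Stream-Bounce Display
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying perceptual disambiguation of the ambiguous
    stream-bounce motion display. Generates noisy space-time luminance movies
    of two bars moving along crossing trajectories, extracts directional
    motion energy with a spatiotemporal quadrature-filter (Adelson-Bergen)
    model, estimates luminance and contrast classification images by reverse
    correlation, and fits a probit-linked linear integration model that
    combines visual motion energy, an auditory click, and the previous
    perceptual report. Includes a synthetic observer for end-to-end
    simulation, cross-validated calibration of the integration model,
    permutation tests for kernel similarity, and readers/writers for the
    MAT v5 layouts used by deposited stimulus and trial datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
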