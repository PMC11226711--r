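Package: uctborn
Title: Distorted Born Iterative Reconstruction for Circular-Array Ultrasound Tomography
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates circular-array ultrasound tomography measurements with a
    method-of-moments Helmholtz forward solver and reconstructs sound-speed
    contrast maps by the distorted Born iterative (DBI) method with Tikhonov
    regularization. Implements the resolution-turning (coarse-to-fine grid),
    frequency-hopping (low-to-high frequency) and combined iteration schedules,
    synthetic disk phantoms, the relative residual error metric, and a small
    command-line interface for simulate/reconstruct/compare experiments.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
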