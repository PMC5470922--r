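Package: devibe
Title: Depth-Extended ViBe Background Subtraction for RGB-D Video
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Sample-based background subtraction for co-registered color and
    depth (RGB-D) video, aimed at foreground extraction in animal- and
    human-behavior recordings from consumer depth cameras. Implements the
    classical per-pixel sample model with stochastic random-subsampling
    updates (ViBe), a depth-only baseline, and a depth-extended variant
    (DEVB) that fuses color with an uncertainty-weighted proximity channel
    and reclassifies ghost pixels using a per-pixel depth model, removing
    the ghosts and black shadows that color-only models leave behind.
    Includes the percentage-of-wrong-classifications (PWC) evaluation
    metric, PNG sequence readers and writers (16-bit depth in millimeters),
    a seeded synthetic RGB-D scene generator covering ghost, black-shadow,
    depth-hole and illumination-flicker scenarios, and a command-line
    interface.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    png,
    yaml,
    optparse,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
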