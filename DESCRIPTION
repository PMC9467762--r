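Package: otoseg
Title: Denoising, Segmentation and Evaluation for Otoscope-Style
    Tympanic-Membrane Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Toolkit for impulse-noise removal and segmentation of 8-bit
    grayscale otoscope-style images of the tympanic membrane, aimed at
    computer-aided otitis media image analysis.  Implements a histogram
    equalization based adaptive center-weighted median (HE/ACWM) switching
    filter with rank-ordered absolute difference noise detection, plus
    weighted-median and adaptive-median baselines; three segmentation
    algorithms (Chan-Vese level-set active contour with an optional shape
    prior, the GrowCut cellular automaton, and Haar wavelet multiscale
    histogram thresholding); the evaluation metrics PSNR, Rand index,
    global consistency error and variation of information; a seeded
    synthetic phantom generator standing in for clinical data; and a
    benchmark harness that produces the corresponding comparison tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    png,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
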