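Package: flico
Title: Colocalization, Contractile-Ring Morphometry and Mixed-Model
    Analysis for Confocal Fluorescence Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative analysis of two-channel confocal
    fluorescence microscopy of Drosophila development: control-calibrated
    thresholded Manders (M1/M2) and thresholded Pearson (tPCC)
    colocalization with pixel-count-weighted hierarchical aggregation and
    Fisher-z population inference; reconstruction of an ImageJ-style
    region-of-interest macro (Otsu/MaxEntropy/Huang auto-thresholds,
    rolling-ball background subtraction, disc mean filter, bright-spot
    exclusion); time-lapse actomyosin-ring segmentation with
    Fourier-descriptor contour smoothing and circularity trend models;
    cortical and depth intensity profiling; and gamma generalized linear
    mixed models with prespecified Wald contrasts including an epistasis
    contrast. Includes synthetic confocal image and measurement
    generators with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    tiff,
    png,
    glmmTMB,
    mgcv,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    lme4,
    multcomp,
    withr
Config/testthat/edition: 3
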