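Package: csjnd
Title: Color-Sensitivity-Based Just-Noticeable-Difference Maps for Images
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimates per-pixel visibility thresholds (just noticeable
    difference, JND) for 8-bit color images in the pixel domain. The model
    combines luminance adaptation with a three-factor visual masking
    estimate (contrast masking, pattern masking via gradient-orientation
    histogram sparsity, and edge protection), modulates masking by visual
    saliency (SDSP-style frequency, location and color priors), fuses the
    terms with the nonlinear additivity model for masking (NAMM), and
    rescales the Y/Cb/Cr sub-thresholds by color-sensitivity weights.
    Includes a JND-guided noise injector calibrated to a target PSNR for
    validating threshold maps, PSNR/SSIM metrics, a deterministic synthetic
    fixture generator, and float-TIFF map input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    grDevices,
    jsonlite,
    png,
    stats,
    tiff,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
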