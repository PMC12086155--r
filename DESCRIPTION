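Package: canopyRGB
Title: Smartphone RGB Color Indices for Lettuce Canopy Phenotyping
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Image-analysis pipeline for estimating lettuce nutritional status
    and fresh weight from smartphone canopy photographs. Reduces segmented
    canopy images to per-color pixel histograms (with optional GIF-style
    median-cut palette quantization), filters green pixels (G strictly greater
    than R and B), and computes two color indices: the normalized intensity
    I = (R + G + B)/3 on the unit scale and the dark green proportion (G-band
    0-85, or a four-code palette set). Includes Bland-Altman agreement analysis
    between two camera devices with device averaging, one-way ANOVA and Welch
    pairwise contrasts for fertilizer treatment effects, an ANCOVA linking
    fresh weight to leaf color within treatments, and a seed-deterministic
    synthetic-data generator (canopy images with ground-truth masks, paired
    device measurements, growth records) so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    png,
    jpeg
Suggests:
    testthat (>= 3.0.0),
    withr,
    tiff,
    lme4,
    jsonlite
Config/testthat/edition: 3
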