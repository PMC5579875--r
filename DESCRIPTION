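Package: hsgrade
Title: Hyperspectral Imaging Chemometrics for Three-Grade Sausage Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Grades intact and sliced Cantonese-style sausage into three
    quality grades from near-infrared hyperspectral image cubes (874-1734 nm,
    256 bands). Covers the full workflow: ENVI cube input/output, white/dark
    reflectance calibration, region-of-interest segmentation, Daubechies-6
    wavelet denoising of pixel spectra, Kennard-Stone sample-set partitioning,
    principal component score exploration, Savitzky-Golay second-derivative
    peak selection, random-forest recursive wavelength elimination with
    out-of-bag error curves, and grid-tuned radial-basis support vector
    machine and random-forest graders with confusion-matrix evaluation. A
    synthetic cube generator with linear lean/fat/binder endmember mixing
    provides seeded ground-truth data for validation and examples.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    ranger,
    signal,
    EBImage,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
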