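Package: lesionfd
Title: Intensity-Difference Box-Counting Fractal Analysis of Pigmented
    Skin Lesion Images
Version: 0.1.0
Author: Package Author
Maintainer: Package Author <author@example.com>
Description: End-to-end fractal analysis of pigmented skin lesion
    photographs acquired under paired polarized and non-polarized
    illumination. Provides divide-blend contrast segmentation of the
    lesion from the surrounding skin, Euclidean morphometry (area and
    perimeter) of the traced mask, the intensity-difference
    (differential) box-counting fractal dimension with power-series and
    block-series scale schemes for lesion shape and surface texture,
    non-overlapping region-of-interest tiling inside the lesion, and the
    normality-gated parametric/nonparametric group-comparison statistics
    used to contrast melanoma, dysplastic nevus and benign nevus
    cohorts. Includes a synthetic-data generator producing exact fractal
    fixtures (Sierpinski carpet, uniform fields, fractional Brownian
    textures) and simulated paired-illumination lesion photographs with
    controllable border irregularity and texture roughness.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    EBImage,
    png,
    tiff,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
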