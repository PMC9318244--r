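# lesionfd

Fractal-geometry quantification of pigmented skin lesion photographs.

Dermatologists grade melanocytic lesions partly by how irregular their
border and pigment texture look — the "B" and "C" of the ABCD rule. This
package turns those visual impressions into numbers for images acquired
under paired polarized (PL) and non-polarized (NPL) illumination, and
provides the group statistics to compare melanoma (MM), dysplastic nevus
(DN) and benign nevus (BN) cohorts. It is aimed at quantitative
dermatology and image-analysis researchers who have such photograph
pairs (plus a mm-per-pixel calibration) and want a deterministic,
scriptable measurement pipeline.

## The measurements

**Segmentation by divide blend.** The photograph is converted to 8-bit
grayscale, tone-inverted, and the grayscale layer is divide-blended over
its inversion:

    E(x, y) = I(x, y) * 256 / (M(x, y) + 1)

truncated and clamped to [0, 255]. With M = 255 − I this is
E = 256·I/(256 − I), strictly increasing in I, so bright skin saturates
to white while the dark lesion keeps its detail; thresholding just below
white, keeping the largest connected component and filling holes yields
the lesion mask.

**Morphometry.** Area = foreground pixel count × (mm/px)²; perimeter =
length of the marching-squares boundary polygon × (mm/px).

**Intensity-difference box-counting FD.** The image is covered by an
ε × ε box grid; each box contributes the spread of its intensities plus
one,

    I(ε) = Σ_boxes [ max − min + 1 ],

and the fractal dimension is the least-squares slope of ln I(ε) versus
ln(1/ε). Two scale schemes are used: a *power series* ε = 4, 16, 64, …
(base 2, exponent step 2, capped at a quarter of the image) for the
lesion **shape FD** computed on the divide-blended image, and a *block
series* — all divisors of the ROI size between 2 and a quarter of it,
so every grid tiles exactly — for the **surface FD** of square regions
of interest (450 × 450 px by default) tiled greedily, without overlap,
inside the mask.

**Statistics.** Shapiro–Wilk-gated branches: paired t / Wilcoxon
signed-rank for PL vs NPL, one-way ANOVA with Fisher LSD post hocs or
Kruskal–Wallis with Dunn mean-rank comparisons (Bonferroni, capped at 1)
across groups, Spearman correlations of shape FD with area and
perimeter, and unpaired t / Mann–Whitney U for melanoma in-situ vs
invasive subgroups.

Because clinical photographs are rarely shareable, the package ships a
synthetic generator: exact fractal fixtures (Sierpinski carpet, uniform
fields, fractional Brownian textures with known Hurst exponent) and
simulated PL/NPL lesion pairs with controllable border irregularity and
texture roughness, fully seeded and bit-reproducible.

## Worked example

```r
library(lesionfd)

## estimator anchor: depth-6 Sierpinski carpet, grid-aligned scales
carpet <- renderFixture("sierpinski_carpet", depth = 6)
estimateFD(carpet, scaleSeries(c(3, 9, 27, 81, 243)))
#> FDResult: FD = 1.8934 (R^2 = 1.0000, 5 scales, explicit series)

## one simulated lesion through the whole chain
p   <- lesionParams(irregularityAmplitude = 0.25, seed = 11)
img <- renderLesion(p)
seg <- segmentLesion(img)
seg$mask
#> LesionMask 256x256, 20179 foreground px (30.8%)
measureLesion(seg$mask, mmPerPixel = 0.05)
#> MorphometryResult: area 50.45 mm^2, perimeter 29.23 mm (marching squares, 3x3-smoothed)
estimateFD(seg$blended, powerSeriesScales(dim(img)))
#> FDResult: FD = 1.1201 (R^2 = 1.0000, 3 scales, power series)
rois <- extractROIs(seg$gray, seg$mask, roiSize = 64)
rois
#> ROISet: 2 non-overlapping 64x64 ROIs
fd(estimateFD(patches(rois)[[1]], blockSeriesScales(64)))
#> [1] 1.127008
```

The carpet's estimate sits on the theoretical log 8 / log 3 ≈ 1.8928.
For the simulated lesion, the mask covers the rendered lesion disc
(radius 80 px at 0.05 mm/px ≈ 50 mm² — matching the measured 50.45 mm²),
the shape FD reflects the moderately irregular border, and each
450-style ROI (64 px here for speed) gets its own surface-texture FD.
Batch analysis runs through `simulateCohort()` / `runPipeline()` (or the
`inst/scripts/lesionfd.R` command-line wrapper), which write per-lesion
measurement CSVs and the full set of statistical report tables.

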