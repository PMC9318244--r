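---
title: "Methods: fractal quantification of lesion shape and surface texture"
author: "lesionfd"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fractal quantification of lesion shape and surface texture}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lesionfd)
```

## Overview

`lesionfd` measures two complementary aspects of a pigmented lesion
photograph: how complex its **border** is (shape FD) and how rough its
**pigment texture** is (surface FD), both with the intensity-difference
(differential) box-counting estimator, plus Euclidean morphometry and
the group statistics needed to compare diagnostic cohorts under paired
polarized (PL) and non-polarized (NPL) illumination. This vignette
documents the model choices, the tunable parameters, the synthetic data
the package is validated on, and the numerical conventions.

## Segmentation: the divide-blend model

The segmentation assumes one lesion per photograph, darker than the
surrounding skin, on a reasonably even background. The grayscale image
(Rec. 709 luma, 0.2126/0.7152/0.0722, rounded half-up; the weights are a
configuration choice recorded in the output metadata) is divide-blended
over its own tone inversion:

$$E = \left\lfloor \frac{256\,I}{(255 - I) + 1} \right\rfloor
    \;\text{clamped to } [0, 255].$$

Because $E(I) = 256I/(256-I)$ is strictly increasing and saturates for
$I \gtrsim 126$, skin-bright pixels map to pure white while lesion-dark
pixels keep their contrast. Integer handling is truncation toward zero
followed by clamping — the behaviour of 8-bit divide blending in raster
editors.

Mask extraction then thresholds strictly below `whiteThreshold`
(default 250), keeps the largest connected component, and fills fully
enclosed holes. This is a deterministic replacement for manual
background-artifact erasing; cleanup never alters the lesion body, only
non-largest components. If a discarded component exceeds
`minComponentFraction` (default 0.01) of the largest, a warning is
raised because it may be genuine structure. An all-white image is a "no
lesion found" error; the operation is idempotent on two-level renderings
of its own output.

## Morphometry

Area is the foreground pixel count times the squared calibration
(`mmPerPixel`, millimetres per pixel; without it results fall back to
pixel units with a warning). Perimeter is the length of the
marching-squares 0.5-level contour of the mask indicator, computed after
one 3×3 box-smoothing pass. The smoothing emulates a hand-drawn contour:
on binary staircase boundaries the raw marching-squares polygon
overestimates a discretized disc's circumference by about 5%, while the
smoothed contour is within about 1% on discs down to radius ≈ 30 px and
within 1% of the exact side length on a 100×100 square (its corners are
slightly rounded). The estimator name is recorded in the result so the
convention is auditable. Whether a hand-drawn selection corresponds to
polygon or spline length is not decidable from the workflow being
reproduced; the choice is declared, not asserted equivalent.

## Intensity-difference box counting

For a box grid of scale $\varepsilon$ anchored at the top-left pixel,
each box contributes $\delta I + 1$ where $\delta I$ is its intensity
spread, and

$$\mathrm{FD} = \text{slope of } \ln I(\varepsilon)
  \text{ vs } \ln(1/\varepsilon), \qquad
  I(\varepsilon) = \sum_{i,j} (\delta I_{i,j,\varepsilon} + 1).$$

The +1 keeps flat boxes countable, so a constant image reduces to
classical box counting of a filled plane and yields FD = 2 exactly under
exactly tiling scales. On the depth-6 Sierpinski carpet with grid-aligned
scales $\{3, 9, 27, 81, 243\}$ the per-scale sums have the closed form
$256\cdot 8^m + (9^m - 8^m)$ (boxes at level $m$ that contain carpet
foreground see the full 0–255 spread; the rest are flat), and the
regression slope is 1.8934, against the theoretical
$\log 8/\log 3 = 1.8928$ — the two fixture anchors the test suite and
`scripts/acceptance.R` verify.

Conventions:

* **Edge boxes.** Power-series scales rarely divide photograph
  dimensions, so edge boxes smaller than $\varepsilon\times\varepsilon$
  are included with their actual pixels — no pixel is discarded. The
  block series avoids partial boxes entirely by construction. Whether
  any scale produced partial boxes is recorded in the result metadata.
* **Grid anchoring.** One fixed top-left grid per scale, for
  determinism. Averaging over shifted grid origins is available
  (`gridOffsets`) but off by default.
* **Scale schemes.** Shape analysis uses the power series
  $\varepsilon = 4, 16, 64, \ldots$ (base 2, exponent step 2) capped at
  a quarter of the smaller image dimension; surface analysis uses the
  block series: all divisors of the ROI side in $[2, \text{side}/4]$.
  The divisor rule is a reasoned reconstruction of "grids calculated
  from the block size" under the constraint of exact tiling, and is
  flagged as such in the metadata. Fewer than three scales is an error
  in either scheme, as is a scale above half the smaller image
  dimension.
* **Input for shape FD.** The divide-blended grayscale image (lesion on
  white), not the binary mask: the estimator operates on intensities,
  and the blended image is the prepared product of the segmentation
  stage.
* **Direction.** On the synthetic cohorts, rougher textures (lower
  Hurst) and more irregular borders both give *higher* FD — the
  classical box-counting convention. The package asserts the fixture
  anchors and these measured orderings only.

## ROI tiling

Surface FD is measured on square ROIs lying entirely inside the mask
(450 px in the reference workflow; configurable, and the test suite uses
64 px). Placement is deterministic greedy raster order: candidate
top-left corners are scanned row-major at stride 1 and accepted iff the
square is fully inside the mask and disjoint from all accepted ROIs. The
fully-inside test uses a summed-area table, so the scan is linear in
image size. This honours the non-overlap and whole-lesion-coverage
intent while avoiding any operator choice of "characteristic" areas; a
centroid-out variant is available behind `placement = "centroid"`. A
lesion in which no ROI fits is flagged and excluded from surface
analysis rather than failing the run.

## Statistics

All tests are the base R implementations (`shapiro.test`, `t.test`,
`wilcox.test`, `aov`, `kruskal.test`, `cor`); the module's own logic is
the gating, pairing, post hocs and table assembly:

* **Normality gate.** Shapiro–Wilk at α = 0.05 per variable per group;
  parametric only if all groups pass. Degenerate inputs (n < 3,
  constant vectors) default to nonparametric with a note.
* **Post hocs.** Parametric branch: Fisher LSD — pairwise t on the
  pooled ANOVA residual mean square, unadjusted, exactly as named.
  Nonparametric branch: Dunn's z on mean ranks with tie correction and
  Bonferroni multiplication capped at 1 (reproducing the
  "p = 1.000000" cells typical of spreadsheet rank tables). Both are
  reconstructions of a commercial package's output and are labelled as
  such in the report objects.
* **Surface FD** is compared at ROI level (n = number of ROIs), which
  treats ROIs of one lesion as independent; that pseudo-replication
  caveat is inherent to the design being reproduced. Lesion-level
  aggregation can be done upstream of the test functions if desired.
* Report assembly is lossless: every lesion lands in exactly one row or
  one logged exclusion, and symmetry/permutation-calibration tests cover
  the assembly logic.

## The synthetic-data generator

Clinical images are not distributable, so validation runs on simulated
data designed to expose exactly the properties the pipeline measures:

* **Boundary**: $r(\theta) = R\,(1 + A \sum_k a_k \cos(k\theta +
  \varphi_k))$ with modes $k = 2\ldots K{+}1$, seeded coefficients
  $a_k \sim U(-1,1)/k$ and uniform phases. $A$
  (`irregularityAmplitude`) is the single border-irregularity knob. A
  perturbation driving $r \le 0$ anywhere is rejected with instructions
  to lower $A$.
* **Texture**: fractional Brownian field synthesized spectrally
  (amplitude $\propto f^{-(H+1)}$), standardized, scaled by `textureSd`
  (grey levels) around `lesionMean`.
* **Illumination pairing**: boundary and texture substreams depend only
  on the lesion seed, so the PL and NPL renders of one lesion share
  them exactly. The NPL variant compresses lesion/background contrast
  toward the background by `nplContrastFactor` and superimposes seeded
  saturated speckle (`specularNoiseDensity`) — the reflection artefacts
  polarization removes.
* **Seeding**: one integer master seed feeds a counter-based substream
  map, so cohorts are bit-reproducible file by file.

Defaults (chosen once, for realism at desk scale): 256×256 frame,
`baseRadius` 80 px, `harmonics` 48, `textureHurst` 0.5, `textureSd` 20,
`lesionMean` 70, `backgroundMean` 200, `nplContrastFactor` 0.7,
`specularNoiseDensity` 0.01. Two of these deserve justification:

* `harmonics = 48` places boundary modes down to ≈ 10 px wavelength.
  Clinical borders are serrated across scales; a border built only from
  low-order modes is smooth at box-counting scales, so amplitude would
  move the regression *intercept* (perimeter) but barely the *slope*
  (FD). Modes spanning the analysed scale range make the shape FD a
  genuine border-irregularity readout.
* `lesionMean = 70` with `nplContrastFactor = 0.7` keeps the NPL lesion
  mean (≈ 109) safely below the divide-blend saturation knee
  ($E$ saturates above $I \approx 126$), as real NPL photographs —
  which remain segmentable — do.

The three group presets (MM/DN/BN) differ in irregularity amplitude
(0.35/0.20/0.05) and Hurst (0.3/0.5/0.7). They are calibration-free
design choices giving a plausible group contrast, *not* estimates of any
patient population; none of the package's tests treats them as such.

What the generator does **not** emulate: hair, ulceration, specular
gradients, uneven illumination fields, colour (the RGB variant is a
fixed tint for exercising the conversion path), camera optics, or the
true appearance distributions of clinical cohorts. Passing tests
therefore demonstrate that the pipeline measures what it claims on
controlled inputs with known ground truth — not that any particular
clinical effect size will be reproduced on real photographs.

## Numerical choices and degenerate inputs

* The log-log regression uses all scales; no scale-window selection.
  The FD of a perfectly flat image is exactly 2 with $R^2 = 1$.
* `boxIntensitySum` reduces blocks by offset-strided `pmax`/`pmin`
  passes (no per-box interpreter loop), verified against a literal
  double-loop oracle.
* Division-by-zero in the blend is impossible by the +1 in the
  denominator; the all-white degenerate image errors at mask
  extraction.
* Ties in ROI placement cannot occur (raster order is total); ties in
  rank statistics use the standard mid-rank correction inside Dunn's z.
* Tie-only (zero-variance) vectors yield `NA` Spearman correlations
  with a note rather than an error.

## Problem sizes used in the test suite

Fixture anchors run at full reference size (729×729 carpet, 512×512
square). Cohort-level checks use 256×256 lesions with 64 px ROIs and
n = 20 per arm for the irregularity-separation check, 10 seeds per Hurst
level for texture monotonicity, and 200 seeded replicates for the
statistical-power reconstructions — sizes at which the whole suite runs
in well under a minute while keeping every assertion at its stated
tolerance.

## Known limitations

* One lesion per photograph; multi-lesion frames are out of scope.
* The divide-blend model assumes the lesion is darker than the
  background everywhere; depigmented or halo lesions would need a
  different contrast model.
* Perimeter is contour-polygon length; against spline-smoothed manual
  tracing a small systematic offset is possible.
* The block-series and post hoc reconstructions match the *described*
  behaviour of the original tools, not bit-level outputs of those
  closed-source programs.
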