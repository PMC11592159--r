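---
title: "Adipocyte morphometry and multiscale wavelet anisotropy: methods"
author: "adipoaniso"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adipocyte morphometry and multiscale wavelet anisotropy: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Perivascular adipose tissue (PVAT) sits on the adventitia of blood vessels
and signals to the vessel wall; its organization differs from subcutaneous
fat (SubQ) in ways that routine histopathology does not resolve. This
package implements a whole-slide computational pipeline for H&E-stained
adipose sections with two outputs per donor: (i) adipocyte morphometry
(area, solidity, circularity, eccentricity, density, stromal fraction) from
an automated sliding-window segmentation, and (ii) a *multiscale anisotropy
factor* that summarizes how directionally organized the stained tissue
matrix is at each of 50 wavelet size scales. Donor groups (e.g. depot
PVAT vs SubQ, or disease groups) are compared per scale with unpaired
Wilcoxon rank-sum tests.

Because no imaging data are deposited with the study this design derives
from, the package ships a synthetic H&E "adipose foam" generator with exact
ground truth. Every stage is tested against that generator; the final
section states what those tests do and do not establish about real tissue.

# Pipeline stages and their parameters

## Tissue mask and sliding windows

The RGB slide is converted to HSV; an Otsu threshold on the 8-bit-quantized
saturation channel separates stained tissue (high saturation) from
background glass and unstained lipid. Ties in the Otsu criterion break
toward the lowest threshold. A tight bounding box around the mask is
expanded rightward/downward to the next multiples of 1024 px (zero-padding
if it overruns the raster), and 1024 x 1024 windows are enumerated
row-major at a 256 px stride, so the window count per row is
`(W - 1024)/256 + 1`.

## Segmentation

Within a window, segmentation runs on the saturation channel: Gaussian blur
(sd 3 px), Triangle threshold (suited to the skewed unimodal histogram of a
mostly-unstained field; pixels below threshold are unstained foreground),
Euclidean distance transform of the foreground, distance-peak markers with
minimum separation `sqrt(minArea/pi)` (~22.6 px, the radius of the smallest
retainable adipocyte), and competitive region growing from those markers
(EBImage's `propagate`), which realizes the seeded watershed. Labels
touching the window border are removed.

One deliberate addition: thresholding a *blurred* channel places the object
edge where the blurred membrane skirt crosses a threshold that sits barely
above the interior noise floor, several pixels outside the membrane — the
raw objects under-estimate the lipid area by ~25% on the synthetic foam.
Since a blurred stained band of half-width comparable to the blur sd
crosses its true edge at about 70% of its blurred peak amplitude, each
label is finally re-grown (competitively, so adjacent cells cannot merge)
into the region below `baseline + 0.7 * (membrane peak - baseline)` of
blurred saturation. This restores the median retained area to within a few
percent of truth (`restoreBoundary = FALSE` disables it). The 0.7 fraction
assumes membranes roughly as wide as the blur; much thinner membranes would
warrant a larger fraction.

## Object and window filters

All thresholds are the published pipeline values, interpreted strictly at
the boundaries: areas outside the inclusive [1600, 9000] px^2 band are
removed; objects above 25000 px^2 with eccentricity above 0.87 are removed
(a rule retained verbatim although the 9000 px^2 cap subsumes it — exposed
as the independent predicate `isBigEccentric()`); perimeter/area of 0.14
or more is removed, with perimeter fixed as the 4-direction Crofton
estimator (accurate to ~2% on disks, ~6% low on straight edges; the ratio
threshold is only meaningful relative to this estimator, which is why it is
frozen and tested). A window is accepted when retained objects cover at
least 30% of it. Centroids within 31 px across overlapping windows are
clustered by transitive closure and one survivor per cluster is drawn
uniformly under the run seed — the pipeline's only stochastic step.
Accepted windows are saved as anisotropy patches greedily, in scan order,
whenever overlap with every previously saved patch is below 20%.

## Morphometrics

Measurements come from pixel counts and image moments: eccentricity
`sqrt(1 - (b/a)^2)` from the second-moment ellipse, solidity as area over
the convex-hull lattice area (Pick's theorem, so a digitized rectangle has
solidity exactly 1), circularity `4 pi A / P^2` with the Crofton perimeter
(hence values up to ~1.3 on straight-edged shapes; a documented property
of the estimator, not an error). Micron conversion multiplies areas by
`pixelSizeUm^2` and linear measures by `pixelSizeUm`. Donor summaries
report medians, adipocytes per 1e5 um^2, and a stromal fraction defined as
tissue-mask area inside analyzed windows minus adipocyte area — a stated
reinterpretation, since the original stromal-area provenance (manual FIJI
analysis) is not fully specified.

The published pixel-micron equivalences are internally inconsistent
(9000 px = 3674 um^2 implies 0.639 um/px; 31 px = 12.7 um implies
0.41 um/px), so `pixelSizeUm` is a required user calibration, defaulting
to 0.41.

## Multiscale anisotropy (2D WTMM)

The analyzing wavelets are the partial derivatives of the unit 2D Gaussian;
at scale `a`,

    T_i(b, a) = (1/a^2) \int f(x) psi_i((x - b)/a) d^2x ,

computed by FFT with mirror padding of at least `3a` (padded sizes rounded
up to 2-3-5-smooth integers; the pad fill is mirrored, never zero). The L1
`1/a^2` normalization only scales the modulus and cannot change the
anisotropy factor — asserted by the intensity-rescaling invariance test. A
pixel is a modulus maximum iff its modulus strictly exceeds the modulus
interpolated one pixel away along both senses of the gradient direction,
with two numerical choices worth stating: interpolation is Catmull-Rom
bicubic, because bilinear interpolation attenuates diagonal directions
more than axis directions and measurably skews the retained orientation
histogram on isotropic fields; and fields whose maximal modulus is below
1e-12 are treated as constant. Points within `a` of the border are
discarded (mirror-seam distortion reaches ~3a; tests assert exact
orientation alignment only beyond that). Orientations are folded to
[0, pi) since membrane edges are orientation, not direction, features.

The anisotropy factor at one scale is the normalized entropy deficit of
the orientation histogram over 90 equal bins:

    F = 1 - H / ln(90),  H = -sum p_i ln p_i ,

0 for an isotropic distribution, 1 for perfect alignment. The study this
derives from cites the WTMM literature without printing a formula; this
definition is bounded, matches the described use, and sits behind the
single function `anisotropyFactor()` so it can be swapped. Two numerical
choices: a Miller-Madow correction `(B_occupied - 1)/(2n)` is added to H
because plug-in entropy is biased low at the few hundred maxima available
at the largest scales (which would fabricate anisotropy out of sampling
noise), and F is clamped to [0, 1]. Scales with fewer than 50 maxima are
recorded as missing. The default grid is 50 log-spaced scales from 3 to
160 px (~1.2-66 um at 0.41 um/px, bracketing membrane-scale and
tissue-organization ranges); the scale in microns is reported as
`scale_px * pixelSizeUm`, the natural choice given that no explicit
scale-to-micron mapping is printed in the source study. A donor's spectrum
is the arithmetic mean of its patch spectra.

The per-scale normalized depot difference is
`(F_SubQ - F_PVAT) / (F_SubQ + F_PVAT)` (0 where both vanish). Note the
figure caption it mirrors describes a reference line "at 1.0" for
equivalence, but the quoted formula is 0 at equivalence; the formula is
implemented as quoted.

## Statistics

`wilcoxonRankSum()` is exact by full enumeration of rank assignments
(average ranks under ties; two-sided as the permutation probability of a
rank sum at least as extreme) for pooled sizes up to 12, and the normal
approximation with tie and continuity corrections (via `wilcox.test`)
above. Per-scale comparisons apply it at each scale with *no*
multiple-testing correction, matching the published per-scale alpha of
0.05 (a Benjamini-Hochberg option exists but is off by default); runs of
significant scales are reported as micron intervals. The donor, not the
patch, is the unit of analysis. The categorical 2x2 test is Pearson
chi-squared without continuity correction — the only choice that
reproduces the published diabetes-incidence p-value (0.022) from its
printed counts; Fisher's exact test does not, so the identification of the
test is an inference and is flagged as such.

# The synthetic foam generator

The generator emulates the features the pipeline is sensitive to: closely
packed polygonal white adipocytes, thin eosin membranes, sparse
hematoxylin nuclei, global anisotropic stretch, and sensor noise. Cells
are the regions of an additively weighted (power-diagram) nearest-seed
assignment over a hexagonal lattice jittered with sd 0.25 x pitch;
lognormal target areas (right-skewed, as adipocyte areas are) enter
through the weights. Membranes arise by eroding every cell by half the
membrane thickness, computed in one distance transform to the region
boundaries; the lattice pitch is solved so the *eroded* cells hit the
requested mean area (the discrete boundary layer adds ~2 px to the
effective band, which the solve accounts for). Stretch is implemented as
the Voronoi assignment in the pulled-back metric — pixel coordinates pass
through the inverse affine before the nearest-seed search — because the
Euclidean Voronoi of affinely stretched seed *points* is provably not a
stretched tessellation (cells grow but barely elongate), which would
defeat the generator's purpose of emulating oriented tissue.

Defaults, chosen once as the study conditions: 1024 x 1024 px, mean cell
area 4000 px^2 (mid retention band; about the reported PVAT median of
~1700 um^2 under the 0.64 um/px calibration), area CV 0.2, membrane 4 px,
one nucleus per cell, Gaussian noise sd 4 on the 0-255 scale. Stain colors
are fixed constants (eosin RGB 235,120,170; hematoxylin 90,60,140; lumen
248,246,248) since only hue/saturation contrast matters downstream.
Identical seeds give bitwise-identical images; the emitted cell table is
definitionally consistent with the label map (areas are its pixel counts).
Cells clipped by the image edge are flagged `touches_border`, because
their truncated areas sit below the bulk size distribution.

What the generator does *not* emulate: stain variability and uneven
illumination, crown-like structures, vessels and ducts, out-of-focus
texture inside lipid droplets, and multi-resolution WSI pyramids. Tests
passing on foam therefore establish the correctness of the computational
chain (thresholds, boundary behavior, recovery of known geometry and
anisotropy), not segmentation accuracy on real slides, where staining
artifacts dominate the error budget.

# Problem sizes used by the test and acceptance suites

The suites run the real pipeline at desk scale, chosen as the smallest
sizes that exercise every code path: single 1024 x 1024 windows (the
minimum the window geometry admits) for segmentation recovery and the full
50-scale spectrum; 512 x 512 textures with 4-8-scale grids for the
anisotropy property checks; two-group studies of 4 donors x 2 depots (one
slide each) for the end-to-end comparison, with 6-scale grids; 200
replicates of 10-vs-10 donors for the null calibration of the per-scale
test, checked against the exactly computable attainable level of the
rank-sum test rather than the nominal 5%.

# Known limitations

- The Crofton perimeter is the contract for the 0.14 ratio; comparing that
  ratio against perimeters from other estimators is meaningless.
- The boundary-restoration fraction (0.7) is derived for membranes about
  as wide as the blur; it is configurable but not auto-calibrated.
- The anisotropy factor definition is one reasonable member of a family
  (entropy-based); absolute F values are not comparable across definitions,
  only contrasts within one definition are.
- Windows are processed independently; adipocytes larger than a window or
  objects split by the border rule are handled by the dedup radius and the
  size cap, not by stitching.
- The dedup survivor draw is the only stochastic step; end-to-end CSV
  outputs are bit-identical under a fixed seed, and this is tested.
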