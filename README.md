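# adipoaniso

Whole-slide analysis of H&E-stained adipose tissue in R: automated
sliding-window segmentation and morphometry of adipocytes, and a
multiscale **anisotropy factor** built on the 2D Wavelet Transform Modulus
Maxima (WTMM) method, with nonparametric group statistics. The package
targets studies that compare adipose depots — e.g. perivascular (PVAT)
versus subcutaneous (SubQ) fat — across donor groups, where routine
histopathology shows little difference but multiscale organization does.

## What it computes

**Segmentation and morphometry.** Slides are masked by an Otsu threshold
on the HSV saturation channel; a bounding box divisible by 1024 is tiled
with 1024 x 1024 windows at a 256 px stride. Each window is segmented
(3 px Gaussian blur, Triangle threshold, seeded watershed on the distance
transform), and objects are filtered by the published rules: areas outside
[1600, 9000] px^2 removed, objects > 25000 px^2 with eccentricity > 0.87
removed, perimeter/area >= 0.14 removed. Windows with >= 30% object
coverage contribute records; centroids within 31 px are deduplicated (one
random survivor under the run seed); low-overlap (< 20%) windows are saved
as analysis patches. Per-donor medians of area, solidity, circularity and
eccentricity, adipocyte density per 1e5 um^2, and stromal fraction are
reported in calibrated microns.

**Multiscale anisotropy.** For each patch, the continuous wavelet
transform with Gaussian-derivative wavelets

    T_i(b, a) = (1/a^2) \int f(x) \psi_i((x - b)/a) d^2 x ,
    \psi_1 = \partial g/\partial x, \psi_2 = \partial g/\partial y

is evaluated at 50 log-spaced scales a (3-160 px). Modulus maxima (pixels
whose modulus exceeds the interpolated modulus along +/- the gradient
direction) are collected and their orientations folded to [0, pi). The
anisotropy factor per scale is the normalized entropy deficit of the
orientation histogram over 90 bins, `F = 1 - H/ln 90`: 0 = isotropic,
1 = perfectly aligned. Donor spectra (patch means) are compared between
groups with an unpaired two-sided Wilcoxon rank-sum test at each scale
(exact by enumeration for pooled n <= 12), and contiguous significant
scales are reported as micron ranges. A Pearson chi-squared test (no
continuity correction) covers 2x2 donor demographics.

**Synthetic ground truth.** `generateFoam()` renders H&E-like adipose
foam (power-diagram cells on a jittered hex lattice, eosin membranes,
nuclei, noise, optional anisotropic stretch) with an exact label map and
cell table, so the whole pipeline is testable without patient slides.

## Worked example

```r
library(adipoaniso)

## a synthetic slide with known truth
foam <- generateFoam(FoamParams(widthPx = 1024L, heightPx = 1024L,
                                seed = 11L))
foam$truth
#> FoamTruth: 269 cells, 1024 x 1024 px, stromal fraction 0.150

## segment and filter one window
lab <- segmentWindow(foam$rgb)
obj <- filterObjects(lab)
acceptWindow(obj)$coverage
#> [1] 0.686
median(obj$area)
#> [1] 3813.5
ct <- cellTable(foam$truth)
median(ct$true_area_px2[ct$true_area_px2 >= 1600 & ct$true_area_px2 <= 9000])
#> [1] 3756      # segmentation recovers the true median within ~2%

## anisotropy spectrum across the 50 default scales
sp <- anisotropySpectrum(foam$rgb, scaleGrid(), source = "foam")
sp
#> AnisotropySpectrum 'foam': 50 scales (50 defined), F in [0.000, 0.084]

## a grating is strongly anisotropic, an isotropic field is not
g8 <- scaleGrid(nScales = 8L, minScalePx = 3, maxScalePx = 24)
max(anisotropyF(anisotropySpectrum(
  generateOrientedTexture(512, 512, 24, pi/3, 1), g8)), na.rm = TRUE)
#> [1] 0.848
max(anisotropyF(anisotropySpectrum(
  generateIsotropicField(512, 512, 8, seed = 1L), g8)), na.rm = TRUE)
#> [1] 0.010

## the published diabetes 2x2 (1/16 vs 14/38 donors)
chiSquared2x2(1, 15, 14, 24)$p
#> [1] 0.0219
```

The numbers mean: on default synthetic tissue the segmentation recovers
the true median adipocyte area to a few percent; foam with no imposed
stretch scores near-zero anisotropy at every scale while an oriented
grating saturates the factor near its closed-form two-bin bound
(`1 - ln 2 / ln 90 = 0.846`); and the one printed statistic that is
recomputable from published counts — the diabetes-incidence chi-squared —
reproduces at p = 0.022.

For a whole study, put one slide per row in a metadata CSV
(`donor_id, group, depot, diabetic, path, pixel_size_um`) and run

```r
runPipeline("meta.csv", "out/", pipelineConfig(), seed = 1)
```

which writes `adipocytes.csv` (published column set), an extended record
table, `donor_summary.csv`, `anisotropy.csv`, per-stratum
`comparison_*.csv`, `significant_ranges.json` and a run manifest. Reruns
with the same seed are bit-identical. A thin command-line wrapper with
`synth` / `mask` / `segment` / `aniso` / `compare` / `run` subcommands
lives at `inst/cli/adipoaniso.R`.

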