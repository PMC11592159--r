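#' @import methods
#' @importFrom stats median rnorm rpois runif sd quantile pchisq rlnorm
#' @importFrom utils read.csv write.csv combn packageVersion
NULL

## ---------------------------------------------------------------------------
## Synthetic foam

#' Parameters of the synthetic H&E adipose foam generator
#'
#' Describes a field of closely packed, lipid-filled (unstained) adipocytes
#' separated by thin eosin-stained membranes, with optional global anisotropic
#' stretch, sparse hematoxylin nuclei and Gaussian imaging noise.
#'
#' @slot widthPx,heightPx image size in pixels (each at least 256).
#' @slot meanCellAreaPx2 target mean cell area in px^2.
#' @slot cellAreaCv coefficient of variation of cell areas, in [0, 1].
#' @slot membraneThicknessPx membrane thickness in pixels; must be smaller
#'   than \code{sqrt(meanCellAreaPx2)}.
#' @slot stretchFactor anisotropic dilation factor (>= 1) applied to the seed
#'   lattice along \code{stretchAngleRad}.
#' @slot stretchAngleRad stretch direction in radians, in [0, pi).
#' @slot nucleiPerCell expected number of nuclei per cell (Poisson).
#' @slot noiseSd Gaussian intensity noise s.d. on the 0-255 scale.
#' @slot seed integer RNG seed; identical seeds give bitwise-identical output.
#' @seealso [generateFoam()]
#' @export
setClass("FoamParams", representation(
  widthPx = "integer", heightPx = "integer",
  meanCellAreaPx2 = "numeric", cellAreaCv = "numeric",
  membraneThicknessPx = "numeric",
  stretchFactor = "numeric", stretchAngleRad = "numeric",
  nucleiPerCell = "numeric", noiseSd = "numeric", seed = "integer"))

setValidity("FoamParams", function(object) {
  msg <- character()
  if (object@widthPx < 256L || object@heightPx < 256L)
    msg <- c(msg, "widthPx and heightPx must each be >= 256")
  if (object@meanCellAreaPx2 <= 0)
    msg <- c(msg, "meanCellAreaPx2 must be positive")
  if (object@cellAreaCv < 0 || object@cellAreaCv > 1)
    msg <- c(msg, "cellAreaCv must lie in [0, 1]")
  if (object@membraneThicknessPx <= 0)
    msg <- c(msg, "membraneThicknessPx must be positive")
  if (object@membraneThicknessPx >= sqrt(object@meanCellAreaPx2))
    msg <- c(msg, "membraneThicknessPx must be < sqrt(meanCellAreaPx2)")
  if (object@stretchFactor < 1)
    msg <- c(msg, "stretchFactor must be >= 1")
  if (object@stretchAngleRad < 0 || object@stretchAngleRad >= pi)
    msg <- c(msg, "stretchAngleRad must lie in [0, pi)")
  if (object@nucleiPerCell < 0) msg <- c(msg, "nucleiPerCell must be >= 0")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct foam generator parameters
#'
#' Defaults describe the study tissue: mean cell area 4000 px^2 (the middle of
#' the 1600-9000 px^2 retention band, matching reported adipocyte medians of
#' roughly 1700-2650 um^2 once calibrated), 20% area CV, 4 px membranes,
#' one nucleus per cell and mild sensor noise.
#'
#' @param widthPx,heightPx image size in pixels.
#' @param meanCellAreaPx2 target mean cell area (px^2).
#' @param cellAreaCv coefficient of variation of cell areas.
#' @param membraneThicknessPx membrane thickness (px).
#' @param stretchFactor global anisotropic dilation (>= 1).
#' @param stretchAngleRad stretch direction in radians, [0, pi).
#' @param nucleiPerCell expected nuclei per cell.
#' @param noiseSd Gaussian noise s.d. (0-255 scale).
#' @param seed integer RNG seed.
#' @return A [FoamParams-class] object.
#' @examples
#' FoamParams(widthPx = 512L, heightPx = 512L, seed = 7L)
#' @export
FoamParams <- function(widthPx = 1024L, heightPx = 1024L,
                       meanCellAreaPx2 = 4000, cellAreaCv = 0.2,
                       membraneThicknessPx = 4, stretchFactor = 1,
                       stretchAngleRad = 0, nucleiPerCell = 1,
                       noiseSd = 4, seed = 1L) {
  new("FoamParams", widthPx = as.integer(widthPx),
      heightPx = as.integer(heightPx),
      meanCellAreaPx2 = as.numeric(meanCellAreaPx2),
      cellAreaCv = as.numeric(cellAreaCv),
      membraneThicknessPx = as.numeric(membraneThicknessPx),
      stretchFactor = as.numeric(stretchFactor),
      stretchAngleRad = as.numeric(stretchAngleRad),
      nucleiPerCell = as.numeric(nucleiPerCell),
      noiseSd = as.numeric(noiseSd), seed = as.integer(seed))
}

#' Ground truth emitted by the foam generator
#'
#' @slot labelMap integer matrix; 0 = membrane/stroma, k > 0 = cell k.
#' @slot cellTable data.frame with one row per cell:
#'   \code{cell_id, true_area_px2, true_cx, true_cy, true_long_axis,
#'   true_short_axis, touches_border} (areas by pixel count of
#'   \code{labelMap}, axes from the second-moment ellipse; cells clipped by
#'   the image edge are flagged, since their clipped areas undershoot the
#'   bulk size distribution).
#' @slot stromalFraction fraction of pixels that are membrane/stroma.
#' @export
setClass("FoamTruth", representation(
  labelMap = "matrix", cellTable = "data.frame", stromalFraction = "numeric"))

setValidity("FoamTruth", function(object) {
  msg <- character()
  npx <- length(object@labelMap)
  if (npx > 0) {
    stromal <- sum(object@labelMap == 0L)
    if (abs(sum(object@cellTable$true_area_px2) + stromal - npx) > 0.5)
      msg <- c(msg, "cell areas + stromal pixels must equal total pixels")
    if (abs(object@stromalFraction - stromal / npx) > 1e-12)
      msg <- c(msg, "stromalFraction inconsistent with labelMap")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn FoamTruth-class label map accessor.
#' @param object a \code{FoamTruth}.
#' @export
setGeneric("labelMap", function(object) standardGeneric("labelMap"))
#' @rdname FoamTruth-class
#' @export
setMethod("labelMap", "FoamTruth", function(object) object@labelMap)

#' @describeIn FoamTruth-class per-cell truth table accessor.
#' @export
setGeneric("cellTable", function(object) standardGeneric("cellTable"))
#' @rdname FoamTruth-class
#' @export
setMethod("cellTable", "FoamTruth", function(object) object@cellTable)

#' @describeIn FoamTruth-class stromal (membrane) pixel fraction.
#' @export
setGeneric("stromalFraction",
           function(object) standardGeneric("stromalFraction"))
#' @rdname FoamTruth-class
#' @export
setMethod("stromalFraction", "FoamTruth",
          function(object) object@stromalFraction)

setMethod("show", "FoamTruth", function(object) {
  cat("FoamTruth:", nrow(object@cellTable), "cells,",
      paste(dim(object@labelMap), collapse = " x "), "px,",
      sprintf("stromal fraction %.3f\n", object@stromalFraction))
})

## ---------------------------------------------------------------------------
## Slides, masks, windows

#' A calibrated H&E slide raster plus donor metadata
#'
#' @slot rgb numeric H x W x 3 array on the 0-255 (8-bit) scale.
#' @slot pixelSizeUm microns per pixel (> 0).
#' @slot donorId donor identifier.
#' @slot group surgical group, \code{"VR"} (valve repair, no coronary artery
#'   disease) or \code{"CABG"} (coronary artery bypass graft).
#' @slot depot adipose depot, \code{"PVAT"} (perivascular) or \code{"SubQ"}
#'   (subcutaneous).
#' @slot diabetic logical; \code{NA} when unknown.
#' @export
setClass("SlideImage", representation(
  rgb = "array", pixelSizeUm = "numeric", donorId = "character",
  group = "character", depot = "character", diabetic = "logical"))

setValidity("SlideImage", function(object) {
  msg <- character()
  if (length(dim(object@rgb)) != 3L || dim(object@rgb)[3L] != 3L)
    msg <- c(msg, "rgb must be an H x W x 3 array")
  if (object@pixelSizeUm <= 0) msg <- c(msg, "pixelSizeUm must be > 0")
  if (!object@group %in% c("VR", "CABG", NA_character_))
    msg <- c(msg, "group must be 'VR' or 'CABG'")
  if (!object@depot %in% c("PVAT", "SubQ", NA_character_))
    msg <- c(msg, "depot must be 'PVAT' or 'SubQ'")
  if (length(msg)) msg else TRUE
})

#' Construct a slide image
#'
#' @param rgb H x W x 3 array, 0-255 scale.
#' @param pixelSizeUm microns per pixel. The default 0.41 corresponds to the
#'   31 px = 12.7 um dedup-radius calibration; supply your own microscope
#'   calibration for real data.
#' @param donorId,group,depot,diabetic donor metadata.
#' @return A [SlideImage-class].
#' @export
SlideImage <- function(rgb, pixelSizeUm = 0.41, donorId = "donor",
                       group = "VR", depot = "PVAT", diabetic = NA) {
  new("SlideImage", rgb = rgb, pixelSizeUm = as.numeric(pixelSizeUm),
      donorId = as.character(donorId), group = as.character(group),
      depot = as.character(depot), diabetic = as.logical(diabetic))
}

setMethod("show", "SlideImage", function(object) {
  d <- dim(object@rgb)
  cat(sprintf("SlideImage %s [%s %s] %d x %d px @ %.3f um/px\n",
              object@donorId, object@group, object@depot,
              d[2L], d[1L], object@pixelSizeUm))
})

#' A binary tissue mask with its 1024-divisible bounding box
#'
#' @slot mask logical matrix aligned to the slide raster (TRUE = tissue).
#' @slot bbox integer vector \code{(x0, y0, width, height)}, 1-based top-left;
#'   width and height are multiples of 1024 and may extend past the raster
#'   (the pipeline zero-pads when extracting windows).
#' @export
setClass("TissueMask", representation(mask = "matrix", bbox = "integer"))

setValidity("TissueMask", function(object) {
  msg <- character()
  if (length(object@bbox) != 4L) msg <- c(msg, "bbox must have length 4")
  else {
    if (object@bbox[3L] %% 1024L != 0L || object@bbox[4L] %% 1024L != 0L)
      msg <- c(msg, "bbox width and height must be divisible by 1024")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "TissueMask", function(object) {
  cat(sprintf("TissueMask: %d tissue px; bbox x0=%d y0=%d %d x %d\n",
              sum(object@mask), object@bbox[1L], object@bbox[2L],
              object@bbox[3L], object@bbox[4L]))
})

#' The sliding-window grid over a bounding box
#'
#' Row-major enumeration of 1024 x 1024 windows advanced in 256 px steps.
#'
#' @slot coords integer matrix with columns \code{x, y} (1-based top-left
#'   corners) in scan order.
#' @slot windowSize window side length (1024).
#' @slot stride step between successive windows (256).
#' @export
setClass("WindowGrid", representation(
  coords = "matrix", windowSize = "integer", stride = "integer"))

setMethod("show", "WindowGrid", function(object) {
  cat(sprintf("WindowGrid: %d windows of %d px, stride %d\n",
              nrow(object@coords), object@windowSize, object@stride))
})

#' @describeIn WindowGrid-class window top-left corners in scan order.
#' @param object a \code{WindowGrid}.
#' @export
setGeneric("windowCoords", function(object) standardGeneric("windowCoords"))
#' @rdname WindowGrid-class
#' @export
setMethod("windowCoords", "WindowGrid", function(object) object@coords)

## ---------------------------------------------------------------------------
## Segmentation filter configuration

#' Object- and window-level quality filters for adipocyte segmentation
#'
#' Defaults are the published pipeline thresholds: objects outside
#' (1600, 9000) px^2 removed (boundaries retained), objects above 25000 px^2
#' with eccentricity above 0.87 removed, perimeter/area ratio of 0.14 or more
#' removed, windows kept when segmented objects cover at least 30%, duplicate
#' centroids collapsed within a 31 px radius, analysis patches kept below 20%
#' mutual overlap, and a 3 px Gaussian blur before thresholding.
#'
#' @slot minAreaPx2,maxAreaPx2 retained object area band (px^2), inclusive.
#' @slot bigAreaPx2 area above which the eccentricity rule applies.
#' @slot maxEccentricityBig eccentricity cut for very large objects.
#' @slot maxPerimeterAreaRatio objects with perimeter/area at or above this
#'   are removed.
#' @slot minCoverageFraction minimum segmented-object coverage of a window.
#' @slot dedupRadiusPx centroid deduplication radius (px).
#' @slot maxPatchOverlapFraction patches must overlap previously saved
#'   patches by less than this fraction.
#' @slot blurPx Gaussian blur s.d. applied to saturation before thresholding.
#' @export
setClass("FilterConfig", representation(
  minAreaPx2 = "numeric", maxAreaPx2 = "numeric", bigAreaPx2 = "numeric",
  maxEccentricityBig = "numeric", maxPerimeterAreaRatio = "numeric",
  minCoverageFraction = "numeric", dedupRadiusPx = "numeric",
  maxPatchOverlapFraction = "numeric", blurPx = "numeric"))

setValidity("FilterConfig", function(object) {
  msg <- character()
  if (!(0 < object@minAreaPx2 && object@minAreaPx2 < object@maxAreaPx2 &&
        object@maxAreaPx2 < object@bigAreaPx2))
    msg <- c(msg, "need 0 < minAreaPx2 < maxAreaPx2 < bigAreaPx2")
  fr <- c(object@minCoverageFraction, object@maxPatchOverlapFraction,
          object@maxEccentricityBig)
  if (any(fr <= 0 | fr >= 1)) msg <- c(msg, "fractions must lie in (0, 1)")
  if (object@maxPerimeterAreaRatio <= 0 || object@dedupRadiusPx <= 0 ||
      object@blurPx <= 0)
    msg <- c(msg, "ratios and radii must be > 0")
  if (length(msg)) msg else TRUE
})

#' @rdname FilterConfig-class
#' @param minAreaPx2,maxAreaPx2,bigAreaPx2,maxEccentricityBig
#'   object filters; see slots.
#' @param maxPerimeterAreaRatio,minCoverageFraction,dedupRadiusPx
#'   further filters; see slots.
#' @param maxPatchOverlapFraction,blurPx see slots.
#' @return \code{FilterConfig()} returns the validated configuration.
#' @examples
#' FilterConfig()
#' @export
FilterConfig <- function(minAreaPx2 = 1600, maxAreaPx2 = 9000,
                         bigAreaPx2 = 25000, maxEccentricityBig = 0.87,
                         maxPerimeterAreaRatio = 0.14,
                         minCoverageFraction = 0.30, dedupRadiusPx = 31,
                         maxPatchOverlapFraction = 0.20, blurPx = 3) {
  new("FilterConfig", minAreaPx2 = minAreaPx2, maxAreaPx2 = maxAreaPx2,
      bigAreaPx2 = bigAreaPx2, maxEccentricityBig = maxEccentricityBig,
      maxPerimeterAreaRatio = maxPerimeterAreaRatio,
      minCoverageFraction = minCoverageFraction,
      dedupRadiusPx = dedupRadiusPx,
      maxPatchOverlapFraction = maxPatchOverlapFraction, blurPx = blurPx)
}

setMethod("show", "FilterConfig", function(object) {
  cat(sprintf(paste0(
    "FilterConfig: area [%g, %g] px^2; big-area %g px^2 @ ecc > %g;\n",
    "  P/A < %g; coverage >= %g; dedup radius %g px; patch overlap < %g;",
    " blur %g px\n"),
    object@minAreaPx2, object@maxAreaPx2, object@bigAreaPx2,
    object@maxEccentricityBig, object@maxPerimeterAreaRatio,
    object@minCoverageFraction, object@dedupRadiusPx,
    object@maxPatchOverlapFraction, object@blurPx))
})

## ---------------------------------------------------------------------------
## Anisotropy

#' The multiscale grid of wavelet size scales
#'
#' @slot scalesPx strictly increasing, log-spaced scales in pixels.
#' @slot pixelSizeUm microns per pixel, used to report scales in microns.
#' @export
setClass("ScaleGrid",
         representation(scalesPx = "numeric", pixelSizeUm = "numeric"))

setValidity("ScaleGrid", function(object) {
  msg <- character()
  if (length(object@scalesPx) < 1L || any(diff(object@scalesPx) <= 0))
    msg <- c(msg, "scalesPx must be strictly increasing")
  if (any(object@scalesPx <= 0)) msg <- c(msg, "scalesPx must be positive")
  if (object@pixelSizeUm <= 0) msg <- c(msg, "pixelSizeUm must be > 0")
  if (length(msg)) msg else TRUE
})

#' Construct the default 50-scale grid
#'
#' 50 log-spaced scales from 3 px to 160 px; at the default 0.41 um/px
#' calibration this spans roughly 1.2-66 um, bracketing both the
#' membrane-scale (a few um) and tissue-organization (tens of um) ranges.
#'
#' @param nScales number of scales.
#' @param minScalePx,maxScalePx scale range in pixels.
#' @param pixelSizeUm microns per pixel.
#' @return A [ScaleGrid-class].
#' @examples
#' scaleGrid()
#' @export
scaleGrid <- function(nScales = 50L, minScalePx = 3, maxScalePx = 160,
                      pixelSizeUm = 0.41) {
  new("ScaleGrid",
      scalesPx = exp(seq(log(minScalePx), log(maxScalePx),
                         length.out = nScales)),
      pixelSizeUm = as.numeric(pixelSizeUm))
}

#' @describeIn ScaleGrid-class scales in pixels.
#' @param object a \code{ScaleGrid} or \code{AnisotropySpectrum}.
#' @export
setGeneric("scalesPx", function(object) standardGeneric("scalesPx"))
#' @rdname ScaleGrid-class
#' @export
setMethod("scalesPx", "ScaleGrid", function(object) object@scalesPx)

#' @describeIn ScaleGrid-class scales in microns.
#' @export
setGeneric("scalesUm", function(object) standardGeneric("scalesUm"))
#' @rdname ScaleGrid-class
#' @export
setMethod("scalesUm", "ScaleGrid",
          function(object) object@scalesPx * object@pixelSizeUm)

setMethod("show", "ScaleGrid", function(object) {
  cat(sprintf("ScaleGrid: %d scales, %.3g-%.3g px (%.3g-%.3g um)\n",
              length(object@scalesPx), min(object@scalesPx),
              max(object@scalesPx), min(scalesUm(object)),
              max(scalesUm(object))))
})

#' Anisotropy factor as a function of wavelet scale
#'
#' @slot scalesPx scales in pixels.
#' @slot F anisotropy factor per scale, in [0, 1]; \code{NA} where fewer than
#'   the minimum number of modulus maxima were available.
#' @slot nMaxima number of retained WTMM points per scale.
#' @slot pixelSizeUm microns per pixel.
#' @slot source identifier of the patch or donor the spectrum belongs to.
#' @export
setClass("AnisotropySpectrum", representation(
  scalesPx = "numeric", F = "numeric", nMaxima = "integer",
  pixelSizeUm = "numeric", source = "character"))

setValidity("AnisotropySpectrum", function(object) {
  msg <- character()
  if (length(object@F) != length(object@scalesPx))
    msg <- c(msg, "F must align with scalesPx")
  ok <- !is.na(object@F)
  if (any(object@F[ok] < 0 | object@F[ok] > 1))
    msg <- c(msg, "F must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' @rdname AnisotropySpectrum-class
#' @export
setMethod("scalesPx", "AnisotropySpectrum", function(object) object@scalesPx)
#' @rdname AnisotropySpectrum-class
#' @export
setMethod("scalesUm", "AnisotropySpectrum",
          function(object) object@scalesPx * object@pixelSizeUm)

#' @describeIn AnisotropySpectrum-class per-scale anisotropy factor.
#' @param object an \code{AnisotropySpectrum}.
#' @export
setGeneric("anisotropyF", function(object) standardGeneric("anisotropyF"))
#' @rdname AnisotropySpectrum-class
#' @export
setMethod("anisotropyF", "AnisotropySpectrum", function(object) object@F)

#' @describeIn AnisotropySpectrum-class retained maxima counts per scale.
#' @export
setGeneric("nMaxima", function(object) standardGeneric("nMaxima"))
#' @rdname AnisotropySpectrum-class
#' @export
setMethod("nMaxima", "AnisotropySpectrum", function(object) object@nMaxima)

setMethod("show", "AnisotropySpectrum", function(object) {
  ok <- !is.na(object@F)
  cat(sprintf(
    "AnisotropySpectrum '%s': %d scales (%d defined), F in [%.3f, %.3f]\n",
    object@source, length(object@F), sum(ok),
    if (any(ok)) min(object@F[ok]) else NA, if (any(ok)) max(object@F[ok])
    else NA))
})

## ---------------------------------------------------------------------------
## Statistics

#' A per-scale two-group comparison
#'
#' @slot scalesPx,scalesUmVec the scale grid in pixels and microns.
#' @slot pValues two-sided Wilcoxon rank-sum p-value at each scale.
#' @slot alpha significance level.
#' @slot significant logical per scale (\code{p < alpha}).
#' @slot ranges data.frame of contiguous significant scale ranges with
#'   columns \code{min_um, max_um}.
#' @export
setClass("ScaleComparison", representation(
  scalesPx = "numeric", scalesUmVec = "numeric", pValues = "numeric",
  alpha = "numeric", significant = "logical", ranges = "data.frame"))

setValidity("ScaleComparison", function(object) {
  msg <- character()
  p <- object@pValues[!is.na(object@pValues)]
  if (any(p < 0 | p > 1)) msg <- c(msg, "pValues must lie in [0, 1]")
  if (length(object@pValues) != length(object@scalesPx))
    msg <- c(msg, "pValues must align with scalesPx")
  if (length(msg)) msg else TRUE
})

#' @rdname ScaleComparison-class
#' @param object a \code{ScaleComparison}.
#' @export
setMethod("scalesPx", "ScaleComparison", function(object) object@scalesPx)
#' @rdname ScaleComparison-class
#' @export
setMethod("scalesUm", "ScaleComparison", function(object) object@scalesUmVec)

#' @describeIn ScaleComparison-class per-scale p-values.
#' @export
setGeneric("pValues", function(object) standardGeneric("pValues"))
#' @rdname ScaleComparison-class
#' @export
setMethod("pValues", "ScaleComparison", function(object) object@pValues)

#' @describeIn ScaleComparison-class contiguous significant ranges (um).
#' @export
setGeneric("significantRanges",
           function(object) standardGeneric("significantRanges"))
#' @rdname ScaleComparison-class
#' @export
setMethod("significantRanges", "ScaleComparison",
          function(object) object@ranges)

setMethod("show", "ScaleComparison", function(object) {
  cat(sprintf(
    "ScaleComparison: %d scales, %d significant at alpha = %g\n",
    length(object@pValues), sum(object@significant, na.rm = TRUE),
    object@alpha))
  if (nrow(object@ranges))
    cat("  ranges (um):",
        paste(sprintf("[%.1f, %.1f]", object@ranges$min_um,
                      object@ranges$max_um), collapse = ", "), "\n")
})
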