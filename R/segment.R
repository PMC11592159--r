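## Per-window adipocyte segmentation and the published object/window filters.

#' Triangle threshold of an 8-bit histogram
#'
#' Geometric threshold for skewed unimodal histograms: a line is drawn from
#' the histogram peak to the farthest non-empty tail bin, and the threshold
#' is the level maximizing the perpendicular distance between histogram and
#' line. Ties break toward the peak-side level.
#'
#' @param counts integer vector of length 256 (counts of levels 0..255).
#' @return threshold level in 0..255; pixels strictly below it are
#'   "unstained" foreground in [segmentWindow()].
#' @export
triangleThreshold <- function(counts) {
  stopifnot(length(counts) == 256L, all(counts >= 0))
  if (sum(counts) == 0) stop("empty histogram")
  peak <- which.max(counts)
  nz <- range(which(counts > 0))
  ## pick the tail farther from the peak
  tail <- if ((peak - nz[1L]) >= (nz[2L] - peak)) nz[1L] else nz[2L]
  if (tail == peak) return(peak - 1L)   # single occupied level
  idx <- if (tail < peak) tail:peak else peak:tail
  h <- counts[idx]
  ## distance from (i, h_i) to the peak-tail line
  x1 <- idx[1L]; y1 <- counts[x1]; x2 <- idx[length(idx)]; y2 <- counts[x2]
  d <- abs((y2 - y1) * idx - (x2 - x1) * h + x2 * y1 - y2 * x1)
  best <- idx[which.max(d)]
  best - 1L   # back to the 0..255 level scale
}

## Distance-transform peak markers with a minimum separation: grayscale
## dilation with a disc of diameter ~ minSep, plateaus collapsed to single
## seed pixels at their centroids.
distancePeakMarkers <- function(dist, minSep, minDist = 3) {
  side <- 2L * as.integer(floor(minSep / 2)) + 1L
  brush <- EBImage::makeBrush(side, shape = "disc")
  dil <- EBImage::imageData(EBImage::dilate(EBImage::Image(dist), brush))
  peaks <- dist >= dil & dist > minDist
  if (!any(peaks)) return(matrix(0L, nrow(dist), ncol(dist)))
  pl <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(peaks)))
  idx <- which(pl > 0)
  y <- (idx - 1L) %% nrow(pl) + 1L
  x <- (idx - 1L) %/% nrow(pl) + 1L
  f <- factor(pl[idx])
  cy <- round(tapply(y, f, mean)); cx <- round(tapply(x, f, mean))
  seeds <- matrix(0L, nrow(dist), ncol(dist))
  seeds[cbind(cy, cx)] <- seq_along(cy)
  seeds
}

#' Segment candidate adipocytes in one 1024 x 1024 window
#'
#' HSV conversion, Gaussian blur (s.d. \code{blurPx}) of the saturation
#' channel, Triangle threshold (stained material dark/background, unstained
#' lipid bright/foreground), then seeded watershed on the Euclidean distance
#' transform of the foreground: markers are distance peaks with minimum
#' separation \code{sqrt(minAreaPx2 / pi)}, and regions are grown with
#' EBImage's propagate. Labels touching any window border are removed.
#'
#' The Triangle threshold sits just above the unstained-interior intensity
#' mode, far down the blurred membrane's skirt, so the raw foreground
#' undershoots the lipid area by several pixels of radius. A final edge
#' localization compensates: for a stained band whose half-width is
#' comparable to the blur s.d., the blurred profile at the true band edge
#' is about 70% of its blurred peak amplitude, so each label is re-grown
#' (competitively, so adjacent cells never merge) into the region below
#' \code{baseline + edgeFraction * (membrane peak - baseline)} of blurred
#' saturation. Set \code{restoreBoundary = FALSE} for the raw thresholded
#' objects.
#'
#' @param rgbWindow size x size x 3 array on the 0-255 scale.
#' @param config a [FilterConfig-class].
#' @param restoreBoundary re-localize object edges after thresholding.
#' @param edgeFraction amplitude fraction of the blurred membrane peak at
#'   which the true edge is taken to sit.
#' @return integer label matrix (0 = background); may be all zero.
#' @export
segmentWindow <- function(rgbWindow, config = FilterConfig(),
                          restoreBoundary = TRUE, edgeFraction = 0.7) {
  stopifnot(length(dim(rgbWindow)) == 3L, dim(rgbWindow)[3L] == 3L)
  sat <- saturationChannel(rgbWindow)
  satB <- EBImage::imageData(EBImage::gblur(EBImage::Image(sat),
                                            sigma = config@blurPx,
                                            boundary = "replicate"))
  q <- quantize8(satB)
  h <- tabulate(as.vector(q) + 1L, nbins = 256L)
  thr <- triangleThreshold(h)
  fg <- q < thr
  if (!any(fg)) return(matrix(0L, nrow(q), ncol(q)))
  dist <- EBImage::imageData(EBImage::distmap(EBImage::Image(fg)))
  seeds <- distancePeakMarkers(dist, minSep = sqrt(config@minAreaPx2 / pi))
  if (!any(seeds > 0L)) return(matrix(0L, nrow(q), ncol(q)))
  lab <- EBImage::imageData(EBImage::propagate(
    EBImage::Image(dist), EBImage::Image(seeds),
    mask = EBImage::Image(fg), lambda = 1e-4))
  storage.mode(lab) <- "integer"
  if (restoreBoundary && any(!fg) && any(lab > 0L)) {
    baseline <- median(satB[fg])
    ridge <- quantile(satB[!fg], 0.9, names = FALSE)
    if (ridge > baseline) {
      level <- baseline + edgeFraction * (ridge - baseline)
      grow <- satB < level | lab > 0L
      lab <- EBImage::imageData(EBImage::propagate(
        EBImage::Image(matrix(0, nrow(lab), ncol(lab))),
        EBImage::Image(lab), mask = EBImage::Image(grow), lambda = 1))
      storage.mode(lab) <- "integer"
    }
  }
  ## drop labels touching the window border
  border <- unique(c(lab[1L, ], lab[nrow(lab), ], lab[, 1L], lab[, ncol(lab)]))
  border <- border[border > 0L]
  if (length(border)) lab[lab %in% border] <- 0L
  lab
}

#' Apply the published object filters to a labeled raster
#'
#' Measures every object and removes those with area outside the inclusive
#' [\code{minAreaPx2}, \code{maxAreaPx2}] band, those larger than
#' \code{bigAreaPx2} with eccentricity above \code{maxEccentricityBig}, and
#' those with perimeter/area ratio at or above
#' \code{maxPerimeterAreaRatio}.
#'
#' @param labels integer label matrix from [segmentWindow()].
#' @param config a [FilterConfig-class].
#' @return data.frame of surviving objects with columns \code{label, area,
#'   perimeter, cx, cy, eccentricity, solidity, circularity, long_axis,
#'   short_axis}.
#' @export
filterObjects <- function(labels, config = FilterConfig()) {
  m <- measureLabeled(labels)
  if (!nrow(m)) return(m)
  keep <- m$area >= config@minAreaPx2 & m$area <= config@maxAreaPx2 &
    !isBigEccentric(m$area, m$eccentricity, config) &
    (m$perimeter / m$area) < config@maxPerimeterAreaRatio
  m[keep, , drop = FALSE]
}

#' The very-large/highly-eccentric removal predicate
#'
#' TRUE for objects larger than \code{bigAreaPx2} (25000 px^2) whose
#' eccentricity exceeds \code{maxEccentricityBig} (0.87). Under the default
#' configuration this rule is subsumed by the 9000 px^2 area cap (no object
#' that survives the cap can trigger it); it is kept as an independent
#' predicate so the published rule stays visible and testable on its own.
#'
#' @param area object areas in px^2.
#' @param eccentricity object eccentricities.
#' @param config a [FilterConfig-class].
#' @return logical vector: which objects the rule removes.
#' @examples
#' isBigEccentric(c(26000, 26000, 5000), c(0.95, 0.5, 0.95))
#' @export
isBigEccentric <- function(area, eccentricity, config = FilterConfig()) {
  area > config@bigAreaPx2 & eccentricity > config@maxEccentricityBig
}

#' Window acceptance by segmented-object coverage
#'
#' A window is accepted when the retained objects occupy at least
#' \code{minCoverageFraction} (30%) of its area.
#'
#' @param objects data.frame from [filterObjects()].
#' @param config a [FilterConfig-class].
#' @param windowSize window side length in pixels.
#' @return list with \code{accept} (logical) and \code{coverage} (fraction).
#' @examples
#' acceptWindow(data.frame(area = 0.31 * 1024^2))
#' @export
acceptWindow <- function(objects, config = FilterConfig(),
                         windowSize = 1024L) {
  coverage <- if (nrow(objects)) sum(objects$area) / windowSize^2 else 0
  list(accept = coverage >= config@minCoverageFraction, coverage = coverage)
}

#' Collapse duplicate centroids from overlapping windows
#'
#' Records whose centroids lie within \code{dedupRadiusPx} (31 px) of one
#' another are clustered by transitive closure; within each cluster exactly
#' one record survives, chosen uniformly at random under the given seed. The
#' output has no centroid pair at distance <= the radius.
#'
#' @param records data.frame with global centroid columns \code{cx, cy}.
#' @param radius deduplication radius in pixels.
#' @param seed integer seed for the survivor draw.
#' @return the surviving subset of \code{records}.
#' @export
deduplicateCentroids <- function(records, radius = 31, seed = 1L) {
  n <- nrow(records)
  if (n <= 1L) return(records)
  cx <- records$cx; cy <- records$cy
  ## neighbor pairs via grid buckets of side = radius
  gx <- floor(cx / radius); gy <- floor(cy / radius)
  key <- paste(gx, gy)
  bucket <- split(seq_len(n), key)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  union2 <- function(i, j) { ri <- find(i); rj <- find(j); if (ri != rj) parent[rj] <<- ri }
  r2 <- radius^2
  for (k in names(bucket)) {
    g <- as.numeric(strsplit(k, " ", fixed = TRUE)[[1L]])
    cand <- integer()
    for (dx in -1:1) for (dy in -1:1) {
      kk <- paste(g[1L] + dx, g[2L] + dy)
      if (!is.null(bucket[[kk]])) cand <- c(cand, bucket[[kk]])
    }
    for (i in bucket[[k]]) {
      d2 <- (cx[cand] - cx[i])^2 + (cy[cand] - cy[i])^2
      for (j in cand[d2 <= r2]) if (j != i) union2(i, j)
    }
  }
  roots <- vapply(seq_len(n), find, integer(1L))
  keep <- withSeed(seed, {
    vapply(split(seq_len(n), roots), function(members) {
      if (length(members) == 1L) members
      else members[sample.int(length(members), 1L)]
    }, integer(1L))
  })
  records[sort(keep), , drop = FALSE]
}

#' Greedy selection of low-overlap anisotropy patches
#'
#' Accepted windows are considered in scan order; a window is saved as an
#' analysis patch iff its pixel-area overlap with every previously saved
#' patch is below \code{maxOverlap} (20%) of the window area.
#'
#' @param origins data.frame or matrix with columns \code{x, y} (top-left
#'   corners of accepted windows, in scan order).
#' @param windowSize window side length.
#' @param maxOverlap maximal tolerated pairwise overlap fraction.
#' @return logical vector: which origins are saved as patches.
#' @examples
#' selectPatches(data.frame(x = c(1, 257, 1025), y = 1))
#' @export
selectPatches <- function(origins, windowSize = 1024L, maxOverlap = 0.20) {
  origins <- as.data.frame(origins)
  n <- nrow(origins)
  saved <- logical(n)
  savedIdx <- integer()
  for (i in seq_len(n)) {
    ok <- TRUE
    for (j in savedIdx) {
      ox <- max(0, windowSize - abs(origins$x[i] - origins$x[j]))
      oy <- max(0, windowSize - abs(origins$y[i] - origins$y[j]))
      if (ox * oy / windowSize^2 >= maxOverlap) { ok <- FALSE; break }
    }
    if (ok) { saved[i] <- TRUE; savedIdx <- c(savedIdx, i) }
  }
  saved
}
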