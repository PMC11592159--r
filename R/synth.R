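## Synthetic H&E adipose "foam" images with ground truth.
##
## Cells are the regions of an additively weighted (power-diagram) nearest
## seed assignment over a jittered hexagonal lattice; lognormal target areas
## enter through the weights so realized areas are right-skewed. Membranes
## are made by eroding every cell by half the membrane thickness (computed
## in one pass as distance-to-region-boundary). Rendering maps membrane to
## eosin pink, sparse nuclei to hematoxylin purple and the lipid-filled cell
## interiors to near-white, then adds Gaussian 8-bit noise.

EOSIN <- c(235, 120, 170)
HEMATOXYLIN <- c(90, 60, 140)
LUMEN <- c(248, 246, 248)

## Jittered hexagonal lattice covering [1,w] x [1,h] with margin; returns
## a matrix with columns x, y. Pitch = nearest-neighbour spacing.
hexLattice <- function(w, h, pitch, margin, jitterSd) {
  rowStep <- pitch * sqrt(3) / 2
  ys <- seq(1 - margin, h + margin, by = rowStep)
  pts <- do.call(rbind, lapply(seq_along(ys), function(j) {
    off <- if (j %% 2L == 0L) pitch / 2 else 0
    xs <- seq(1 - margin + off, w + margin, by = pitch)
    cbind(x = xs, y = rep(ys[j], length(xs)))
  }))
  pts + matrix(rnorm(2L * nrow(pts), sd = jitterSd), ncol = 2L)
}

## Power-diagram pixel assignment, block-wise to keep the distance matrices
## small. seeds: n x 2 (x, y); w: additive weights (argmin of d^2 - w).
## An optional inverse affine (invT, about center ctr) maps pixel
## coordinates into the seeds' frame before the nearest-seed search: the
## resulting cells are the image of the isotropic tessellation under the
## forward affine, i.e. genuinely stretched cells.
assignPowerCells <- function(width, height, seeds, w, searchRadius,
                             block = 128L, invT = NULL, ctr = NULL) {
  lab <- matrix(0L, nrow = height, ncol = width)
  for (by in seq(1L, height, by = block)) {
    ye <- min(by + block - 1L, height)
    for (bx in seq(1L, width, by = block)) {
      xe <- min(bx + block - 1L, width)
      xs <- bx:xe; ys <- by:ye
      px <- rep(xs, each = length(ys))
      py <- rep(ys, times = length(xs))
      if (!is.null(invT)) {
        tx <- ctr[1L] + invT[1L, 1L] * (px - ctr[1L]) +
          invT[1L, 2L] * (py - ctr[2L])
        ty <- ctr[2L] + invT[2L, 1L] * (px - ctr[1L]) +
          invT[2L, 2L] * (py - ctr[2L])
        px <- tx; py <- ty
      }
      cand <- which(seeds[, 1L] >= min(px) - searchRadius &
                    seeds[, 1L] <= max(px) + searchRadius &
                    seeds[, 2L] >= min(py) - searchRadius &
                    seeds[, 2L] <= max(py) + searchRadius)
      if (!length(cand)) next
      d2 <- outer(px, seeds[cand, 1L], "-")^2 +
            outer(py, seeds[cand, 2L], "-")^2
      d2 <- sweep(d2, 2L, w[cand])
      lab[ys, xs] <- cand[max.col(-d2, ties.method = "first")]
    }
  }
  lab
}

## Per-cell pixel statistics of a label map: area, centroid, moment-ellipse
## axes. Vectorized over labels via rowsum.
labelStats <- function(lab) {
  idx <- which(lab > 0L)
  l <- lab[idx]
  y <- (idx - 1L) %% nrow(lab) + 1L
  x <- (idx - 1L) %/% nrow(lab) + 1L
  f <- factor(l)
  n <- as.vector(rowsum(rep(1, length(l)), f))
  sx <- as.vector(rowsum(as.numeric(x), f))
  sy <- as.vector(rowsum(as.numeric(y), f))
  sxx <- as.vector(rowsum(as.numeric(x)^2, f))
  syy <- as.vector(rowsum(as.numeric(y)^2, f))
  sxy <- as.vector(rowsum(as.numeric(x) * y, f))
  cx <- sx / n; cy <- sy / n
  mxx <- sxx / n - cx^2; myy <- syy / n - cy^2; mxy <- sxy / n - cx * cy
  tr <- (mxx + myy) / 2
  dt <- sqrt(pmax(((mxx - myy) / 2)^2 + mxy^2, 0))
  l1 <- pmax(tr + dt, 0); l2 <- pmax(tr - dt, 0)
  onBorder <- x == 1L | x == ncol(lab) | y == 1L | y == nrow(lab)
  tb <- as.vector(rowsum(as.numeric(onBorder), f)) > 0
  data.frame(cell_id = as.integer(levels(f)), true_area_px2 = n,
             true_cx = cx, true_cy = cy,
             true_long_axis = 4 * sqrt(l1), true_short_axis = 4 * sqrt(l2),
             touches_border = tb)
}

#' Generate a synthetic H&E adipose foam image with ground truth
#'
#' Produces a rendered RGB image of closely packed white adipocytes separated
#' by thin eosin-stained membranes, together with the true label map and
#' per-cell geometry. Output is bitwise reproducible for a fixed seed.
#'
#' @param params a [FoamParams-class] object.
#' @return A list with elements \code{truth} (a [FoamTruth-class]) and
#'   \code{rgb} (integer H x W x 3 array on the 0-255 scale).
#' @examples
#' foam <- generateFoam(FoamParams(widthPx = 256L, heightPx = 256L,
#'                                 meanCellAreaPx2 = 1200, seed = 3L))
#' stromalFraction(foam$truth)
#' @export
generateFoam <- function(params) {
  stopifnot(is(params, "FoamParams"))
  validObject(params)
  W <- params@widthPx; H <- params@heightPx
  t <- params@membraneThicknessPx
  ## Voronoi region area compensated for the membrane band so that realized
  ## (eroded) cell areas track meanCellAreaPx2: solve Av - (w/2) P(Av) = A
  ## with hexagon perimeter P(A) = 3.722 sqrt(A). The effective band width
  ## w is t plus the 2 px of the discrete region-boundary layer (one pixel
  ## on each side of every interface).
  k <- 3.722 * (t + 2) / 2
  u <- (k + sqrt(k^2 + 4 * params@meanCellAreaPx2)) / 2
  Av <- u^2
  pitch <- sqrt(2 * Av / sqrt(3))

  withSeed(params@seed, {
    seeds <- hexLattice(W, H, pitch, margin = 2 * pitch,
                        jitterSd = 0.25 * pitch)
    areas <- if (params@cellAreaCv > 0) {
      sdlog <- sqrt(log(1 + params@cellAreaCv^2))
      rlnorm(nrow(seeds), log(Av) - sdlog^2 / 2, sdlog)
    } else rep(Av, nrow(seeds))
    wts <- (areas - Av) / pi
    invT <- NULL; ctr <- NULL
    if (params@stretchFactor > 1) {
      th <- params@stretchAngleRad; s <- params@stretchFactor
      ctr <- c((W + 1) / 2, (H + 1) / 2)
      R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2L)
      invT <- R %*% diag(c(1 / s, 1)) %*% t(R)
    }
    lab <- assignPowerCells(W, H, seeds, wts, searchRadius = 3 * pitch,
                            invT = invT, ctr = ctr)

    ## Region boundary pixels (4-connectivity), then one distance transform
    ## gives the erosion by t/2 for every cell at once.
    bnd <- matrix(FALSE, H, W)
    bnd[-H, ] <- bnd[-H, ] | (lab[-H, ] != lab[-1L, ])
    bnd[-1L, ] <- bnd[-1L, ] | (lab[-1L, ] != lab[-H, ])
    bnd[, -W] <- bnd[, -W] | (lab[, -W] != lab[, -1L])
    bnd[, -1L] <- bnd[, -1L] | (lab[, -1L] != lab[, -W])
    dBnd <- EBImage::imageData(EBImage::distmap(EBImage::Image(!bnd)))
    interior <- dBnd > t / 2
    labelMap <- ifelse(interior, lab, 0L)

    keep <- sort(unique(labelMap[labelMap > 0L]))
    if (length(keep) < 4L)
      stop("degenerate tessellation: fewer than 4 cells")
    relab <- integer(max(keep)); relab[keep] <- seq_along(keep)
    labelMap[labelMap > 0L] <- relab[labelMap[labelMap > 0L]]
    storage.mode(labelMap) <- "integer"

    tab <- labelStats(labelMap)
    stromal <- sum(labelMap == 0L) / length(labelMap)

    ## Render: lumen interiors, eosin membranes, nuclei on the membrane.
    img <- array(0, dim = c(H, W, 3L))
    for (ch in 1:3)
      img[, , ch] <- ifelse(interior, LUMEN[ch], EOSIN[ch])
    if (params@nucleiPerCell > 0) {
      nNuc <- rpois(length(keep), params@nucleiPerCell)
      bndIdx <- which(bnd)
      bndLab <- lab[bndIdx]
      off <- expand.grid(dy = -2:2, dx = -2:2)
      off <- off[off$dx^2 + off$dy^2 <= 6.25, ]   # disc, radius 2.5 px
      for (ci in seq_along(keep)) {
        if (nNuc[ci] == 0L) next
        own <- bndIdx[bndLab == keep[ci]]
        if (!length(own)) next
        at <- own[sample.int(length(own), min(nNuc[ci], length(own)))]
        ay <- (at - 1L) %% H + 1L
        ax <- (at - 1L) %/% H + 1L
        for (ni in seq_along(at)) {
          yy <- ay[ni] + off$dy; xx <- ax[ni] + off$dx
          okp <- yy >= 1L & yy <= H & xx >= 1L & xx <= W
          for (ch in 1:3)
            img[cbind(yy[okp], xx[okp], ch)] <- HEMATOXYLIN[ch]
        }
      }
    }
    if (params@noiseSd > 0)
      img <- img + rnorm(length(img), sd = params@noiseSd)
    img <- round(pmin(pmax(img, 0), 255))
    storage.mode(img) <- "integer"

    list(truth = new("FoamTruth", labelMap = labelMap, cellTable = tab,
                     stromalFraction = stromal),
         rgb = img)
  })
}

#' Generate a sinusoidal oriented grating
#'
#' A grayscale test texture with known wavelength and orientation, used as a
#' fully aligned reference for the anisotropy analysis. \code{orientationRad}
#' is the direction of the wave vector (the image gradient); stripes run
#' perpendicular to it.
#'
#' @param width,height image size (px).
#' @param wavelengthPx grating wavelength in pixels (>= 4).
#' @param orientationRad wave-vector direction in radians.
#' @param contrast amplitude as a fraction of half-range, in [0, 1].
#' @return numeric matrix (rows = y) with values in [0, 255].
#' @examples
#' g <- generateOrientedTexture(128, 128, 16, 0, 1)
#' range(g)
#' @export
generateOrientedTexture <- function(width, height, wavelengthPx,
                                    orientationRad, contrast = 1) {
  stopifnot(wavelengthPx >= 4, contrast >= 0, contrast <= 1)
  x <- matrix(rep(seq_len(width), each = height), nrow = height)
  y <- matrix(rep(seq_len(height), times = width), nrow = height)
  phase <- 2 * pi * (x * cos(orientationRad) + y * sin(orientationRad)) /
    wavelengthPx
  127.5 * (1 + contrast * sin(phase))
}

#' Generate an isotropic Gaussian random field
#'
#' Gaussian-smoothed white noise with isotropic covariance: the null model
#' for the anisotropy factor. The smoothing is periodic (FFT) so the field is
#' stationary; it is standardized to mean 127.5 and s.d. 30 then clipped to
#' [0, 255].
#'
#' @param width,height image size (px).
#' @param correlationLengthPx Gaussian smoothing s.d. (>= 1).
#' @param seed integer RNG seed.
#' @return numeric matrix with values in [0, 255].
#' @examples
#' f <- generateIsotropicField(128, 128, 4, seed = 1L)
#' @export
generateIsotropicField <- function(width, height, correlationLengthPx,
                                   seed = 1L) {
  stopifnot(correlationLengthPx >= 1)
  withSeed(seed, {
    wn <- matrix(rnorm(width * height), nrow = height)
    ky <- 2 * pi * c(0:floor((height - 1) / 2),
                     -(ceiling((height - 1) / 2):1)) / height
    kx <- 2 * pi * c(0:floor((width - 1) / 2),
                     -(ceiling((width - 1) / 2):1)) / width
    G <- exp(-outer(ky^2, kx^2, "+") * correlationLengthPx^2 / 2)
    sm <- Re(fft(fft(wn) * G, inverse = TRUE)) / length(wn)
    sm <- (sm - mean(sm)) / sd(sm)
    pmin(pmax(127.5 + 30 * sm, 0), 255)
  })
}

#' Write a generated foam to disk
#'
#' Writes the rendered image (PNG or TIFF by extension), the ground-truth
#' cell table as CSV and the generator parameters as a JSON sidecar.
#'
#' @param foam result of [generateFoam()].
#' @param params the [FoamParams-class] used.
#' @param imagePath output image path (.png or .tif).
#' @return invisibly, the image path.
#' @export
writeFoam <- function(foam, params, imagePath) {
  EBImage::writeImage(EBImage::Image(aperm(foam$rgb / 255, c(2L, 1L, 3L)),
                                     colormode = "Color"), imagePath)
  base <- tools::file_path_sans_ext(imagePath)
  write.csv(cellTable(foam$truth), paste0(base, "_truth.csv"),
            row.names = FALSE)
  p <- attributes(params)[slotNames("FoamParams")]
  jsonlite::write_json(p, paste0(base, "_params.json"), auto_unbox = TRUE)
  invisible(imagePath)
}
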