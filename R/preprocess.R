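## Tissue masking and sliding-window enumeration.

#' Otsu threshold of an 8-bit histogram
#'
#' Exhaustive maximization of the between-class variance over all 256
#' candidate levels. The threshold t splits levels into background [0, t-1]
#' and foreground [t, 255]; ties are broken toward the lowest t attaining the
#' maximal between-class variance.
#'
#' @param counts integer vector of length 256 (counts of levels 0..255).
#' @return the threshold level t (an integer in 1..255).
#' @examples
#' h <- tabulate(findInterval(c(rnorm(500, 60, 10), rnorm(500, 180, 10)),
#'                            0:255), nbins = 256)
#' otsuThreshold(h)
#' @export
otsuThreshold <- function(counts) {
  stopifnot(length(counts) == 256L, all(counts >= 0))
  n <- sum(counts)
  if (n == 0) stop("empty histogram")
  lev <- 0:255
  cumN <- cumsum(as.numeric(counts))
  cumS <- cumsum(as.numeric(counts) * lev)
  totS <- cumS[256L]
  ## for threshold t (1..255): class0 = levels < t, class1 = levels >= t
  n0 <- cumN[1:255]
  n1 <- n - n0
  s0 <- cumS[1:255]
  valid <- n0 > 0 & n1 > 0
  mu0 <- s0 / n0
  mu1 <- (totS - s0) / n1
  bcv <- ifelse(valid, n0 * n1 * (mu0 - mu1)^2, -Inf)
  if (!any(is.finite(bcv))) stop("degenerate histogram: single level")
  which.max(bcv)   # lowest t at the max (which.max returns first)
}

#' Compute the tissue mask and its 1024-divisible bounding box
#'
#' Converts RGB to HSV, applies an Otsu threshold to the 8-bit quantized
#' saturation channel (tissue = saturation at or above threshold), fits the
#' tight bounding box around the tissue and expands it rightward/downward to
#' the next multiples of 1024. The box may extend past the raster; windows
#' there are zero-padded downstream.
#'
#' @param x a [SlideImage-class] or an H x W x 3 array on the 0-255 scale.
#' @return A [TissueMask-class].
#' @examples
#' foam <- generateFoam(FoamParams(widthPx = 1100L, heightPx = 1100L,
#'                                 seed = 2L))
#' computeTissueMask(foam$rgb)
#' @export
computeTissueMask <- function(x) {
  rgb <- if (is(x, "SlideImage")) x@rgb else x
  stopifnot(length(dim(rgb)) == 3L, dim(rgb)[3L] == 3L)
  sat <- quantize8(saturationChannel(rgb))
  h <- tabulate(as.vector(sat) + 1L, nbins = 256L)
  thr <- tryCatch(otsuThreshold(h),
                  error = function(e) stop("blank slide: no tissue detected"))
  mask <- sat >= thr
  if (!any(mask)) stop("blank slide: no tissue detected")
  rows <- range(which(rowSums(mask) > 0))
  cols <- range(which(colSums(mask) > 0))
  w <- 1024L * as.integer(ceiling((cols[2L] - cols[1L] + 1L) / 1024))
  h2 <- 1024L * as.integer(ceiling((rows[2L] - rows[1L] + 1L) / 1024))
  new("TissueMask", mask = mask,
      bbox = c(x0 = as.integer(cols[1L]), y0 = as.integer(rows[1L]),
               width = w, height = h2))
}

#' Enumerate sliding windows over a bounding box
#'
#' Row-major enumeration starting at the bounding-box top-left corner:
#' 1024 x 1024 windows advanced in 256 px x-steps until the window's right
#' edge meets the box's right edge, then the y coordinate advances by 256 px.
#'
#' @param mask a [TissueMask-class] (or an integer bbox vector
#'   \code{(x0, y0, width, height)}).
#' @return A [WindowGrid-class].
#' @examples
#' enumerateWindows(c(1L, 1L, 2048L, 1024L))   # 5 windows
#' @export
enumerateWindows <- function(mask) {
  bbox <- if (is(mask, "TissueMask")) mask@bbox else as.integer(mask)
  stopifnot(length(bbox) == 4L)
  if (bbox[3L] < 1024L || bbox[4L] < 1024L)
    stop("bounding box smaller than 1024 px in at least one dimension")
  xs <- seq.int(bbox[1L], bbox[1L] + bbox[3L] - 1024L, by = 256L)
  ys <- seq.int(bbox[2L], bbox[2L] + bbox[4L] - 1024L, by = 256L)
  coords <- cbind(x = rep(xs, times = length(ys)),
                  y = rep(ys, each = length(xs)))
  new("WindowGrid", coords = coords, windowSize = 1024L, stride = 256L)
}

#' Extract a window from a slide, zero-padding beyond the raster
#'
#' @param rgb H x W x 3 array (0-255 scale).
#' @param x,y 1-based top-left corner of the window.
#' @param size window side length.
#' @return a size x size x 3 array.
#' @export
extractWindow <- function(rgb, x, y, size = 1024L) {
  d <- dim(rgb)
  out <- array(0, dim = c(size, size, 3L))
  ys <- y:(y + size - 1L); xs <- x:(x + size - 1L)
  okY <- ys >= 1L & ys <= d[1L]; okX <- xs >= 1L & xs <= d[2L]
  if (any(okY) && any(okX))
    out[which(okY), which(okX), ] <- rgb[ys[okY], xs[okX], , drop = FALSE]
  out
}

#' Read a slide image with metadata into a SlideImage
#'
#' Reads TIFF or PNG via EBImage and scales intensities to 0-255.
#'
#' @param path image file path.
#' @param pixelSizeUm microns per pixel.
#' @param donorId,group,depot,diabetic donor metadata.
#' @return A [SlideImage-class].
#' @export
readSlideImage <- function(path, pixelSizeUm = 0.41, donorId = "donor",
                           group = "VR", depot = "PVAT", diabetic = NA) {
  img <- EBImage::readImage(path)
  a <- EBImage::imageData(img)
  if (length(dim(a)) == 2L) a <- array(rep(a, 3L), dim = c(dim(a), 3L))
  if (dim(a)[3L] > 3L) a <- a[, , 1:3]
  rgb <- aperm(a, c(2L, 1L, 3L)) * 255   # EBImage stores x,y; we use row=y
  SlideImage(rgb, pixelSizeUm, donorId, group, depot, diabetic)
}
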