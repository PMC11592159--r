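## Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded package internals never
#' disturb the caller's RNG stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return value of `expr`.
#' @keywords internal
#' @noRd
withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

## Mirror (symmetric, edge-including) padding of a matrix, possibly
## asymmetric. Each pad must be <= the corresponding dimension.
mirrorPad <- function(m, p, pBottom = p, pRight = p) {
  nr <- nrow(m); nc <- ncol(m)
  stopifnot(p <= nr, p <= nc, pBottom <= nr, pRight <= nc)
  ridx <- c(rev(seq_len(p)), seq_len(nr), nr + 1L - seq_len(pBottom))
  cidx <- c(rev(seq_len(p)), seq_len(nc), nc + 1L - seq_len(pRight))
  m[ridx, cidx]
}

## Mirror-pad img by at least p on every side, growing the bottom/right
## pads so the padded size is FFT-friendly (factors 2, 3, 5 only). Returns
## the padded matrix plus the top/left pad (for cropping back).
padForFFT <- function(img, p) {
  nr <- nextFastSize(nrow(img) + 2L * p)
  nc <- nextFastSize(ncol(img) + 2L * p)
  list(z = mirrorPad(img, p, pBottom = nr - nrow(img) - p,
                     pRight = nc - ncol(img) - p),
       p = p)
}

## Rec. 709 luma of an H x W x 3 array (any intensity scale).
luminance <- function(rgb) {
  stopifnot(length(dim(rgb)) == 3L, dim(rgb)[3L] == 3L)
  0.2126 * rgb[, , 1L] + 0.7152 * rgb[, , 2L] + 0.0722 * rgb[, , 3L]
}

## Saturation channel (hexcone HSV, S in [0,1]) of an 8-bit H x W x 3 array.
saturationChannel <- function(rgb) {
  stopifnot(length(dim(rgb)) == 3L, dim(rgb)[3L] == 3L)
  d <- dim(rgb)
  m <- rbind(as.vector(rgb[, , 1L]), as.vector(rgb[, , 2L]),
             as.vector(rgb[, , 3L]))
  s <- grDevices::rgb2hsv(m, maxColorValue = 255)[2L, ]
  matrix(s, d[1L], d[2L])
}

## Smallest integer >= n whose prime factors are all in {2, 3, 5}; keeps
## FFT sizes fast.
nextFastSize <- function(n) {
  n <- as.integer(n)
  repeat {
    m <- n
    for (p in c(2L, 3L, 5L)) while (m %% p == 0L) m <- m %/% p
    if (m == 1L) return(n)
    n <- n + 1L
  }
}

## Quantize a [0,1] channel to 8-bit levels 0..255.
quantize8 <- function(x) {
  q <- as.integer(round(pmin(pmax(x, 0), 1) * 255))
  dim(q) <- dim(x)
  q
}
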