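## Multiscale anisotropy via the 2D wavelet transform modulus maxima (WTMM).
##
## The analyzing wavelets are the first partial derivatives of the unit
## (normalized) 2D Gaussian g(x) = (1/2pi) exp(-|x|^2/2):
##   T_i(b, a) = (1/a^2) \int f(x) psi_i((x - b)/a) d^2x,
## computed by FFT convolution with mirror padding. (T1, T2) equals a times
## the gradient of the Gaussian-smoothed image at smoothing scale a. Modulus
## maxima are pixels whose modulus exceeds the bilinearly interpolated
## modulus one pixel away along +/- the gradient direction. The anisotropy
## factor at a scale is the normalized entropy deficit of the distribution
## of maxima orientations (folded to [0, pi)).

## Fourier-domain multipliers of the two wavelet filters at scale a for a
## padded N x M grid; returns H1 + 1i*H2 so that one inverse FFT yields
## T1 (real part) and T2 (imaginary part).
cwtMultiplier <- function(nr, nc, scale) {
  ky <- 2 * pi * c(0:floor((nr - 1) / 2), -(ceiling((nr - 1) / 2):1)) / nr
  kx <- 2 * pi * c(0:floor((nc - 1) / 2), -(ceiling((nc - 1) / 2):1)) / nc
  KY <- matrix(ky, nr, nc)
  KX <- matrix(kx, nr, nc, byrow = TRUE)
  E <- exp(-scale^2 * (KX^2 + KY^2) / 2)
  ## H1 = -i a kx E ; H2 = -i a ky E ; return H1 + i H2
  scale * E * (KY - 1i * KX)
}

#' Gaussian-derivative continuous wavelet transform at one scale
#'
#' @param img grayscale matrix (rows = y).
#' @param scale wavelet scale a in pixels; the patch must be at least 4a on
#'   each side.
#' @return list with matrices \code{T1} (x-derivative component) and
#'   \code{T2} (y-derivative component), same size as \code{img}.
#' @examples
#' r <- cwtGradient(outer(1:64, 1:64, function(y, x) 0.5 * x), 4)
#' mean(r$T1[20:44, 20:44])   # ~ -0.5 * 4
#' @export
cwtGradient <- function(img, scale) {
  stopifnot(is.matrix(img), scale > 0)
  if (min(dim(img)) < 4 * scale)
    stop("scale too large for patch: need >= 4 * scale pixels per side")
  p <- min(ceiling(3 * scale), dim(img))
  pad <- padForFFT(img, p)
  nr <- nrow(pad$z); nc <- ncol(pad$z)
  Tc <- fft(fft(pad$z) * cwtMultiplier(nr, nc, scale), inverse = TRUE) /
    (nr * nc)
  rows <- p + seq_len(nrow(img)); cols <- p + seq_len(ncol(img))
  list(T1 = Re(Tc)[rows, cols], T2 = Im(Tc)[rows, cols])
}

## Catmull-Rom bicubic sample of matrix M at fractional (row, col)
## positions, with clamped borders. Bicubic rather than bilinear sampling
## in the non-maximum suppression: bilinear attenuates the modulus more
## along diagonal than axis directions, which visibly skews the retained
## orientation distribution on isotropic fields.
bicubicAt <- function(M, row, col) {
  nr <- nrow(M); nc <- ncol(M)
  row <- pmin(pmax(row, 1), nr); col <- pmin(pmax(col, 1), nc)
  r0 <- pmin(pmax(floor(row), 1L), nr - 1L)
  c0 <- pmin(pmax(floor(col), 1L), nc - 1L)
  fr <- row - r0; fc <- col - c0
  w <- function(t) list((-t^3 + 2 * t^2 - t) / 2,
                        (3 * t^3 - 5 * t^2 + 2) / 2,
                        (-3 * t^3 + 4 * t^2 + t) / 2,
                        (t^3 - t^2) / 2)
  wr <- w(fr); wc <- w(fc)
  ri <- list(pmax(r0 - 1L, 1L), r0, r0 + 1L, pmin(r0 + 2L, nr))
  ci <- list(pmax(c0 - 1L, 1L), c0, c0 + 1L, pmin(c0 + 2L, nc))
  out <- 0
  for (i in 1:4) for (j in 1:4)
    out <- out + wr[[i]] * wc[[j]] * M[cbind(ri[[i]], ci[[j]])]
  out
}

#' Detect wavelet transform modulus maxima
#'
#' A pixel is a WTMM point iff its modulus \code{sqrt(T1^2 + T2^2)} strictly
#' exceeds the bilinearly interpolated modulus one pixel away along both
#' +/- the gradient direction, and is at least \code{relThreshold} times the
#' maximal modulus. Points within \code{scale} pixels of the patch border
#' are discarded; orientations are folded to [0, pi).
#'
#' @param T1,T2 coefficient fields from [cwtGradient()] at one scale.
#' @param scale the scale the fields were computed at (border exclusion).
#' @param relThreshold modulus floor relative to the field maximum.
#' @return data.frame with columns \code{x, y, modulus, argument}.
#' @export
findWtmm <- function(T1, T2, scale, relThreshold = 1e-6) {
  M <- sqrt(T1^2 + T2^2)
  mx <- max(M)
  ## fields with no structure beyond floating-point noise are constant
  if (mx <= 1e-12) return(data.frame(x = integer(), y = integer(),
                                     modulus = numeric(),
                                     argument = numeric()))
  A <- atan2(T2, T1)
  nr <- nrow(M); nc <- ncol(M)
  b <- as.integer(ceiling(scale))
  if (nr - 2L * b < 1L || nc - 2L * b < 1L)
    return(data.frame(x = integer(), y = integer(),
                      modulus = numeric(), argument = numeric()))
  rows <- (b + 1L):(nr - b); cols <- (b + 1L):(nc - b)
  ri <- rep(rows, times = length(cols))
  ci <- rep(cols, each = length(rows))
  a <- A[cbind(ri, ci)]
  m <- M[cbind(ri, ci)]
  dx <- cos(a); dy <- sin(a)
  mPlus <- bicubicAt(M, ri + dy, ci + dx)
  mMinus <- bicubicAt(M, ri - dy, ci - dx)
  keep <- m > mPlus & m > mMinus & m >= relThreshold * mx
  data.frame(x = ci[keep], y = ri[keep], modulus = m[keep],
             argument = a[keep] %% pi)
}

#' Anisotropy factor of an orientation sample
#'
#' Orientations (folded to [0, pi)) are histogrammed into \code{nBins} equal
#' bins; with bin probabilities p_i and Shannon entropy
#' \code{H = -sum(p_i log p_i)} the factor is \code{F = 1 - H / log(nBins)}:
#' 0 for an isotropic (uniform) distribution, 1 for perfect alignment. A
#' Miller-Madow correction (\code{(B_occupied - 1) / (2 n)} added to H)
#' removes the small-sample bias of plug-in entropy; F is clamped to [0, 1].
#' Fewer than \code{nMin} orientations yield \code{NA}.
#'
#' @param arguments numeric vector of orientations in [0, pi).
#' @param nBins number of histogram bins.
#' @param nMin minimal sample size for a defined factor.
#' @param biasCorrect apply the Miller-Madow correction (default TRUE).
#' @return the anisotropy factor in [0, 1], or \code{NA}.
#' @examples
#' anisotropyFactor(rep(1, 100))            # 1: perfectly aligned
#' anisotropyFactor(runif(5000, 0, pi))     # ~0: isotropic
#' @export
anisotropyFactor <- function(arguments, nBins = 90L, nMin = 50L,
                             biasCorrect = TRUE) {
  n <- length(arguments)
  if (n < nMin) return(NA_real_)
  bins <- pmin(floor((arguments %% pi) / pi * nBins), nBins - 1L)
  cnt <- tabulate(bins + 1L, nbins = nBins)
  p <- cnt / n
  H <- -sum(p[p > 0] * log(p[p > 0]))
  if (biasCorrect) H <- H + (sum(cnt > 0) - 1) / (2 * n)
  min(max(1 - H / log(nBins), 0), 1)
}

#' Anisotropy factor across a multiscale grid
#'
#' Computes the WTMM orientation distribution and its anisotropy factor at
#' every scale of the grid. Scales are grouped by padded FFT size so the
#' forward transform of the patch is reused.
#'
#' @param patch 2D grayscale matrix or H x W x 3 RGB array (0-255); RGB is
#'   reduced to Rec. 709 luminance.
#' @param grid a [ScaleGrid-class].
#' @param nBins,nMin,biasCorrect passed to [anisotropyFactor()].
#' @param source identifier stored in the result.
#' @return An [AnisotropySpectrum-class].
#' @export
anisotropySpectrum <- function(patch, grid = scaleGrid(), nBins = 90L,
                               nMin = 50L, biasCorrect = TRUE,
                               source = "patch") {
  img <- if (length(dim(patch)) == 3L) luminance(patch) else patch
  stopifnot(is.matrix(img))
  scales <- grid@scalesPx
  if (min(dim(img)) < 4 * max(scales))
    stop("patch too small for the largest scale of the grid")
  Fv <- rep(NA_real_, length(scales))
  nm <- integer(length(scales))
  ## bucket scales by identical padded size; one forward FFT per bucket
  pads <- pmin(ceiling(3 * scales), min(dim(img)))
  sizes <- paste(vapply(as.integer(nrow(img) + 2 * pads), nextFastSize, 1L),
                 vapply(as.integer(ncol(img) + 2 * pads), nextFastSize, 1L))
  for (sz in unique(sizes)) {
    sel <- which(sizes == sz)
    p <- max(pads[sel])
    pad <- padForFFT(img, p)
    nr <- nrow(pad$z); nc <- ncol(pad$z)
    Fhat <- fft(pad$z)
    rows <- p + seq_len(nrow(img)); cols <- p + seq_len(ncol(img))
    for (i in sel) {
      Tc <- fft(Fhat * cwtMultiplier(nr, nc, scales[i]), inverse = TRUE) /
        (nr * nc)
      w <- findWtmm(Re(Tc)[rows, cols], Im(Tc)[rows, cols], scales[i])
      nm[i] <- nrow(w)
      Fv[i] <- anisotropyFactor(w$argument, nBins, nMin, biasCorrect)
    }
  }
  new("AnisotropySpectrum", scalesPx = scales, F = Fv, nMaxima = nm,
      pixelSizeUm = grid@pixelSizeUm, source = source)
}

#' Average patch spectra into a donor spectrum
#'
#' The donor-level spectrum is the arithmetic mean of its patch spectra at
#' each scale (NA scales ignored per scale; all-NA stays NA).
#'
#' @param spectra list of [AnisotropySpectrum-class] on one grid.
#' @param source identifier for the averaged spectrum.
#' @return An [AnisotropySpectrum-class].
#' @export
meanSpectrum <- function(spectra, source = "donor") {
  stopifnot(length(spectra) >= 1L)
  sc <- spectra[[1L]]@scalesPx
  for (s in spectra)
    if (!isTRUE(all.equal(s@scalesPx, sc))) stop("scale grid mismatch")
  Fm <- do.call(rbind, lapply(spectra, anisotropyF))
  Fv <- colMeans(Fm, na.rm = TRUE)
  Fv[is.nan(Fv)] <- NA_real_
  new("AnisotropySpectrum", scalesPx = sc, F = Fv,
      nMaxima = as.integer(round(colMeans(
        do.call(rbind, lapply(spectra, nMaxima))))),
      pixelSizeUm = spectra[[1L]]@pixelSizeUm, source = source)
}

#' Per-scale normalized difference of two mean spectra
#'
#' \code{(F_subq - F_pvat) / (F_subq + F_pvat)} at every scale, with 0 where
#' both factors are 0. The two spectra must share one scale grid.
#'
#' @param pvat,subq numeric vectors or [AnisotropySpectrum-class] objects
#'   (mean spectra of the PVAT and SubQ depots, or any two groups).
#' @return numeric vector in [-1, 1] per scale.
#' @examples
#' normalizedDifference(c(0.2, 0.3), c(0.6, 0.3))   # 0.5, 0
#' @export
normalizedDifference <- function(pvat, subq) {
  if (is(pvat, "AnisotropySpectrum") && is(subq, "AnisotropySpectrum")) {
    if (!isTRUE(all.equal(pvat@scalesPx, subq@scalesPx)))
      stop("scale grid mismatch")
    pvat <- anisotropyF(pvat); subq <- anisotropyF(subq)
  }
  if (length(pvat) != length(subq)) stop("scale grid mismatch")
  s <- pvat + subq
  out <- ifelse(s == 0, 0, (subq - pvat) / s)
  out
}
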