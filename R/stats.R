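## Nonparametric group comparisons.

#' Two-sided Wilcoxon rank-sum test
#'
#' Exact p by full enumeration of rank assignments (average ranks under
#' ties; two-sided as the permutation probability of a rank sum at least as
#' far from its null mean as observed) when the pooled size is at most 12;
#' otherwise the normal approximation with tie and continuity corrections.
#' Identical pooled samples give p = 1.
#'
#' @param x,y numeric samples (each nonempty).
#' @return the two-sided p-value.
#' @examples
#' wilcoxonRankSum(c(1, 2), c(3, 4))   # exact: 1/3
#' @export
wilcoxonRankSum <- function(x, y) {
  stopifnot(length(x) >= 1L, length(y) >= 1L)
  pool <- c(x, y)
  if (length(unique(pool)) == 1L) return(1)
  nx <- length(x); N <- length(pool)
  if (N <= 12L) {
    r <- rank(pool)
    wObs <- sum(r[seq_len(nx)])
    mu <- nx * (N + 1) / 2
    splits <- combn(N, nx)
    ws <- colSums(matrix(r[splits], nrow = nx))
    mean(abs(ws - mu) >= abs(wObs - mu) - 1e-9)
  } else {
    stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value
  }
}

#' Per-scale two-group comparison of anisotropy spectra
#'
#' An unpaired two-sided Wilcoxon rank-sum test at every wavelet scale, with
#' no multiple-testing correction by default (each scale is tested at its
#' own alpha); contiguous runs of significant scales are reported as
#' [min um, max um] intervals. The unit of analysis is the donor (one
#' patch-mean spectrum per donor).
#'
#' @param groupA,groupB donor spectra: matrices (donors x scales) or lists
#'   of [AnisotropySpectrum-class] objects on one grid.
#' @param grid the [ScaleGrid-class] the spectra live on (taken from the
#'   spectra when lists are given).
#' @param alpha per-scale significance level.
#' @param adjust \code{"none"} (default, as published) or \code{"BH"}.
#' @return A [ScaleComparison-class].
#' @export
perScaleComparison <- function(groupA, groupB, grid = NULL, alpha = 0.05,
                               adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  asMat <- function(g) {
    if (is.list(g) && all(vapply(g, is, TRUE, "AnisotropySpectrum"))) {
      if (is.null(grid))
        grid <<- new("ScaleGrid", scalesPx = g[[1L]]@scalesPx,
                     pixelSizeUm = g[[1L]]@pixelSizeUm)
      do.call(rbind, lapply(g, anisotropyF))
    } else as.matrix(g)
  }
  A <- asMat(groupA); B <- asMat(groupB)
  if (nrow(A) < 2L || nrow(B) < 2L)
    stop("need at least 2 donors per group")
  if (ncol(A) != ncol(B)) stop("scale grid mismatch")
  if (is.null(grid))
    grid <- new("ScaleGrid", scalesPx = seq_len(ncol(A)), pixelSizeUm = 1)
  if (length(grid@scalesPx) != ncol(A)) stop("scale grid mismatch")
  p <- vapply(seq_len(ncol(A)), function(i) {
    a <- A[!is.na(A[, i]), i]; b <- B[!is.na(B[, i]), i]
    if (length(a) < 2L || length(b) < 2L) return(NA_real_)
    wilcoxonRankSum(a, b)
  }, numeric(1L))
  pUse <- if (adjust == "BH") stats::p.adjust(p, "BH") else p
  sig <- !is.na(pUse) & pUse < alpha
  um <- scalesUm(grid)
  rl <- rle(sig)
  ends <- cumsum(rl$lengths)
  starts <- ends - rl$lengths + 1L
  runs <- which(rl$values)
  ranges <- data.frame(min_um = um[starts[runs]], max_um = um[ends[runs]])
  new("ScaleComparison", scalesPx = grid@scalesPx, scalesUmVec = um,
      pValues = p, alpha = alpha, significant = sig, ranges = ranges)
}

#' Pearson chi-squared test of a 2x2 table
#'
#' Pearson's chi-squared without continuity correction, df = 1, upper-tail
#' p. This is the test that reproduces the published diabetes-incidence
#' comparison from its printed counts. All margins must be positive.
#'
#' @param a,b,c,d the 2x2 cell counts (row-wise: a b / c d).
#' @return list with \code{statistic} and \code{p}.
#' @examples
#' chiSquared2x2(1, 15, 14, 24)   # p ~ 0.022
#' @export
chiSquared2x2 <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be nonnegative integers")
  m <- matrix(counts, 2L, 2L, byrow = TRUE)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    stop("zero margin in 2x2 table")
  ct <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  list(statistic = unname(ct$statistic), p = unname(ct$p.value))
}
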