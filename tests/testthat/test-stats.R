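test_that("the exact Wilcoxon branch matches enumeration and references", {
  ## worked example: x = {1,2}, y = {3,4} -> two-sided p = 1/3
  expect_equal(wilcoxonRankSum(c(1, 2), c(3, 4)), 1 / 3)
  ## identical pooled samples -> p = 1
  expect_equal(wilcoxonRankSum(c(2, 2, 2), c(2, 2)), 1)
  expect_equal(wilcoxonRankSum(c(1, 5), c(1, 5)), 1)
  ## against base wilcox.test exact p on tie-free samples, all n_x, n_y <= 5
  set.seed(11)
  for (i in 1:40) {
    nx <- sample(2:5, 1); ny <- sample(2:5, 1)
    x <- sample(seq_len(50), nx); y <- sample(setdiff(seq_len(50), x), ny)
    expect_equal(wilcoxonRankSum(x, y),
                 stats::wilcox.test(x, y, exact = TRUE)$p.value,
                 tolerance = 1e-12)
  }
  ## with ties, against a brute-force permutation oracle
  bruteP <- function(x, y) {
    pool <- c(x, y); r <- rank(pool); nx <- length(x)
    mu <- nx * (length(pool) + 1) / 2
    wObs <- sum(r[seq_len(nx)])
    ws <- combn(length(pool), nx, function(s) sum(r[s]))
    mean(abs(ws - mu) >= abs(wObs - mu) - 1e-9)
  }
  set.seed(12)
  for (i in 1:20) {
    x <- sample(1:4, sample(2:5, 1), replace = TRUE)
    y <- sample(1:4, sample(2:5, 1), replace = TRUE)
    expect_equal(wilcoxonRankSum(x, y), bruteP(x, y))
  }
})

test_that("exact and normal-approximation branches agree for n = 6 + 6", {
  set.seed(21)
  for (i in 1:25) {
    x <- rnorm(6); y <- rnorm(6)
    pExact <- wilcoxonRankSum(x, y)   # 12 <= 12: exact branch
    pApprox <- stats::wilcox.test(x, y, exact = FALSE,
                                  correct = TRUE)$p.value
    expect_lt(abs(pExact - pApprox), 0.02)
  }
})

test_that("per-scale comparison finds shifted scales and only those", {
  set.seed(31)
  nd <- 10L; ns <- 30L
  A <- matrix(rnorm(nd * ns, sd = 0.05), nd, ns)
  B <- matrix(rnorm(nd * ns, sd = 0.05), nd, ns)
  B[, 10:20] <- B[, 10:20] + 0.2
  grid <- new("ScaleGrid", scalesPx = seq_len(ns), pixelSizeUm = 1)
  cmp <- perScaleComparison(A, B, grid, alpha = 0.05)
  expect_true(all(cmp@significant[10:20]))
  ## off-shift scales are mostly null
  expect_lt(mean(cmp@significant[-(10:20)]), 0.25)
  ## contiguous ranges cover the shifted block
  rg <- significantRanges(cmp)
  expect_true(any(rg$min_um <= 10 & rg$max_um >= 20))
  ## single-scale grid degenerates to one test
  cmp1 <- perScaleComparison(A[, 1, drop = FALSE], B[, 1, drop = FALSE],
                             new("ScaleGrid", scalesPx = 5,
                                 pixelSizeUm = 1))
  expect_equal(length(pValues(cmp1)), 1L)
  expect_equal(pValues(cmp1), wilcoxonRankSum(A[, 1], B[, 1]))
  expect_error(perScaleComparison(A[1, , drop = FALSE], B, grid), "donors")
})

test_that("null per-scale type-I error matches the attainable level", {
  ## with n = 10 + 10 the approximate branch rejects iff |W - 105| >= 27;
  ## the exact null probability of that event is the oracle rate
  rate0 <- 2 * stats::pwilcox(78 - 55, 10, 10)
  set.seed(41)
  reps <- 200L; ns <- 25L
  hits <- 0L; total <- 0L
  for (r in seq_len(reps)) {
    A <- matrix(rnorm(10 * ns), 10, ns)
    B <- matrix(rnorm(10 * ns), 10, ns)
    for (s in seq_len(ns)) {
      hits <- hits + (wilcoxonRankSum(A[, s], B[, s]) < 0.05)
      total <- total + 1L
    }
  }
  rate <- hits / total
  se <- sqrt(rate0 * (1 - rate0) / total)
  expect_lt(abs(rate - rate0), 4 * se)
  ## and the attainable level is itself close to the nominal alpha
  expect_lt(abs(rate0 - 0.05), 0.02)
})

test_that("BH adjustment is available but off by default", {
  set.seed(51)
  A <- matrix(rnorm(200), 10, 20); B <- matrix(rnorm(200), 10, 20)
  raw <- perScaleComparison(A, B, alpha = 0.5)
  adj <- perScaleComparison(A, B, alpha = 0.5, adjust = "BH")
  expect_equal(pValues(raw), pValues(adj))   # reported p stays raw
  expect_lte(sum(adj@significant), sum(raw@significant))
})

test_that("the published diabetes table reproduces p ~ 0.022", {
  res <- chiSquared2x2(1, 15, 14, 24)
  expect_equal(round(res$p, 3), 0.022)
  ## independent oracle: closed-form Pearson statistic + chi-squared tail
  n <- 54; stat <- n * (1 * 24 - 15 * 14)^2 / (16 * 38 * 15 * 39)
  expect_equal(res$statistic, stat, tolerance = 1e-12)
  expect_equal(res$p, stats::pchisq(stat, 1, lower.tail = FALSE),
               tolerance = 1e-12)
})

test_that("chi-squared handles degenerate and symmetric tables", {
  flat <- chiSquared2x2(10, 10, 10, 10)
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p, 1)
  diagt <- chiSquared2x2(5, 0, 0, 5)
  expect_equal(diagt$statistic, 10)
  expect_equal(diagt$p, stats::pchisq(10, 1, lower.tail = FALSE),
               tolerance = 1e-9)   # ~0.00157
  ## transpose invariance
  a <- chiSquared2x2(3, 8, 12, 5); b <- chiSquared2x2(3, 12, 8, 5)
  expect_equal(a$statistic, b$statistic)
  expect_error(chiSquared2x2(0, 0, 3, 4), "margin")
  expect_error(chiSquared2x2(-1, 2, 3, 4), "nonnegative")
})
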