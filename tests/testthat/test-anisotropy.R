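test_that("the wavelet gradient vanishes on constant patches", {
  r <- cwtGradient(matrix(5, 64, 64), 4)
  expect_lt(max(abs(r$T1)), 1e-10)
  expect_lt(max(abs(r$T2)), 1e-10)
  expect_error(cwtGradient(matrix(0, 64, 64), 20), "scale too large")
})

test_that("a linear ramp gives the closed-form response -c*a", {
  for (a in c(3, 5, 8)) {
    cc <- 0.7
    img <- matrix(rep(cc * seq_len(96), each = 96), 96)
    r <- cwtGradient(img, a)
    ctr <- 40:56
    expect_lt(max(abs(r$T1[ctr, ctr] - (-cc * a))) / (cc * a), 0.01)
    expect_lt(max(abs(r$T2[ctr, ctr])) / (cc * a), 0.01)
  }
})

test_that("the FFT path agrees with direct spatial quadrature", {
  set.seed(4)
  img <- generateIsotropicField(96, 96, 5, seed = 21L)
  for (a in c(4, 8)) {
    r <- cwtGradient(img, a)
    for (b in list(c(48, 48), c(40, 60))) {
      q <- cwtQuadratureAt(img, a, b[1L], b[2L])
      scaleRef <- max(abs(c(r$T1, r$T2)))
      expect_lt(abs(r$T1[b[2L], b[1L]] - q["T1"]) / scaleRef, 0.01)
      expect_lt(abs(r$T2[b[2L], b[1L]] - q["T2"]) / scaleRef, 0.01)
    }
  }
})

test_that("rotating the patch 90 degrees rotates the gradient field", {
  img <- generateIsotropicField(80, 80, 4, seed = 13L)
  a <- 5
  r <- cwtGradient(img, a)
  rot <- t(img)[ncol(img):1, ]   # rotate the raster by 90 degrees
  rr <- cwtGradient(rot, a)
  ## the modulus is rotation-invariant; the argument shifts by pi/2
  M <- sqrt(r$T1^2 + r$T2^2)
  Mr <- sqrt(rr$T1^2 + rr$T2^2)
  MrBack <- t(Mr)[, nrow(Mr):1]   # undo the rotation
  ctr <- 25:56
  expect_lt(max(abs(MrBack[ctr, ctr] - M[ctr, ctr])) / max(M), 1e-6)
  A <- atan2(r$T2, r$T1)[ctr, ctr]
  Ar <- atan2(rr$T2, rr$T1)
  ArBack <- t(Ar)[, nrow(Ar):1][ctr, ctr]
  strong <- M[ctr, ctr] > 0.2 * max(M)
  dAng <- abs(((ArBack - A + pi / 2) + pi / 2) %% pi - pi / 2)
  expect_lt(max(dAng[strong]), 1e-6)
})

test_that("modulus maxima of a grating align with its wave vector", {
  th <- pi / 5
  g <- generateOrientedTexture(256, 256, 24, th, 1)
  r <- cwtGradient(g, 4)
  w <- findWtmm(r$T1, r$T2, 4)
  expect_gt(nrow(w), 100)
  ## folded arguments within 5 degrees of the grating orientation; points
  ## near the border carry mirror-seam distortion (the reflected wave
  ## rotates the local gradient), so exact alignment is asserted beyond
  ## 3 scales from the border and a high fraction overall
  d <- abs(w$argument - th)
  d <- pmin(d, pi - d)
  interior <- w$x > 12 & w$x <= 244 & w$y > 12 & w$y <= 244
  expect_lt(max(d[interior]), 5 * pi / 180)
  expect_gt(mean(d < 5 * pi / 180), 0.9)
  ## constant field: no maxima at all
  rc <- cwtGradient(matrix(1, 128, 128), 4)
  expect_equal(nrow(findWtmm(rc$T1, rc$T2, 4)), 0L)
})

test_that("isotropic fields give uniform maxima orientations", {
  ## chi-squared uniformity over pooled seeds at alpha = 0.01
  args <- unlist(lapply(1:20, function(s) {
    img <- generateIsotropicField(128, 128, 3, seed = 300L + s)
    r <- cwtGradient(img, 3)
    findWtmm(r$T1, r$T2, 3)$argument
  }))
  expect_gt(length(args), 2000)
  cnt <- tabulate(pmin(floor(args / pi * 18), 17) + 1L, nbins = 18L)
  p <- stats::chisq.test(cnt)$p.value
  expect_gt(p, 0.01)
})

test_that("the anisotropy factor has its closed-form fixed points", {
  expect_equal(anisotropyFactor(rep(0.3, 200)), 1)
  ## exactly uniform over the 90 bins -> 0 (clamped)
  u <- rep((seq_len(90) - 0.5) * pi / 90, each = 10)
  expect_equal(anisotropyFactor(u), 0)
  ## equal split between two bins -> 1 - ln2/ln90
  two <- rep(c(0.5, 2.5) * pi / 90, each = 500)
  expect_equal(anisotropyFactor(two), 1 - log(2) / log(90),
               tolerance = 2e-3)
  ## below the minimal sample size -> NA
  expect_true(is.na(anisotropyFactor(rep(1, 49))))
  expect_false(is.na(anisotropyFactor(rep(1, 50))))
})

test_that("F is invariant under affine intensity rescaling", {
  img <- generateIsotropicField(192, 192, 4, seed = 17L)
  grid <- scaleGrid(nScales = 4L, minScalePx = 3, maxScalePx = 12)
  f1 <- anisotropyF(anisotropySpectrum(img, grid))
  f2 <- anisotropyF(anisotropySpectrum(3.7 * img + 40, grid))
  expect_equal(f1, f2, tolerance = 1e-6)
})

test_that("F is invariant under 90-degree patch rotation", {
  foam <- generateFoam(FoamParams(widthPx = 512L, heightPx = 512L,
                                  stretchFactor = 1.8,
                                  stretchAngleRad = pi / 6, seed = 19L))
  img <- adipoaniso:::luminance(foam$rgb)
  grid <- scaleGrid(nScales = 5L, minScalePx = 4, maxScalePx = 24)
  f1 <- anisotropyF(anisotropySpectrum(img, grid))
  f2 <- anisotropyF(anisotropySpectrum(t(img)[ncol(img):1, ], grid))
  expect_lt(max(abs(f1 - f2), na.rm = TRUE), 0.02)
})

test_that("gratings score high and isotropic fields low", {
  g <- generateOrientedTexture(512, 512, 24, pi / 3, 1)
  grid <- scaleGrid(nScales = 8L, minScalePx = 3, maxScalePx = 24)
  fg <- anisotropyF(anisotropySpectrum(g, grid))
  expect_gt(max(fg, na.rm = TRUE), 0.5)
  iso <- generateIsotropicField(512, 512, 8, seed = 23L)
  fi <- anisotropyF(anisotropySpectrum(iso, grid))
  expect_lt(max(fi, na.rm = TRUE), 0.1)
})

test_that("mean isotropic F stays near zero well above the corr. length", {
  ## Monte-Carlo over seeds; scales 16-48 px >> correlation length 3 px
  grid <- scaleGrid(nScales = 3L, minScalePx = 16, maxScalePx = 48)
  fs <- vapply(1:8, function(s) {
    iso <- generateIsotropicField(384, 384, 3, seed = 700L + s)
    mean(anisotropyF(anisotropySpectrum(iso, grid)), na.rm = TRUE)
  }, numeric(1L))
  expect_lt(mean(fs), 0.05)
})

test_that("foam stretch raises F at membrane and cell scales", {
  grid <- scaleGrid(nScales = 5L, minScalePx = 6, maxScalePx = 40)
  meanF <- vapply(c(1, 2), function(s) {
    foam <- generateFoam(FoamParams(widthPx = 1024L, heightPx = 1024L,
                                    stretchFactor = s,
                                    stretchAngleRad = pi / 4, seed = 31L))
    mean(anisotropyF(anisotropySpectrum(foam$rgb, grid)), na.rm = TRUE)
  }, numeric(1L))
  expect_gt(meanF[2L], meanF[1L])
})

test_that("donor spectra average patch spectra and NA propagates", {
  g <- new("ScaleGrid", scalesPx = c(2, 4, 8), pixelSizeUm = 0.5)
  s1 <- new("AnisotropySpectrum", scalesPx = g@scalesPx,
            F = c(0.2, NA, 0.4), nMaxima = c(100L, 10L, 100L),
            pixelSizeUm = 0.5, source = "p1")
  s2 <- new("AnisotropySpectrum", scalesPx = g@scalesPx,
            F = c(0.4, NA, 0.8), nMaxima = c(100L, 10L, 100L),
            pixelSizeUm = 0.5, source = "p2")
  m <- meanSpectrum(list(s1, s2))
  expect_equal(anisotropyF(m), c(0.3, NA, 0.6))
  expect_equal(scalesUm(m), c(1, 2, 4))
})

test_that("normalized difference matches its arithmetic definition", {
  expect_equal(normalizedDifference(c(0.2, 0.3, 0), c(0.6, 0.3, 0)),
               c(0.5, 0, 0))
  set.seed(2)
  a <- runif(50); b <- runif(50)
  nd <- normalizedDifference(a, b)
  expect_true(all(nd >= -1 & nd <= 1))
  expect_error(normalizedDifference(c(0.1, 0.2), c(0.1, 0.2, 0.3)),
               "mismatch")
})
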