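test_that("triangle threshold lands between peak and tail on skewed data", {
  ## skewed unimodal: tall narrow peak with a long flat tail
  h <- integer(256)
  h[6:10] <- c(2000L, 40000L, 400000L, 60000L, 8000L)
  h[11:150] <- 3000L
  thr <- triangleThreshold(h)
  expect_true(thr > 9 && thr < 60)
  ## flat tail removed -> threshold hugs the peak
  h2 <- integer(256); h2[6:10] <- h[6:10]
  expect_lt(triangleThreshold(h2), 12)
  expect_error(triangleThreshold(integer(256)), "empty")
})

test_that("foam windows segment into the true cells with high IoU", {
  lab <- defaultFoamLabels()
  ious <- iouByCell(lab, defaultFoam()$truth)
  expect_gt(mean(ious >= 0.7), 0.8)
})

test_that("an unstained window yields no (or one border-removed) object", {
  white <- array(250, dim = c(512, 512, 3))
  lab <- segmentWindow(white)
  expect_lte(length(setdiff(unique(as.vector(lab)), 0L)), 1L)
})

test_that("watershed splits two cells merged through a membrane gap", {
  ## two discs fused through a narrow neck; distance peaks are distinct
  m <- matrix(FALSE, 300, 300)
  m <- m | outer(1:300, 1:300, function(y, x) (x - 100)^2 + (y - 150)^2 <= 45^2)
  m <- m | outer(1:300, 1:300, function(y, x) (x - 200)^2 + (y - 150)^2 <= 45^2)
  m[146:154, 100:200] <- TRUE   # broken-membrane bridge
  rgb <- array(0, dim = c(300, 300, 3))
  for (ch in 1:3) rgb[, , ch] <- ifelse(m, c(248, 246, 248)[ch],
                                        c(235, 120, 170)[ch])
  lab <- segmentWindow(rgb)
  expect_equal(length(setdiff(unique(as.vector(lab)), 0L)), 2L)
})

test_that("size filter boundaries are strict at 1600 and 9000 px^2", {
  masks <- list(rectMask(40L, 40L, minus = 1L),   # 1599
                rectMask(40L, 40L),               # 1600
                rectMask(90L, 100L),              # 9000
                rectMask(90L, 100L, minus = -0L)) # placeholder
  masks[[4L]] <- {
    m <- matrix(TRUE, 91L, 100L); m[91L, 2:100] <- FALSE; m  # 9001
  }
  lab <- masksToLabels(masks, size = 1024L, gap = 30L)
  kept <- filterObjects(lab)$label
  expect_false(1L %in% kept)   # 1599 removed
  expect_true(2L %in% kept)    # 1600 retained
  expect_true(3L %in% kept)    # 9000 retained
  expect_false(4L %in% kept)   # 9001 removed
})

test_that("perimeter/area removal boundary sits at the 0.14 ratio", {
  ## sweep rectangle families whose measured ratio straddles 0.14
  widths <- 11:16
  ms <- lapply(widths, function(w) rectMask(w, 300L))
  lab <- masksToLabels(ms, size = 1024L, gap = 25L)
  meas <- measureLabeled(lab)
  ratio <- meas$perimeter / meas$area
  kept <- filterObjects(lab)$label
  inBand <- meas$area >= 1600 & meas$area <= 9000
  expect_true(any(ratio[inBand] < 0.14) && any(ratio[inBand] >= 0.14))
  for (i in meas$label[inBand])
    expect_equal(i %in% kept, ratio[meas$label == i] < 0.14)
})

test_that("the big-area/high-eccentricity rule fires as published", {
  round_obj <- measureObject(diskMask(95L))     # ~28000 px^2, ecc ~ 0
  thin_obj <- measureObject(rectMask(60L, 500L))  # 30000 px^2, ecc > 0.87
  expect_gt(round_obj$area, 25000)
  expect_lt(round_obj$eccentricity, 0.87)
  expect_gt(thin_obj$area, 25000)
  expect_gt(thin_obj$eccentricity, 0.87)
  expect_false(isBigEccentric(round_obj$area, round_obj$eccentricity))
  expect_true(isBigEccentric(thin_obj$area, thin_obj$eccentricity))
  ## boundary strictness: > on both components
  expect_false(isBigEccentric(25000, 0.95))
  expect_false(isBigEccentric(26000, 0.87))
  expect_true(isBigEccentric(25001, 0.871))
  ## under defaults the area cap subsumes it: nothing retained can trigger
  expect_false(any(isBigEccentric(seq(1600, 9000, by = 100), 0.999)))
})

test_that("window acceptance flips exactly at 30% coverage", {
  sz <- 1024L
  expect_true(acceptWindow(data.frame(area = 0.31 * sz^2))$accept)
  expect_false(acceptWindow(data.frame(area = 0.29 * sz^2))$accept)
  expect_true(acceptWindow(data.frame(area = 0.30 * sz^2))$accept)  # >= rule
  expect_false(acceptWindow(data.frame(area = 0.30 * sz^2 - 1))$accept)
  empty <- acceptWindow(data.frame(area = numeric()))
  expect_false(empty$accept); expect_equal(empty$coverage, 0)
})

test_that("centroid deduplication respects the 31 px radius exactly", {
  rec <- function(...) data.frame(cx = c(...)[c(TRUE, FALSE)],
                                  cy = c(...)[c(FALSE, TRUE)])
  expect_equal(nrow(deduplicateCentroids(rec(0, 0, 30, 0), seed = 1L)), 1L)
  expect_equal(nrow(deduplicateCentroids(rec(0, 0, 31, 0), seed = 1L)), 1L)
  expect_equal(nrow(deduplicateCentroids(rec(0, 0, 32, 0), seed = 1L)), 2L)
  ## transitive chain: 3 records pairwise within 31 -> 1 survivor, seeded
  tri <- rec(0, 0, 20, 0, 10, 17)
  s1 <- deduplicateCentroids(tri, seed = 5L)
  s2 <- deduplicateCentroids(tri, seed = 5L)
  expect_equal(nrow(s1), 1L)
  expect_identical(s1, s2)
  ## chain where the ends are > 31 apart still collapses to one
  chain <- rec(0, 0, 25, 0, 50, 0)
  expect_equal(nrow(deduplicateCentroids(chain, seed = 2L)), 1L)
})

test_that("deduplicated sets have nearest-neighbor distance > 31 px", {
  set.seed(8)
  rec <- data.frame(cx = runif(400, 0, 600), cy = runif(400, 0, 600))
  out <- deduplicateCentroids(rec, radius = 31, seed = 3L)
  d <- as.matrix(dist(out[, c("cx", "cy")]))
  diag(d) <- Inf
  expect_gt(min(d), 31)
})

test_that("patch selection is greedy with a strict 20% overlap cut", {
  ## offset 256: overlap 0.75 -> second rejected
  expect_equal(selectPatches(data.frame(x = c(1, 257), y = 1)),
               c(TRUE, FALSE))
  ## offset 1024: no overlap -> both kept
  expect_equal(selectPatches(data.frame(x = c(1, 1025), y = 1)),
               c(TRUE, TRUE))
  ## offset 896: overlap 0.125 -> both kept
  expect_equal(selectPatches(data.frame(x = c(1, 897), y = 1)),
               c(TRUE, TRUE))
  ## overlap just above 20% is not "minimal (<20%)": rejected
  expect_equal(selectPatches(data.frame(x = c(0, 819), y = 0)),
               c(TRUE, FALSE))   # overlap 205/1024 ~ 0.2002
  expect_equal(selectPatches(data.frame(x = c(0, 820), y = 0)),
               c(TRUE, TRUE))    # overlap 204/1024 ~ 0.1992
  ## greedy order dependence: window overlapping the first saved patch is
  ## skipped even if a later one would have allowed it
  expect_equal(selectPatches(data.frame(x = c(1, 513, 1025), y = 1)),
               c(TRUE, FALSE, TRUE))
})

test_that("every emitted record satisfies the filter constraints", {
  lab <- defaultFoamLabels()
  cfg <- FilterConfig()
  obj <- filterObjects(lab, cfg)
  expect_gt(nrow(obj), 20)
  expect_true(all(obj$area >= cfg@minAreaPx2 & obj$area <= cfg@maxAreaPx2))
  expect_true(all(obj$perimeter / obj$area < cfg@maxPerimeterAreaRatio))
  expect_true(all(obj$short_axis <= obj$long_axis + 1e-9))
  expect_true(all(obj$eccentricity >= 0 & obj$eccentricity < 1))
  expect_true(all(obj$solidity > 0 & obj$solidity <= 1))
})
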