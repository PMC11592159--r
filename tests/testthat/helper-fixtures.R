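## Shared fixtures, generated in code and cached per session.

fixtureCache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = fixtureCache))
    assign(key, force(expr), envir = fixtureCache)
  get(key, envir = fixtureCache)
}

## The default-condition foam slide used across segmentation/morphometry
## tests: 1024 x 1024, mean cell area 4000 px^2, cv 0.2, membrane 4 px.
defaultFoam <- function() cached("foam1024", {
  generateFoam(FoamParams(widthPx = 1024L, heightPx = 1024L, seed = 11L))
})

defaultFoamLabels <- function() cached("foamLab", {
  segmentWindow(defaultFoam()$rgb)
})

## Rasterize a digitized disk of radius r (pixel centers).
diskMask <- function(r, pad = 3L) {
  n <- 2L * (r + pad) + 1L
  ctr <- r + pad + 1L
  outer(seq_len(n), seq_len(n),
        function(y, x) (x - ctr)^2 + (y - ctr)^2 <= r^2)
}

## Put a list of binary masks into one labeled raster, side by side.
masksToLabels <- function(masks, size = 1024L, gap = 20L) {
  lab <- matrix(0L, size, size)
  x <- gap; y <- gap
  rowH <- 0L
  for (i in seq_along(masks)) {
    m <- masks[[i]]
    if (x + ncol(m) >= size) { x <- gap; y <- y + rowH + gap; rowH <- 0L }
    stopifnot(y + nrow(m) < size)
    sub <- lab[y + seq_len(nrow(m)), x + seq_len(ncol(m))]
    sub[m > 0] <- i
    lab[y + seq_len(nrow(m)), x + seq_len(ncol(m))] <- sub
    x <- x + ncol(m) + gap
    rowH <- max(rowH, nrow(m))
  }
  lab
}

## A rectangle mask of exactly a x b pixels, optionally with px pixels
## removed from a corner (to hit exact areas).
rectMask <- function(a, b, minus = 0L) {
  m <- matrix(TRUE, a, b)
  if (minus > 0L) m[1L, seq_len(minus)] <- FALSE
  m
}

## Match segmentation labels to ground-truth cells by IoU.
iouByCell <- function(lab, truth) {
  lm <- labelMap(truth)
  ct <- cellTable(truth)
  interior <- ct$cell_id[!ct$touches_border]
  vapply(interior, function(cid) {
    px <- which(lm == cid)
    cand <- lab[px]
    cand <- cand[cand > 0L]
    if (!length(cand)) return(0)
    best <- as.integer(names(which.max(table(cand))))
    inter <- sum(lab[px] == best)
    inter / (length(px) + sum(lab == best) - inter)
  }, numeric(1L))
}

## Direct spatial-domain evaluation of the wavelet integral at one point:
## T_i(b) = (1/a^2) sum_x f(x) psi_i((x - b)/a), psi = grad of the unit
## 2D Gaussian. Independent of the FFT path.
cwtQuadratureAt <- function(img, a, bx, by) {
  x <- matrix(rep(seq_len(ncol(img)), each = nrow(img)), nrow(img))
  y <- matrix(rep(seq_len(nrow(img)), times = ncol(img)), nrow(img))
  ux <- (x - bx) / a; uy <- (y - by) / a
  g <- exp(-(ux^2 + uy^2) / 2) / (2 * pi)
  psi1 <- -ux * g; psi2 <- -uy * g
  c(T1 = sum(img * psi1) / a^2, T2 = sum(img * psi2) / a^2)
}

## Build a tiny two-group study (isotropic vs stretched foam donors) as
## slide images; used by pipeline tests.
makeStudySlides <- function(nPerGroup = 3L, seedBase = 100L) {
  slides <- list()
  for (i in seq_len(nPerGroup)) {
    iso <- generateFoam(FoamParams(widthPx = 1024L, heightPx = 1024L,
                                   seed = seedBase + i))
    str <- generateFoam(FoamParams(widthPx = 1024L, heightPx = 1024L,
                                   stretchFactor = 2, stretchAngleRad = pi / 4,
                                   seed = seedBase + 50L + i))
    slides[[paste0("D", i, "_SubQ")]] <-
      SlideImage(iso$rgb, donorId = paste0("D", i), depot = "SubQ")
    slides[[paste0("D", i, "_PVAT")]] <-
      SlideImage(str$rgb, donorId = paste0("D", i), depot = "PVAT")
  }
  slides
}
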