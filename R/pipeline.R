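## End-to-end orchestration: mask -> windows -> segment -> filter -> accept
## -> records/patches -> dedup -> morphometrics -> anisotropy -> stats.

#' Pipeline configuration
#'
#' A flat, yaml-serializable list of every tunable of the pipeline. The
#' defaults are the published values (see [FilterConfig()] and
#' [scaleGrid()]).
#'
#' @param pixelSizeUm microns per pixel.
#' @param alpha per-scale significance level.
#' @param seed integer seed for the (single) stochastic stage, the
#'   deduplication survivor draw.
#' @param nScales,minScalePx,maxScalePx the wavelet scale grid.
#' @param contrast which metadata column defines the two compared groups
#'   (\code{"depot"} compares PVAT vs SubQ within each surgical group).
#' @param ... overrides for any [FilterConfig()] slot.
#' @return a named list of class \code{adipoPipelineConfig}.
#' @examples
#' cfg <- pipelineConfig(pixelSizeUm = 0.5)
#' @export
pipelineConfig <- function(pixelSizeUm = 0.41, alpha = 0.05, seed = 1L,
                           nScales = 50L, minScalePx = 3, maxScalePx = 160,
                           contrast = "depot", ...) {
  fc <- FilterConfig(...)
  cfg <- list(pixelSizeUm = pixelSizeUm, alpha = alpha,
              seed = as.integer(seed),
              nScales = as.integer(nScales), minScalePx = minScalePx,
              maxScalePx = maxScalePx, contrast = contrast,
              minAreaPx2 = fc@minAreaPx2, maxAreaPx2 = fc@maxAreaPx2,
              bigAreaPx2 = fc@bigAreaPx2,
              maxEccentricityBig = fc@maxEccentricityBig,
              maxPerimeterAreaRatio = fc@maxPerimeterAreaRatio,
              minCoverageFraction = fc@minCoverageFraction,
              dedupRadiusPx = fc@dedupRadiusPx,
              maxPatchOverlapFraction = fc@maxPatchOverlapFraction,
              blurPx = fc@blurPx)
  class(cfg) <- "adipoPipelineConfig"
  cfg
}

#' @rdname pipelineConfig
#' @param path yaml file path.
#' @export
readPipelineConfig <- function(path) {
  v <- yaml::read_yaml(path)
  do.call(pipelineConfig, v)
}

#' @rdname pipelineConfig
#' @param config a pipeline configuration.
#' @export
writePipelineConfig <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

configFilter <- function(cfg) {
  FilterConfig(minAreaPx2 = cfg$minAreaPx2, maxAreaPx2 = cfg$maxAreaPx2,
               bigAreaPx2 = cfg$bigAreaPx2,
               maxEccentricityBig = cfg$maxEccentricityBig,
               maxPerimeterAreaRatio = cfg$maxPerimeterAreaRatio,
               minCoverageFraction = cfg$minCoverageFraction,
               dedupRadiusPx = cfg$dedupRadiusPx,
               maxPatchOverlapFraction = cfg$maxPatchOverlapFraction,
               blurPx = cfg$blurPx)
}

configGrid <- function(cfg) {
  scaleGrid(nScales = cfg$nScales, minScalePx = cfg$minScalePx,
            maxScalePx = cfg$maxScalePx, pixelSizeUm = cfg$pixelSizeUm)
}

#' Analyze one slide: segmentation, morphometrics and anisotropy patches
#'
#' Runs the full single-slide chain on an in-memory [SlideImage-class]:
#' tissue mask, sliding windows, per-window segmentation and filters, window
#' acceptance, centroid deduplication, micron conversion, donor summary and
#' anisotropy spectra of the saved low-overlap patches.
#'
#' @param slide a [SlideImage-class].
#' @param config a [pipelineConfig()] list.
#' @param slideSeed seed for the dedup survivor draw.
#' @return list with \code{records} (deduplicated adipocyte table),
#'   \code{summary} (one-row donor summary), \code{spectra} (list of patch
#'   [AnisotropySpectrum-class]), \code{meanSpectrum}, \code{patchOrigins},
#'   and \code{nWindows}, \code{nAccepted} bookkeeping.
#' @export
analyzeSlide <- function(slide, config = pipelineConfig(),
                         slideSeed = config$seed) {
  fc <- configFilter(config)
  grid <- configGrid(config)
  tm <- computeTissueMask(slide)
  wg <- enumerateWindows(tm)
  co <- windowCoords(wg)
  recs <- list(); acc <- list()
  for (i in seq_len(nrow(co))) {
    win <- extractWindow(slide@rgb, co[i, 1L], co[i, 2L], wg@windowSize)
    lab <- segmentWindow(win, fc)
    obj <- filterObjects(lab, fc)
    aw <- acceptWindow(obj, fc, wg@windowSize)
    if (!aw$accept) next
    obj$window_x <- co[i, 1L]; obj$window_y <- co[i, 2L]
    obj$cx <- obj$cx + co[i, 1L] - 1L
    obj$cy <- obj$cy + co[i, 2L] - 1L
    recs[[length(recs) + 1L]] <- obj
    acc[[length(acc) + 1L]] <- data.frame(x = co[i, 1L], y = co[i, 2L],
                                          coverage = aw$coverage)
  }
  records <- if (length(recs)) do.call(rbind, recs) else
    measureLabeled(matrix(0L, 1L, 1L))
  accepted <- if (length(acc)) do.call(rbind, acc) else
    data.frame(x = integer(), y = integer(), coverage = numeric())
  if (nrow(records))
    records <- deduplicateCentroids(records, fc@dedupRadiusPx, slideSeed)
  records <- toMicrons(records, config$pixelSizeUm)
  if (nrow(records)) {
    records$donor_id <- slide@donorId
    records$group <- slide@group
    records$depot <- slide@depot
  }

  ## tissue area = mask area within accepted windows (um^2)
  cover <- matrix(FALSE, nrow(tm@mask), ncol(tm@mask))
  for (k in seq_len(nrow(accepted))) {
    ys <- accepted$y[k]:min(accepted$y[k] + wg@windowSize - 1L, nrow(cover))
    xs <- accepted$x[k]:min(accepted$x[k] + wg@windowSize - 1L, ncol(cover))
    cover[ys, xs] <- TRUE
  }
  tissueAreaUm2 <- sum(tm@mask & cover) * config$pixelSizeUm^2

  summary <- if (nrow(records) && tissueAreaUm2 > 0)
    donorSummary(records, tissueAreaUm2, slide@donorId, slide@group,
                 slide@depot, slide@diabetic) else NULL

  sel <- selectPatches(accepted, wg@windowSize, fc@maxPatchOverlapFraction)
  origins <- accepted[sel, , drop = FALSE]
  spectra <- lapply(seq_len(nrow(origins)), function(k) {
    win <- extractWindow(slide@rgb, origins$x[k], origins$y[k],
                         wg@windowSize)
    anisotropySpectrum(win, grid,
                       source = sprintf("%s_%s_patch_%d_%d", slide@donorId,
                                        slide@depot, origins$x[k],
                                        origins$y[k]))
  })
  ms <- if (length(spectra))
    meanSpectrum(spectra, source = paste(slide@donorId, slide@depot,
                                         sep = "_")) else NULL
  list(records = records, summary = summary, spectra = spectra,
       meanSpectrum = ms, patchOrigins = origins,
       nWindows = nrow(co), nAccepted = nrow(accepted))
}

#' Run the full pipeline over a metadata table
#'
#' @param metadata data.frame or CSV path with columns
#'   \code{donor_id, group, depot, diabetic, path, pixel_size_um}
#'   (pixel_size_um optional; falls back to the config value). Each row is
#'   one slide.
#' @param outDir output directory (created if needed).
#' @param config a [pipelineConfig()] list.
#' @param seed overrides \code{config$seed} when given.
#' @return invisibly, a list with the per-donor records, summaries, donor
#'   mean spectra, comparisons and the names of skipped slides. Writes
#'   \code{adipocytes.csv} (published column set),
#'   \code{adipocytes_extended.csv}, \code{donor_summary.csv},
#'   \code{anisotropy.csv}, per-stratum \code{comparison_*.csv},
#'   \code{significant_ranges.json} and \code{manifest.json} to
#'   \code{outDir}.
#' @export
runPipeline <- function(metadata, outDir, config = pipelineConfig(),
                        seed = NULL) {
  if (is.character(metadata)) metadata <- read.csv(metadata)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  need <- c("donor_id", "group", "depot", "path")
  if (!all(need %in% names(metadata)))
    stop("metadata must have columns ", paste(need, collapse = ", "))

  allRecords <- list(); summaries <- list(); meanSpectra <- list()
  skipped <- character()
  for (i in seq_len(nrow(metadata))) {
    row <- metadata[i, ]
    res <- tryCatch({
      psz <- if (!is.null(row$pixel_size_um) && !is.na(row$pixel_size_um))
        row$pixel_size_um else config$pixelSizeUm
      slide <- readSlideImage(row$path, psz, row$donor_id, row$group,
                              row$depot,
                              if (!is.null(row$diabetic)) row$diabetic
                              else NA)
      cfg <- config; cfg$pixelSizeUm <- psz
      analyzeSlide(slide, cfg, slideSeed = config$seed + i)
    }, error = function(e) {
      message(sprintf("skipping slide %s (%s): %s", row$donor_id,
                      row$path, conditionMessage(e)))
      NULL
    })
    if (is.null(res)) { skipped <- c(skipped, as.character(row$path)); next }
    allRecords[[length(allRecords) + 1L]] <- res$records
    if (!is.null(res$summary))
      summaries[[length(summaries) + 1L]] <- res$summary
    if (!is.null(res$meanSpectrum)) {
      key <- paste(row$donor_id, row$group, row$depot, sep = "|")
      meanSpectra[[key]] <- res$meanSpectrum
    }
  }
  records <- if (length(allRecords)) do.call(rbind, allRecords) else NULL
  summary <- if (length(summaries)) do.call(rbind, summaries) else NULL

  ## outputs
  if (!is.null(records) && nrow(records)) {
    paper <- data.frame(x_centroid = records$cx, y_centroid = records$cy,
                        eccentricity = records$eccentricity,
                        area = records$area, perimeter = records$perimeter,
                        long_axis = records$long_axis,
                        short_axis = records$short_axis)
    write.csv(paper, file.path(outDir, "adipocytes.csv"), row.names = FALSE)
    write.csv(records, file.path(outDir, "adipocytes_extended.csv"),
              row.names = FALSE)
  }
  if (!is.null(summary))
    write.csv(summary, file.path(outDir, "donor_summary.csv"),
              row.names = FALSE)
  if (length(meanSpectra)) {
    an <- do.call(rbind, lapply(meanSpectra, function(s)
      data.frame(source = s@source, scale_px = s@scalesPx,
                 scale_um = scalesUm(s), F = s@F, n_maxima = s@nMaxima)))
    write.csv(an, file.path(outDir, "anisotropy.csv"), row.names = FALSE)
  }

  ## stats stage: compare the two levels of `contrast`, stratified by the
  ## other grouping column
  comparisons <- list()
  if (length(meanSpectra)) {
    meta <- do.call(rbind, lapply(names(meanSpectra), function(k) {
      p <- strsplit(k, "|", fixed = TRUE)[[1L]]
      data.frame(key = k, donor_id = p[1L], group = p[2L], depot = p[3L])
    }))
    cvar <- config$contrast
    svar <- if (cvar == "depot") "group" else "depot"
    for (st in unique(meta[[svar]])) {
      sub <- meta[meta[[svar]] == st, ]
      lv <- sort(unique(sub[[cvar]]))
      if (length(lv) != 2L) next
      ga <- meanSpectra[sub$key[sub[[cvar]] == lv[1L]]]
      gb <- meanSpectra[sub$key[sub[[cvar]] == lv[2L]]]
      if (length(ga) < 2L || length(gb) < 2L) {
        warning("fewer than 2 donors per group in stratum ", st,
                "; comparison skipped", call. = FALSE)
        next
      }
      cmp <- perScaleComparison(unname(ga), unname(gb),
                                alpha = config$alpha)
      comparisons[[paste(st, lv[1L], "vs", lv[2L], sep = "_")]] <- cmp
    }
    for (nm in names(comparisons)) {
      cmp <- comparisons[[nm]]
      write.csv(data.frame(scale_um = scalesUm(cmp), p = pValues(cmp),
                           significant = cmp@significant),
                file.path(outDir, paste0("comparison_", nm, ".csv")),
                row.names = FALSE)
    }
    jsonlite::write_json(
      lapply(comparisons, function(cmp) significantRanges(cmp)),
      file.path(outDir, "significant_ranges.json"), digits = NA)
  }

  csvs <- list.files(outDir, pattern = "\\.csv$", full.names = TRUE)
  manifest <- list(
    package = "adipoaniso",
    version = as.character(packageVersion("adipoaniso")),
    seed = config$seed, config = unclass(config),
    skipped = skipped,
    outputs = as.list(tools::md5sum(csvs)))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(records = records, summary = summary,
                 meanSpectra = meanSpectra, comparisons = comparisons,
                 skipped = skipped, outDir = outDir))
}

#' Re-run the comparison stage from saved CSV outputs
#'
#' Re-entrant stats stage: reads an \code{anisotropy.csv} written by
#' [runPipeline()] (donor mean spectra) plus a metadata table and recomputes
#' the per-scale comparison for one stratum.
#'
#' @param anisoCsv path to \code{anisotropy.csv}.
#' @param sourcesA,sourcesB the \code{source} identifiers of the donors in
#'   each group.
#' @param alpha per-scale significance level.
#' @return A [ScaleComparison-class].
#' @export
compareAnisotropyCsv <- function(anisoCsv, sourcesA, sourcesB,
                                 alpha = 0.05) {
  an <- read.csv(anisoCsv)
  toMat <- function(src) do.call(rbind, lapply(src, function(s) {
    sub <- an[an$source == s, ]
    sub$F[order(sub$scale_px)]
  }))
  sc <- sort(unique(an$scale_px))
  px <- sort(unique(an$scale_um / an$scale_px))[1L]
  grid <- new("ScaleGrid", scalesPx = sc, pixelSizeUm = px)
  perScaleComparison(toMat(sourcesA), toMat(sourcesB), grid, alpha)
}
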