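# File I/O, pipeline configuration, the end-to-end pipeline, and output
# tables/overlays.

#' Pipeline configuration
#'
#' Collects every tunable of the analysis pipeline with its module-level
#' default. Serializes to YAML (\code{\link{writeConfig}} /
#' \code{\link{readConfig}}) and round-trips identically.
#'
#' @param input path to the input sequence (multi-page TIFF or frame
#'   directory), or "" when the sequence is passed in memory.
#' @param outputDir directory for output tables.
#' @param pixelSizeUm,frameIntervalH imaging geometry.
#' @param kernelRadiusPx,haloSigmaPx,interiorSigmaPx,haloK,haloBoost,thresholdMethod,threshold,minAreaPx,thresholdFloor,splitTouching,splitTolerance
#'   detection parameters (see \code{\link{detectCells}}).
#' @param gatePx,minFrames,maxStepPx tracking parameters (see
#'   \code{\link{linkObjects}}, \code{\link{classifyTracks}}).
#' @param minCells,colonyDiameterUm,mergeDistanceUm colony rule (see
#'   \code{\link{colonyConfig}}).
#' @param kGroups,durationDays growth-analysis parameters.
#' @param seed integer seed recorded in the run manifest.
#' @return named list of class "pipelineConfig".
#' @export
pipelineConfig <- function(input = "", outputDir = "colonytrack-out",
                           pixelSizeUm = 4, frameIntervalH = 6,
                           kernelRadiusPx = 25, haloSigmaPx = 2,
                           interiorSigmaPx = 2, haloK = 6, haloBoost = 1,
                           thresholdMethod = "otsu", threshold = NA,
                           minAreaPx = 20, thresholdFloor = 8,
                           splitTouching = TRUE, splitTolerance = 8,
                           gatePx = 10, minFrames = 3, maxStepPx = 10,
                           minCells = 4, colonyDiameterUm = 320,
                           mergeDistanceUm = 100,
                           kGroups = 7, durationDays = 14, seed = 1) {
  cfg <- list(input = input, outputDir = outputDir,
              pixelSizeUm = pixelSizeUm, frameIntervalH = frameIntervalH,
              kernelRadiusPx = kernelRadiusPx, haloSigmaPx = haloSigmaPx,
              interiorSigmaPx = interiorSigmaPx, haloK = haloK,
              haloBoost = haloBoost, thresholdMethod = thresholdMethod,
              threshold = threshold, minAreaPx = minAreaPx,
              thresholdFloor = thresholdFloor,
              splitTouching = splitTouching, splitTolerance = splitTolerance,
              gatePx = gatePx,
              minFrames = minFrames, maxStepPx = maxStepPx,
              minCells = minCells, colonyDiameterUm = colonyDiameterUm,
              mergeDistanceUm = mergeDistanceUm, kGroups = kGroups,
              durationDays = durationDays, seed = seed)
  class(cfg) <- c("pipelineConfig", "list")
  cfg
}

#' Write a pipeline configuration as YAML
#'
#' @param config a \code{\link{pipelineConfig}}.
#' @param path output file path.
#' @export
writeConfig <- function(config, path) {
  yaml::write_yaml(unclass(config), path, precision = 15)
  invisible(path)
}

#' Read a pipeline configuration from YAML
#'
#' Unknown keys are rejected; missing keys take their defaults.
#'
#' @param path YAML file written by \code{\link{writeConfig}} or by hand.
#' @return a \code{\link{pipelineConfig}}.
#' @export
readConfig <- function(path) {
  vals <- yaml::read_yaml(path)
  defaults <- pipelineConfig()
  unknown <- setdiff(names(vals), names(defaults))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  defaults[names(vals)] <- vals
  defaults$threshold <- if (is.null(vals$threshold)) NA else vals$threshold
  class(defaults) <- c("pipelineConfig", "list")
  defaults
}

readOneFrame <- function(path) {
  lower <- tolower(path)
  img <- if (grepl("\\.tiff?$", lower)) {
    tiff::readTIFF(path, as.is = TRUE)
  } else if (grepl("\\.png$", lower)) {
    round(png::readPNG(path) * 255)
  } else {
    stop("unsupported image format: ", path)
  }
  toGray(img, path)
}

toGray <- function(img, what) {
  if (length(dim(img)) == 3) {
    warning("RGB input ", what, " converted to grayscale by channel mean")
    img <- apply(img[, , 1:min(3, dim(img)[3]), drop = FALSE], c(1, 2), mean)
  }
  if (length(dim(img)) != 2) stop("cannot interpret image ", what)
  img
}

#' Read a time-lapse sequence from disk
#'
#' Accepts a multi-page TIFF, a single-image file, or a directory of
#' per-frame TIFF/PNG files taken in lexical filename order. 16-bit TIFF
#' gray levels are preserved as stored; 8-bit PNG is scaled to 0..255.
#' RGB frames are converted to grayscale by channel mean with a warning.
#'
#' @param path file or directory.
#' @param pixelSizeUm micrometres per pixel (metadata is never trusted for
#'   physical scale).
#' @param frameIntervalH hours between frames.
#' @return an \linkS4class{ImageSequence}.
#' @export
readSequence <- function(path, pixelSizeUm = 4, frameIntervalH = 6) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.(tiff?|png)$",
                             ignore.case = TRUE, full.names = TRUE))
    if (!length(files)) stop("no TIFF/PNG frames found in ", path)
    frames <- lapply(files, readOneFrame)
  } else if (file.exists(path)) {
    if (grepl("\\.tiff?$", tolower(path))) {
      pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
      if (!is.list(pages)) pages <- list(pages)
      frames <- lapply(seq_along(pages), function(i)
        toGray(pages[[i]], sprintf("%s page %d", path, i)))
      files <- rep(path, length(frames))
    } else {
      frames <- list(readOneFrame(path))
      files <- path
    }
  } else {
    stop("input not found: ", path)
  }
  dims <- vapply(frames, dim, integer(2))
  bad <- which(dims[1, ] != dims[1, 1] | dims[2, ] != dims[2, 1])
  if (length(bad))
    stop("frame dimensions differ from the first frame: ",
         paste(basename(files[bad]), collapse = ", "))
  ImageSequence(frames, pixelSizeUm = pixelSizeUm,
                frameIntervalH = frameIntervalH)
}

#' Run the full analysis pipeline
#'
#' Detection, temporal tracking with persistence classification, colony
#' grouping/tracking, merge exclusion, growth curves, clustering, day-by-day
#' prediction, and end-of-culture morphometrics, in order. Stage timings and
#' counts are logged via \code{message()}.
#'
#' @param input an \linkS4class{ImageSequence} or a path readable by
#'   \code{\link{readSequence}}.
#' @param config a \code{\link{pipelineConfig}}.
#' @return list: sequence, detections, tracks, colonies, curves
#'   (a \linkS4class{GrowthCurveSet}, clustered when enough colonies),
#'   r2ByDay, morphometrics, config.
#' @export
runPipeline <- function(input, config = pipelineConfig()) {
  seqs <- if (is(input, "ImageSequence")) input else
    readSequence(input, config$pixelSizeUm, config$frameIntervalH)
  if (!length(seqs@frames)) stop("no frames in input sequence")

  nDays <- min(config$durationDays,
               floor(max(seqs@timestampsH) / 24))
  if (nDays < 1) stop("sequence shorter than one day of imaging")
  refFrames <- vapply(seq_len(nDays), function(d)
    dayReferenceFrame(d, config$frameIntervalH) - 1L, integer(1))

  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- force(expr)
    message(sprintf("[%s] %.1fs", name, proc.time()[["elapsed"]] - t0))
    res
  }

  detections <- stage("detect", detectCells(
    seqs, kernelRadiusPx = config$kernelRadiusPx,
    haloSigmaPx = config$haloSigmaPx,
    interiorSigmaPx = config$interiorSigmaPx, haloK = config$haloK,
    haloBoost = config$haloBoost, thresholdMethod = config$thresholdMethod,
    threshold = if (is.na(config$threshold)) NULL else config$threshold,
    minAreaPx = config$minAreaPx, thresholdFloor = config$thresholdFloor,
    splitTouching = config$splitTouching,
    splitTolerance = config$splitTolerance,
    keepPixelFrames = refFrames))
  message(sprintf("  %d objects in %d frames", nrow(detections@objects),
                  length(seqs@frames)))

  tracks <- stage("track", classifyTracks(
    linkObjects(detections, gatePx = config$gatePx),
    minFrames = config$minFrames, maxStepPx = config$maxStepPx))
  message(sprintf("  %d tracks, %d living", length(tracks@labels),
                  sum(tracks@labels == "living")))

  ccfg <- colonyConfig(config$minCells, config$colonyDiameterUm,
                       config$mergeDistanceUm)
  colonies <- stage("colonies", detectMerges(
    trackColonies(tracks, config$pixelSizeUm, ccfg)))
  message(sprintf("  %d colonies (%d confirmed, %d merged)",
                  nrow(colonies@colonies),
                  sum(!is.na(colonies@colonies$confirmedFrame)),
                  sum(colonies@colonies$merged)))

  curves <- stage("curves", buildGrowthCurves(
    colonies, durationDays = nDays, frameIntervalH = config$frameIntervalH))

  if (nrow(curves) >= config$kGroups && nrow(curves) >= 2) {
    curves <- clusterCurves(curves, kGroups = config$kGroups)
  } else if (nrow(curves) > 0) {
    warning("too few colonies (", nrow(curves), ") for kGroups = ",
            config$kGroups, "; clustering skipped")
  }

  r2 <- if (nrow(curves) >= 3 &&
            var(growthCounts(curves)[, ncol(curves)]) > 0)
    predictDay14(curves) else
      setNames(rep(NA_real_, nDays), paste0("day", seq_len(nDays)))

  morpho <- stage("morphometrics", colonyMorphometrics(
    colonies, detections, frame = refFrames[nDays]))

  list(sequence = seqs, detections = detections, tracks = tracks,
       colonies = colonies, curves = curves, r2ByDay = r2,
       morphometrics = morpho, config = config)
}

#' Write pipeline outputs
#'
#' Writes the CSV tables (per-frame objects, labelled tracks, colony table,
#' growth-curve matrix excluding merged colonies, cluster labels,
#' morphometrics, per-day R2) plus a JSON run manifest, and optionally PNG
#' overlays of the day reference frames with colony-coloured cells.
#'
#' @param results list from \code{\link{runPipeline}}.
#' @param dir output directory (created if needed); defaults to the
#'   configured one.
#' @param overlays write per-reference-frame PNG overlays.
#' @return invisibly, the vector of files written.
#' @export
writeOutputs <- function(results, dir = results$config$outputDir,
                         overlays = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(dir, 2) != 0) stop("output directory not writable: ", dir)
  wrt <- function(df, name) {
    p <- file.path(dir, name)
    write.csv(df, p, row.names = FALSE)
    p
  }
  files <- character(0)
  files <- c(files, wrt(results$detections@objects, "objects.csv"))

  obs <- results$tracks@observations
  obs$label <- as.character(results$tracks@labels[obs$track])
  files <- c(files, wrt(obs, "tracks.csv"))

  files <- c(files, wrt(results$colonies@colonies, "colonies.csv"))

  cm <- growthCounts(results$curves)
  rd <- SummarizedExperiment::rowData(results$curves)
  gdf <- data.frame(colonyId = rd$colonyId, cm, check.names = FALSE)
  files <- c(files, wrt(gdf, "growth_curves.csv"))

  if (!is.null(rd$cluster))
    files <- c(files, wrt(data.frame(colonyId = rd$colonyId,
                                     cluster = rd$cluster),
                          "cluster_labels.csv"))
  files <- c(files, wrt(results$morphometrics, "morphometrics.csv"))
  files <- c(files, wrt(data.frame(day = seq_along(results$r2ByDay),
                                   r2 = unname(results$r2ByDay)),
                        "r2_by_day.csv"))

  manifest <- list(
    config = unclass(results$config),
    package = list(name = "colonytrack",
                   version = as.character(utils::packageVersion("colonytrack")),
                   rVersion = paste(R.version$major, R.version$minor, sep = ".")),
    nFrames = length(results$sequence@frames),
    nObjects = nrow(results$detections@objects),
    nColonies = nrow(results$colonies@colonies))
  mp <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  files <- c(files, mp)

  if (overlays) files <- c(files, writeOverlays(results, dir))
  invisible(files)
}

# Stable colour per colony id (hash of the id, constant across frames).
colonyColor <- function(id) {
  hues <- ((id * 2654435761) %% 360) / 360
  grDevices::hsv(hues, 0.9, 1)
}

writeOverlays <- function(results, dir) {
  det <- results$detections
  cs <- results$colonies
  ps <- results$config$pixelSizeUm
  out <- character(0)
  for (f in det@pixelFrames) {
    key <- paste0("f", f)
    if (!key %in% names(det@pixelSets)) next
    frame <- results$sequence@frames[[f + 1L]]
    g <- pmin(pmax(frame / 255, 0), 1)
    rgb <- array(rep(g, 3), c(dim(g), 3))
    fc <- cs@cells[cs@cells$frame == f, , drop = FALSE]
    for (k in seq_len(nrow(fc))) {
      px <- det@pixelSets[[key]][[fc$obj[k]]]
      col <- grDevices::col2rgb(colonyColor(fc$colonyId[k])) / 255
      for (ch in 1:3) {
        idx <- cbind(px[, 1] + 1L, px[, 2] + 1L, ch)
        rgb[idx] <- 0.4 * rgb[idx] + 0.6 * col[ch]
      }
    }
    p <- file.path(dir, sprintf("overlay_frame%03d.png", f))
    png::writePNG(rgb, p)
    out <- c(out, p)
  }
  out
}
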