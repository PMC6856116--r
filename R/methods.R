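# Accessors and show methods.

#' @rdname ImageSequence
#' @export
setMethod("pixelSize", "ImageSequence", function(x) x@pixelSizeUm)

#' @rdname ImageSequence
#' @export
setMethod("frameInterval", "ImageSequence", function(x) x@frameIntervalH)

#' @rdname ImageSequence
#' @export
setMethod("timestamps", "ImageSequence", function(x) x@timestampsH)

#' @rdname ImageSequence
#' @param i frame number (1-based).
#' @export
setMethod("getFrame", "ImageSequence", function(x, i) x@frames[[i]])

#' @rdname ImageSequence
#' @export
setMethod("length", "ImageSequence", function(x) length(x@frames))

setMethod("show", "ImageSequence", function(object) {
  d <- if (length(object@frames)) dim(object@frames[[1]]) else c(0, 0)
  cat(sprintf(paste0("ImageSequence: %d frames of %dx%d px, %.3g um/px, ",
                     "every %g h (t = %g..%g h)\n"),
              length(object@frames), d[1], d[2], object@pixelSizeUm,
              object@frameIntervalH,
              if (length(object@timestampsH)) min(object@timestampsH) else NA,
              if (length(object@timestampsH)) max(object@timestampsH) else NA))
})

#' @rdname DetectionSet
#' @export
setMethod("detectedObjects", "DetectionSet", function(x) x@objects)

#' @rdname DetectionSet
#' @param frame 0-based frame index.
#' @export
setMethod("pixelSets", "DetectionSet", function(x, frame) {
  key <- paste0("f", frame)
  if (!key %in% names(x@pixelSets))
    stop("pixel sets for frame ", frame, " were not retained")
  x@pixelSets[[key]]
})

setMethod("show", "DetectionSet", function(object) {
  ob <- object@objects
  cat(sprintf("DetectionSet: %d objects over %d frames (%.3g um/px)\n",
              nrow(ob), length(unique(ob$frame)), object@pixelSizeUm))
})

#' @rdname CellTracks
#' @export
setMethod("trackLabels", "CellTracks", function(x) x@labels)

#' @rdname CellTracks
#' @export
setMethod("observations", "CellTracks", function(x) x@observations)

#' @rdname CellTracks
#' @export
setMethod("length", "CellTracks", function(x) length(x@labels))

setMethod("show", "CellTracks", function(object) {
  tab <- table(object@labels)
  cat(sprintf("CellTracks: %d tracks (%d living, %d noise, %d undecided)\n",
              length(object@labels), tab[["living"]], tab[["noise"]],
              tab[["undecided"]]))
})

#' @rdname ColonySet
#' @export
setMethod("colonyInfo", "ColonySet", function(x) x@colonies)

#' @rdname ColonySet
#' @param frame 0-based frame index.
#' @export
setMethod("colonyCells", "ColonySet", function(x, frame) {
  x@cells[x@cells$frame == frame, , drop = FALSE]
})

setMethod("show", "ColonySet", function(object) {
  co <- object@colonies
  cat(sprintf(paste0("ColonySet: %d colonies (%d confirmed, %d merged), ",
                     "rule: >=%d cells within %g um, merge below %g um\n"),
              nrow(co), sum(!is.na(co$confirmedFrame)), sum(co$merged),
              object@config$minCells, object@config$colonyDiameterUm,
              object@config$mergeDistanceUm))
})

setMethod("show", "SimTruth", function(object) {
  cat(sprintf(paste0("SimTruth: %d colonies, %d cells, %d debris/frame, ",
                     "%d days at %g-h frames\n"),
              nrow(object@colonies), nrow(object@cells),
              length(unique(object@debris$debrisId)),
              object@config@durationDays, object@config@frameIntervalH))
})

setMethod("show", "SimConfig", function(object) {
  cat(sprintf(paste0("SimConfig: %d colonies, %d days every %g h, %dx%d px ",
                     "at %g um/px, seed %d\n"),
              object@nColonies, object@durationDays, object@frameIntervalH,
              object@frameShape[1], object@frameShape[2], object@pixelSizeUm,
              object@seed))
  cat("  mix:", paste(sprintf("%s %.2f", names(object@groupMix),
                              object@groupMix), collapse = ", "), "\n")
})
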