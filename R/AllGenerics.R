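#' @rdname ImageSequence
#' @param x,object an object.
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))

#' @rdname ImageSequence
#' @export
setGeneric("frameInterval", function(x) standardGeneric("frameInterval"))

#' @rdname ImageSequence
#' @export
setGeneric("timestamps", function(x) standardGeneric("timestamps"))

#' @rdname ImageSequence
#' @export
setGeneric("getFrame", function(x, i) standardGeneric("getFrame"))

#' @rdname DetectionSet
#' @export
setGeneric("detectedObjects", function(x) standardGeneric("detectedObjects"))

#' @rdname DetectionSet
#' @export
setGeneric("pixelSets", function(x, frame) standardGeneric("pixelSets"))

#' @rdname CellTracks
#' @export
setGeneric("trackLabels", function(x) standardGeneric("trackLabels"))

#' @rdname CellTracks
#' @export
setGeneric("observations", function(x) standardGeneric("observations"))

#' @rdname ColonySet
#' @export
setGeneric("colonyInfo", function(x) standardGeneric("colonyInfo"))

#' @rdname ColonySet
#' @export
setGeneric("colonyCells", function(x, frame) standardGeneric("colonyCells"))

#' Classify growth curves by complete-linkage clustering
#'
#' @param x a \linkS4class{GrowthCurveSet} or a colony x day count matrix.
#' @param ... passed to methods.
#' @export
setGeneric("clusterCurves", function(x, ...) standardGeneric("clusterCurves"))

#' Day-by-day prediction of final colony counts
#'
#' @param x a \linkS4class{GrowthCurveSet} or a colony x day count matrix.
#' @param ... passed to methods.
#' @export
setGeneric("predictDay14", function(x, ...) standardGeneric("predictDay14"))
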