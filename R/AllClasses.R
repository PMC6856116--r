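#' @import methods
#' @importFrom stats cor dist hclust cutree median mad rnorm runif rexp rgamma
#'   quantile var setNames
#' @importFrom utils write.csv read.csv head tail
NULL

#' Simulation configuration for synthetic colony time-lapse data
#'
#' Holds every parameter of the synthetic-data generator: imaging geometry
#' (frame shape, pixel size, frame interval), culture duration, the mix of
#' colony growth archetypes and their kinetic parameters, debris behaviour,
#' and rendering parameters (background gradient, cell contrast, noise).
#'
#' The defaults describe the imaging setup the package targets: frames every
#' 6 h for 14 days at 4 um/px, colonies founded by single cells seeded
#' sparsely, and three growth archetypes (large, medium, small) whose
#' division kinetics span the range of observed colony sizes.
#'
#' @slot nColonies number of colonies to simulate.
#' @slot seed integer seed; every stochastic step derives from it.
#' @slot frameIntervalH hours between frames; must divide 24.
#' @slot durationDays culture length in days.
#' @slot pixelSizeUm physical pixel size in micrometres per pixel.
#' @slot frameShape integer c(height, width) in pixels.
#' @slot groupMix named proportions over archetypes large/medium/small; sums to 1.
#' @slot divisionIntervalH named mean waiting time (h) between divisions per archetype.
#' @slot lagH named mean lag (h) before the first division per archetype.
#' @slot debrisCount number of debris objects per frame.
#' @slot debrisJumpPx minimum per-frame displacement of each debris object (px).
#' @slot backgroundGradientAmplitude peak-to-peak amplitude (gray levels) of the
#'   smooth background brightness gradient.
#' @slot cellContrast gray levels by which a cell interior is darker than the
#'   local background.
#' @slot haloContrast gray levels by which the halo rim is brighter than the
#'   local background.
#' @slot noiseSd standard deviation of additive Gaussian pixel noise (gray levels).
#' @slot cellSpacingPx minimum centre-to-centre spacing between cells of a
#'   colony (px); daughters are placed at about this distance.
#' @slot jitterPx per-frame Brownian jitter of cell centroids (px); 0 disables.
#'
#' @seealso [simConfig()], [simulateGrowthCurves()], [simulateColonies()]
#' @export
setClass("SimConfig", representation(
  nColonies = "numeric",
  seed = "numeric",
  frameIntervalH = "numeric",
  durationDays = "numeric",
  pixelSizeUm = "numeric",
  frameShape = "numeric",
  groupMix = "numeric",
  divisionIntervalH = "numeric",
  lagH = "numeric",
  debrisCount = "numeric",
  debrisJumpPx = "numeric",
  backgroundGradientAmplitude = "numeric",
  cellContrast = "numeric",
  haloContrast = "numeric",
  noiseSd = "numeric",
  cellSpacingPx = "numeric",
  jitterPx = "numeric"
))

setValidity("SimConfig", function(object) {
  msg <- character()
  if (abs(sum(object@groupMix) - 1) > 1e-8)
    msg <- c(msg, "groupMix must sum to 1")
  if (any(object@groupMix < 0))
    msg <- c(msg, "groupMix proportions must be non-negative")
  if (24 %% object@frameIntervalH != 0)
    msg <- c(msg, "frameIntervalH must divide 24")
  if (object@durationDays < 1)
    msg <- c(msg, "durationDays must be >= 1")
  if (object@nColonies < 0 || object@debrisCount < 0)
    msg <- c(msg, "counts must be >= 0")
  if (length(object@frameShape) != 2 || any(object@frameShape < 32))
    msg <- c(msg, "frameShape must be c(height, width), each >= 32 px")
  if (object@pixelSizeUm <= 0)
    msg <- c(msg, "pixelSizeUm must be > 0")
  arch <- c("large", "medium", "small")
  for (s in c("groupMix", "divisionIntervalH", "lagH"))
    if (!identical(names(slot(object, s)), arch))
      msg <- c(msg, sprintf("%s must be named c('large','medium','small')", s))
  if (length(msg)) msg else TRUE
})

#' An ordered grayscale time-lapse image sequence
#'
#' Frames are numeric matrices (rows = y, columns = x) on a common gray-level
#' scale, with the physical pixel size and acquisition times attached.
#' Coordinates reported by the package are 0-based, x = column, y = row.
#'
#' @slot frames list of numeric matrices, all of identical dimension.
#' @slot pixelSizeUm micrometres per pixel.
#' @slot frameIntervalH hours between consecutive frames.
#' @slot timestampsH hours since seeding, strictly increasing, one per frame.
#'
#' @seealso [ImageSequence()], [readSequence()], [renderSequence()]
#' @export
setClass("ImageSequence", representation(
  frames = "list",
  pixelSizeUm = "numeric",
  frameIntervalH = "numeric",
  timestampsH = "numeric"
))

setValidity("ImageSequence", function(object) {
  msg <- character()
  if (length(object@frames)) {
    dims <- vapply(object@frames, function(f) dim(f), integer(2))
    if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
      msg <- c(msg, "all frames must have the same dimensions")
  }
  if (length(object@timestampsH) != length(object@frames))
    msg <- c(msg, "need one timestamp per frame")
  if (length(object@timestampsH) > 1 && any(diff(object@timestampsH) <= 0))
    msg <- c(msg, "timestamps must be strictly increasing")
  if (object@pixelSizeUm <= 0) msg <- c(msg, "pixelSizeUm must be > 0")
  if (length(msg)) msg else TRUE
})

#' Ground truth of a synthetic colony simulation
#'
#' Records every simulated cell (static position, birth time, colony of
#' origin, drawn ellipse), the per-frame positions of teleporting debris,
#' per-colony daily true counts at the day reference frames, and any colony
#' merge events.
#'
#' @slot cells data.frame with one row per cell: cellId, colonyId, birthH,
#'   x, y (0-based px), majorAxisPx, minorAxisPx, thetaRad.
#' @slot colonies data.frame with one row per colony: colonyId, archetype,
#'   founderX, founderY (0-based px), lagH.
#' @slot debris data.frame with one row per debris per frame: frame (0-based),
#'   debrisId, x, y, majorAxisPx, minorAxisPx, thetaRad.
#' @slot dailyCounts integer matrix, colonies x days; entry (c, d) is the
#'   number of cells of colony c alive at the day-d reference frame.
#' @slot mergeEvents data.frame: frame, colonyA, colonyB (empty when founder
#'   placement keeps colonies clear of each other, the default).
#' @slot config the \linkS4class{SimConfig} used.
#' @export
setClass("SimTruth", representation(
  cells = "data.frame",
  colonies = "data.frame",
  debris = "data.frame",
  dailyCounts = "matrix",
  mergeEvents = "data.frame",
  config = "SimConfig"
))

setValidity("SimTruth", function(object) {
  msg <- character()
  if (nrow(object@cells) &&
      !all(object@cells$colonyId %in% object@colonies$colonyId))
    msg <- c(msg, "every cell must map to a known colony")
  if (nrow(object@cells) && anyDuplicated(object@cells$cellId))
    msg <- c(msg, "cellId must be unique")
  if (length(msg)) msg else TRUE
})

#' Per-frame segmentation results
#'
#' One row per detected object with its frame (0-based), centroid (0-based
#' px, x = column, y = row), area and bounding box. Pixel sets (n x 2
#' matrices of 0-based (row, col)) are retained for the frames listed in
#' \code{pixelFrames} so that shape statistics can be computed there without
#' holding full label images for every frame.
#'
#' @slot objects data.frame: frame, obj, x, y, area, minRow, minCol, maxRow, maxCol.
#' @slot pixelSets named list, one entry per retained frame ("f<frame>"),
#'   each a list of pixel-coordinate matrices parallel to that frame's objects.
#' @slot pixelFrames integer vector of 0-based frames with retained pixel sets.
#' @slot pixelSizeUm micrometres per pixel, carried from the sequence.
#' @export
setClass("DetectionSet", representation(
  objects = "data.frame",
  pixelSets = "list",
  pixelFrames = "numeric",
  pixelSizeUm = "numeric"
))

#' Temporally linked cell tracks
#'
#' Observations are (track, frame, obj) triples pointing into a
#' \linkS4class{DetectionSet}; \code{labels} holds the persistence
#' classification of each track: living cells persist in place over several
#' frames, image noise (debris) does not.
#'
#' @slot observations data.frame: track, frame, obj, x, y (px, 0-based).
#' @slot labels factor per track with levels living/noise/undecided.
#' @slot maxStepPx numeric per track: largest inter-frame centroid displacement.
#' @export
setClass("CellTracks", representation(
  observations = "data.frame",
  labels = "factor",
  maxStepPx = "numeric"
))

setValidity("CellTracks", function(object) {
  msg <- character()
  ob <- object@observations
  if (nrow(ob)) {
    if (anyDuplicated(ob[, c("frame", "obj")]))
      msg <- c(msg, "an object may belong to at most one track")
    o <- order(ob$track, ob$frame)
    if (any(tapply(ob$frame[o], ob$track[o], function(f) any(diff(f) <= 0)),
            na.rm = TRUE))
      msg <- c(msg, "frames within a track must be strictly increasing")
  }
  if (length(object@labels) != length(object@maxStepPx))
    msg <- c(msg, "labels and maxStepPx must have one entry per track")
  if (length(msg)) msg else TRUE
})

#' Colonies tracked through a time-lapse sequence
#'
#' \code{cells} lists, for every frame, the living cells assigned to each
#' colony (positions in micrometres); \code{colonies} records per-colony
#' status: the frame at which the colony definition (minimum cell count
#' within the confirmation diameter) was first met, and whether/when the
#' colony merged with another one (merged colonies are excluded from growth
#' curves).
#'
#' @slot cells data.frame: frame, colonyId, track, obj, xUm, yUm.
#' @slot colonies data.frame: colonyId, firstFrame, confirmedFrame (NA if
#'   never confirmed), merged, mergedFrame (NA if never merged).
#' @slot config list of colony-rule parameters (minCells, colonyDiameterUm,
#'   mergeDistanceUm).
#' @slot pixelSizeUm micrometres per pixel.
#' @export
setClass("ColonySet", representation(
  cells = "data.frame",
  colonies = "data.frame",
  config = "list",
  pixelSizeUm = "numeric"
))

#' Per-colony daily growth curves
#'
#' Extends \code{SummarizedExperiment}: rows are colonies, columns are
#' culture days, the \code{counts} assay holds the number of living cells
#' per colony at each day's reference frame and the \code{sqrtCounts} assay
#' its element-wise square root (the scale used for curve classification).
#' Cluster labels live in \code{rowData()}; the dendrogram and the
#' day-by-day coefficient of determination against the final day are kept
#' in \code{metadata()}.
#'
#' @seealso [GrowthCurveSet()], [clusterCurves()], [predictDay14()]
#' @export
setClass("GrowthCurveSet", contains = "SummarizedExperiment")
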