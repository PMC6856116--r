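# Colony identification and growth-curve extraction: single-linkage
# grouping of living cells, the confirmation rule (minimum cell number
# within a fixed diameter), temporal identity, merge exclusion, and the
# per-day count matrix.

#' Colony rule parameters
#'
#' @param minCells minimum number of cells for a confirmed colony (>= 2).
#' @param colonyDiameterUm confirmation diameter in micrometres: a colony is
#'   confirmed once at least \code{minCells} of its cells fit within a circle
#'   of this diameter.
#' @param mergeDistanceUm two colonies whose closest cells come strictly
#'   within this distance are both flagged merged and excluded from growth
#'   analysis; also the single-linkage cutoff used for grouping, so distinct
#'   groups are at least this far apart by construction.
#' @return a named list.
#' @export
colonyConfig <- function(minCells = 4, colonyDiameterUm = 320,
                         mergeDistanceUm = 100) {
  stopifnot(minCells >= 2, colonyDiameterUm > 0, mergeDistanceUm > 0)
  list(minCells = minCells, colonyDiameterUm = colonyDiameterUm,
       mergeDistanceUm = mergeDistanceUm)
}

#' Group one frame's living cells into candidate colonies
#'
#' Single-linkage grouping at the merge-distance cutoff (strict): cells
#' connected by chains of spacings below \code{mergeDistanceUm} share a
#' group. A group is a confirmed colony when at least \code{minCells} of its
#' members fit within a circle of diameter \code{colonyDiameterUm}
#' (minimum-enclosing-circle sense, boundary inclusive).
#'
#' @param centroidsUm numeric n x 2 matrix of cell centroids in micrometres.
#' @param config a \code{\link{colonyConfig}} list.
#' @return list with \code{membership} (integer per cell) and
#'   \code{confirmed} (logical per group).
#' @examples
#' sq <- cbind(c(0, 40, 0, 40), c(0, 0, 40, 40))
#' groupCells(sq, colonyConfig())
#' @export
groupCells <- function(centroidsUm, config = colonyConfig()) {
  stopIfNot2col(centroidsUm, "centroidsUm")
  membership <- singleLinkageGroups(centroidsUm, config$mergeDistanceUm)
  nG <- if (length(membership)) max(membership) else 0L
  confirmed <- vapply(seq_len(nG), function(g) {
    fitsWithinDiameter(centroidsUm[membership == g, , drop = FALSE],
                       config$colonyDiameterUm, config$minCells)
  }, logical(1))
  list(membership = membership, confirmed = confirmed)
}

#' Track colony identity through a sequence and flag merges
#'
#' For every frame, groups the living cells (\code{\link{groupCells}}) and
#' propagates colony identity by track overlap: a group inherits the id of
#' the previous colony with which it shares the most cell tracks; groups
#' sharing no track found a new colony. When one group overlaps several
#' previous colonies the colonies have fused: all of them record the fused
#' membership for that frame, which \code{\link{detectMerges}} then flags.
#' A colony's \code{confirmedFrame} is the first frame the confirmation rule
#' is met.
#'
#' @param tracks a classified \linkS4class{CellTracks}.
#' @param pixelSizeUm micrometres per pixel.
#' @param config a \code{\link{colonyConfig}} list.
#' @param frames 0-based frame indices to process; defaults to every frame
#'   present in the tracks.
#' @return a \linkS4class{ColonySet} (merge flags not yet set; see
#'   \code{\link{detectMerges}}).
#' @export
trackColonies <- function(tracks, pixelSizeUm, config = colonyConfig(),
                          frames = NULL) {
  stopifnot(is(tracks, "CellTracks"))
  obs <- tracks@observations
  if (is.null(frames))
    frames <- if (nrow(obs)) sort(unique(obs$frame)) else integer(0)

  cellRows <- vector("list", length(frames))
  reg <- list()   # per colony: lastTracks, firstFrame, confirmedFrame
  nextId <- 0L

  for (fi in seq_along(frames)) {
    f <- frames[fi]
    cells <- livingCellsAtFrame(tracks, f)
    if (!nrow(cells)) next
    pts <- cbind(cells$x, cells$y) * pixelSizeUm
    membership <- singleLinkageGroups(pts, config$mergeDistanceUm)
    nG <- max(membership)

    # which colonies does each group continue? (overlap of the group's
    # tracks with each colony's last-seen tracks; many groups may continue
    # one colony -- e.g. a transient single-linkage split -- and one group
    # may continue several colonies, which is a fusion)
    groupCols <- vector("list", nG)
    if (length(reg)) {
      for (g in seq_len(nG)) {
        tg <- cells$track[membership == g]
        ov <- vapply(reg, function(cl)
          sum(tg %in% cl$lastTracks), integer(1))
        groupCols[[g]] <- which(ov > 0)
      }
    }

    rowsPerColony <- list()
    for (g in seq_len(nG)) {
      sel <- membership == g
      if (!length(groupCols[[g]])) {
        nextId <- nextId + 1L
        reg[[nextId]] <- list(lastTracks = integer(0), firstFrame = f,
                              confirmedFrame = NA_integer_)
        groupCols[[g]] <- nextId
      }
      rows <- data.frame(frame = f, colonyId = NA_integer_,
                         track = cells$track[sel], obj = cells$obj[sel],
                         xUm = pts[sel, 1], yUm = pts[sel, 2])
      for (ci in groupCols[[g]]) {
        rows$colonyId <- ci
        key <- as.character(ci)
        rowsPerColony[[key]] <- rbind(rowsPerColony[[key]], rows)
      }
    }
    for (key in names(rowsPerColony)) {
      ci <- as.integer(key)
      rows <- unique(rowsPerColony[[key]])
      reg[[ci]]$lastTracks <- rows$track
      if (is.na(reg[[ci]]$confirmedFrame) &&
          fitsWithinDiameter(cbind(rows$xUm, rows$yUm),
                             config$colonyDiameterUm, config$minCells))
        reg[[ci]]$confirmedFrame <- f
      cellRows[[fi]] <- rbind(cellRows[[fi]], rows)
    }
  }

  cellsDf <- if (length(cellRows)) do.call(rbind, cellRows) else
    data.frame(frame = integer(0), colonyId = integer(0), track = integer(0),
               obj = integer(0), xUm = numeric(0), yUm = numeric(0))
  colDf <- data.frame(
    colonyId = seq_along(reg),
    firstFrame = vapply(reg, `[[`, numeric(1), "firstFrame"),
    confirmedFrame = vapply(reg, function(x)
      as.numeric(x$confirmedFrame), numeric(1)),
    merged = FALSE,
    mergedFrame = NA_real_)
  new("ColonySet", cells = cellsDf, colonies = colDf, config = config,
      pixelSizeUm = pixelSizeUm)
}

#' Flag merged colonies
#'
#' For every frame and every pair of colonies present, computes the minimum
#' cell-to-cell distance between the two memberships; if it is strictly
#' below \code{mergeDistanceUm}, both colonies are flagged merged from that
#' frame onward (no un-merging: merged colonies are excluded from growth
#' analysis entirely).
#'
#' @param colonySet a \linkS4class{ColonySet}.
#' @param config colony rule parameters; defaults to those in the set.
#' @return the \linkS4class{ColonySet} with merged flags and frames set.
#' @export
detectMerges <- function(colonySet, config = colonySet@config) {
  cells <- colonySet@cells
  cols <- colonySet@colonies
  dMax <- config$mergeDistanceUm
  for (f in sort(unique(cells$frame))) {
    fc <- cells[cells$frame == f, , drop = FALSE]
    ids <- sort(unique(fc$colonyId))
    if (length(ids) < 2) next
    pts <- split(seq_len(nrow(fc)), fc$colonyId)
    bb <- t(vapply(ids, function(i) {
      r <- pts[[as.character(i)]]
      c(min(fc$xUm[r]), max(fc$xUm[r]), min(fc$yUm[r]), max(fc$yUm[r]))
    }, numeric(4)))
    for (a in seq_along(ids)[-length(ids)]) {
      for (b in (a + 1):length(ids)) {
        ia <- ids[a]; ib <- ids[b]
        if (cols$merged[ia] && cols$merged[ib]) next
        # bounding-box prefilter
        gapX <- max(bb[a, 1], bb[b, 1]) - min(bb[a, 2], bb[b, 2])
        gapY <- max(bb[a, 3], bb[b, 3]) - min(bb[a, 4], bb[b, 4])
        if (gapX >= dMax || gapY >= dMax) next
        ra <- pts[[as.character(ia)]]; rb <- pts[[as.character(ib)]]
        d2 <- crossDist2(cbind(fc$xUm[ra], fc$yUm[ra]),
                         cbind(fc$xUm[rb], fc$yUm[rb]))
        if (min(d2) < dMax^2) {
          for (i in c(ia, ib)) {
            if (!cols$merged[i]) {
              cols$merged[i] <- TRUE
              cols$mergedFrame[i] <- f
            }
          }
        }
      }
    }
  }
  initialize(colonySet, colonies = cols)
}

#' Build per-colony daily growth curves
#'
#' For every confirmed, non-merged colony, counts its living cells at each
#' day's reference frame (the last frame of the 24-h window). A colony with
#' no observation at a reference frame carries its last known count forward
#' (with a warning); days before its first observation use the earliest
#' known count.
#'
#' @param colonySet a \linkS4class{ColonySet} after \code{\link{detectMerges}}.
#' @param durationDays number of days (columns).
#' @param frameIntervalH hours between frames.
#' @return a \linkS4class{GrowthCurveSet}; zero qualifying colonies yield a
#'   0-row set with a warning.
#' @export
buildGrowthCurves <- function(colonySet, durationDays = 14, frameIntervalH = 6) {
  cols <- colonySet@colonies
  keep <- cols$colonyId[!is.na(cols$confirmedFrame) & !cols$merged]
  refFrames <- vapply(seq_len(durationDays), function(d)
    dayReferenceFrame(d, frameIntervalH) - 1L, integer(1))  # 0-based
  counts <- matrix(NA_real_, length(keep), durationDays,
                   dimnames = list(keep, paste0("day", seq_len(durationDays))))
  cells <- colonySet@cells
  carried <- FALSE
  for (i in seq_along(keep)) {
    cc <- cells[cells$colonyId == keep[i], , drop = FALSE]
    perFrame <- table(cc$frame)
    known <- as.integer(names(perFrame))
    for (d in seq_len(durationDays)) {
      f <- refFrames[d]
      if (f %in% known) {
        counts[i, d] <- perFrame[[as.character(f)]]
      } else {
        earlier <- known[known < f]
        if (length(earlier)) {
          counts[i, d] <- perFrame[[as.character(max(earlier))]]
          carried <- TRUE
        } else {
          counts[i, d] <- perFrame[[as.character(min(known))]]
          carried <- TRUE
        }
      }
    }
  }
  if (carried)
    warning("some colonies had no observation at a reference frame; ",
            "nearest known count used")
  if (!length(keep))
    warning("no confirmed, non-merged colonies; growth-curve set is empty")
  GrowthCurveSet(counts,
                 colonyId = keep,
                 confirmedFrame = cols$confirmedFrame[match(keep, cols$colonyId)],
                 refFrames = refFrames)
}
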