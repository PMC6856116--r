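# Temporal linking of per-frame objects and the persistence rule that
# separates living cells (stable position over several frames) from image
# noise such as debris (which moves rapidly between frames).

#' Link detected objects across consecutive frames
#'
#' Greedy nearest-neighbour assignment between each consecutive frame pair:
#' candidate links (centroid distance at most \code{gatePx}) are accepted in
#' order of increasing distance (ties broken by the next frame object's
#' bounding-box (minRow, minCol)), each object joining at most one track.
#' Unmatched objects found a new track.
#'
#' @param detections a \linkS4class{DetectionSet}.
#' @param gatePx maximum linking distance in pixels.
#' @return a \linkS4class{CellTracks} with all labels "undecided".
#' @export
linkObjects <- function(detections, gatePx = 10) {
  stopifnot(is(detections, "DetectionSet"), gatePx > 0)
  ob <- detections@objects
  if (!nrow(ob))
    return(new("CellTracks",
               observations = data.frame(track = integer(0), frame = integer(0),
                                         obj = integer(0), x = numeric(0),
                                         y = numeric(0)),
               labels = factor(character(0),
                               levels = c("living", "noise", "undecided")),
               maxStepPx = numeric(0)))
  frames <- sort(unique(ob$frame))
  # trackOf[[f]] maps object index in frame f to its track id
  byFrame <- split(seq_len(nrow(ob)), ob$frame)
  nextTrack <- 0L
  trackId <- integer(nrow(ob))

  prevRows <- byFrame[[as.character(frames[1])]]
  trackId[prevRows] <- nextTrack + seq_along(prevRows)
  nextTrack <- nextTrack + length(prevRows)

  for (fi in seq_along(frames)[-1]) {
    curRows <- byFrame[[as.character(frames[fi])]]
    consecutive <- frames[fi] == frames[fi - 1] + 1
    matchedCur <- logical(length(curRows))
    if (consecutive && length(prevRows) && length(curRows)) {
      d <- sqrt(crossDist2(cbind(ob$x[prevRows], ob$y[prevRows]),
                           cbind(ob$x[curRows], ob$y[curRows])))
      cand <- which(d <= gatePx, arr.ind = TRUE)
      if (nrow(cand)) {
        dist <- d[cand]
        o <- order(dist,
                   ob$minRow[curRows][cand[, 2]],
                   ob$minCol[curRows][cand[, 2]])
        usedPrev <- logical(length(prevRows))
        for (k in o) {
          i <- cand[k, 1]; j <- cand[k, 2]
          if (usedPrev[i] || matchedCur[j]) next
          usedPrev[i] <- TRUE
          matchedCur[j] <- TRUE
          trackId[curRows[j]] <- trackId[prevRows[i]]
        }
      }
    }
    newIdx <- which(!matchedCur)
    trackId[curRows[newIdx]] <- nextTrack + seq_along(newIdx)
    nextTrack <- nextTrack + length(newIdx)
    prevRows <- curRows
  }

  obs <- data.frame(track = trackId, frame = ob$frame, obj = ob$obj,
                    x = ob$x, y = ob$y)
  obs <- obs[order(obs$track, obs$frame), , drop = FALSE]
  rownames(obs) <- NULL
  steps <- maxStepPerTrack(obs, nextTrack)
  new("CellTracks", observations = obs,
      labels = factor(rep("undecided", nextTrack),
                      levels = c("living", "noise", "undecided")),
      maxStepPx = steps)
}

maxStepPerTrack <- function(obs, nTracks) {
  out <- numeric(nTracks)
  sp <- split(seq_len(nrow(obs)), obs$track)
  for (t in seq_along(sp)) {
    i <- sp[[t]]
    out[as.integer(names(sp)[t])] <- if (length(i) < 2) 0 else
      max(sqrt(diff(obs$x[i])^2 + diff(obs$y[i])^2))
  }
  out
}

#' Classify tracks as living cells or image noise
#'
#' A track is labelled \code{living} when it contains a run of at least
#' \code{minFrames} observations in consecutive frames whose successive
#' centroid displacements are all at most \code{maxStepPx} --- the
#' "same position in several frames" persistence rule. All other tracks
#' (too short, or moving faster than \code{maxStepPx}) are \code{noise}.
#'
#' @param tracks a \linkS4class{CellTracks}.
#' @param minFrames minimum persistent run length in frames (>= 2).
#' @param maxStepPx maximum per-frame displacement within a persistent run.
#' @return the tracks with labels filled in.
#' @export
classifyTracks <- function(tracks, minFrames = 3, maxStepPx = 10) {
  stopifnot(is(tracks, "CellTracks"), minFrames >= 2)
  obs <- tracks@observations
  labels <- as.character(tracks@labels)
  sp <- split(seq_len(nrow(obs)), obs$track)
  for (t in names(sp)) {
    i <- sp[[t]]
    tid <- as.integer(t)
    if (length(i) < minFrames) {
      labels[tid] <- "noise"
      next
    }
    okStep <- diff(obs$frame[i]) == 1 &
      sqrt(diff(obs$x[i])^2 + diff(obs$y[i])^2) <= maxStepPx
    # longest run of consecutive persistent steps; run of k steps = k+1 frames
    best <- 0L; cur <- 0L
    for (s in okStep) {
      cur <- if (s) cur + 1L else 0L
      best <- max(best, cur)
    }
    labels[tid] <- if (best + 1L >= minFrames) "living" else "noise"
  }
  initialize(tracks,
             labels = factor(labels, levels = c("living", "noise", "undecided")))
}

#' Living cells present at one frame
#'
#' @param tracks a classified \linkS4class{CellTracks}.
#' @param frame 0-based frame index.
#' @param pixelSizeUm if given, coordinates are returned in micrometres.
#' @return data.frame: track, obj, x, y (px or um).
#' @export
livingCellsAtFrame <- function(tracks, frame, pixelSizeUm = NULL) {
  obs <- tracks@observations
  living <- which(tracks@labels == "living")
  sel <- obs$frame == frame & obs$track %in% living
  out <- obs[sel, c("track", "obj", "x", "y"), drop = FALSE]
  if (!is.null(pixelSizeUm)) {
    out$x <- out$x * pixelSizeUm
    out$y <- out$y * pixelSizeUm
  }
  rownames(out) <- NULL
  out
}
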