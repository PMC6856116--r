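# Scoring a pipeline run against simulation ground truth.

#' Score a pipeline run against simulation ground truth
#'
#' Quantifies how faithfully the pipeline recovered a simulated experiment:
#' per-frame detection precision/recall against true object positions
#' (cells and debris alike), rejection of teleporting debris by the
#' persistence classifier, agreement of the growth-curve matrix with the
#' simulator's per-colony daily counts, and the OLS agreement of final-day
#' counts.
#'
#' @param results list from \code{\link{runPipeline}} on a rendered
#'   sequence.
#' @param truth the \linkS4class{SimTruth} behind that sequence.
#' @param matchRadiusPx maximum centroid distance for a detection to match
#'   a true object.
#' @return list: \code{detectionPrecision}, \code{detectionRecall} (pooled
#'   over frames), \code{debrisRejection} (fraction of debris-majority
#'   tracks labelled noise), \code{growthMatrixAgreement} (fraction of
#'   colony x day entries equal to truth), \code{countR2} and
#'   \code{countMeanRelativeError} (final-day counts vs truth),
#'   \code{nColoniesScored}.
#' @export
scoreAgainstTruth <- function(results, truth, matchRadiusPx = 8) {
  ob <- results$detections@objects
  tsH <- results$sequence@timestampsH
  r2px <- matchRadiusPx^2

  nDet <- 0L; nDetMatched <- 0L; nTruth <- 0L; nTruthMatched <- 0L
  for (f in seq_along(tsH) - 1L) {
    d <- ob[ob$frame == f, , drop = FALSE]
    tc <- truth@cells[truth@cells$birthH <= tsH[f + 1L], , drop = FALSE]
    deb <- truth@debris[truth@debris$frame == f, , drop = FALSE]
    tx <- c(tc$x, deb$x); ty <- c(tc$y, deb$y)
    nDet <- nDet + nrow(d); nTruth <- nTruth + length(tx)
    if (!nrow(d) || !length(tx)) next
    d2 <- crossDist2(cbind(d$x, d$y), cbind(tx, ty))
    nDetMatched <- nDetMatched + sum(apply(d2, 1, min) <= r2px)
    nTruthMatched <- nTruthMatched + sum(apply(d2, 2, min) <= r2px)
  }

  # debris-majority tracks must be classified noise
  obs <- results$tracks@observations
  isDebrisObs <- logical(nrow(obs))
  for (f in unique(obs$frame)) {
    deb <- truth@debris[truth@debris$frame == f, , drop = FALSE]
    sel <- which(obs$frame == f)
    if (!nrow(deb) || !length(sel)) next
    d2 <- crossDist2(cbind(obs$x[sel], obs$y[sel]), cbind(deb$x, deb$y))
    isDebrisObs[sel] <- apply(d2, 1, min) <= 25
  }
  share <- tapply(isDebrisObs, obs$track, mean)
  debrisTracks <- as.integer(names(share)[share > 0.5])
  debrisRejection <- if (!length(debrisTracks)) NA_real_ else
    mean(results$tracks@labels[debrisTracks] == "noise")

  # growth matrix vs truth daily counts, colonies matched by founder position
  cm <- growthCounts(results$curves)
  agreement <- NA_real_; countR2 <- NA_real_; relErr <- NA_real_
  if (nrow(cm) >= 3) {
    rd <- SummarizedExperiment::rowData(results$curves)
    cells <- results$colonies@cells
    ps <- results$colonies@pixelSizeUm
    firstPos <- t(vapply(rd$colonyId, function(id) {
      cc <- cells[cells$colonyId == id, , drop = FALSE]
      cc <- cc[cc$frame == min(cc$frame), , drop = FALSE]
      c(mean(cc$xUm), mean(cc$yUm))
    }, numeric(2)))
    fp <- cbind(truth@colonies$founderX, truth@colonies$founderY) *
      results$config$pixelSizeUm
    match <- apply(firstPos, 1, function(p)
      which.min((fp[, 1] - p[1])^2 + (fp[, 2] - p[2])^2))
    days <- seq_len(min(ncol(cm), ncol(truth@dailyCounts)))
    tm <- truth@dailyCounts[match, days, drop = FALSE]
    agreement <- mean(cm[, days] == tm)
    v <- validateCounts(cm[, max(days)], tm[, max(days)])
    countR2 <- v$r2
    relErr <- v$meanRelativeError
  }

  list(detectionPrecision = nDetMatched / nDet,
       detectionRecall = nTruthMatched / nTruth,
       debrisRejection = debrisRejection,
       growthMatrixAgreement = agreement,
       countR2 = countR2,
       countMeanRelativeError = relErr,
       nColoniesScored = nrow(cm))
}
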