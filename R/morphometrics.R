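# Colony shape statistics: the cell long axis from normalized second
# central moments, and the mean Delaunay inter-cell distance.

#' Cell long axis from second central moments
#'
#' Length of the major axis of the ellipse with the same normalized second
#' central moments as the pixel region. Each pixel contributes its centre
#' plus the 1/12 pixel-extent correction to the diagonal moments (the usual
#' regionprops convention), so a single pixel has a long axis of
#' 4 * sqrt(1/12) px.
#'
#' @param pixelSet integer n x 2 matrix of (row, col) pixel coordinates.
#' @param pixelSizeUm micrometres per pixel.
#' @return long axis in micrometres.
#' @examples
#' px <- as.matrix(expand.grid(row = 0:20, col = 0:20))
#' disc <- px[(px[, 1] - 10)^2 + (px[, 2] - 10)^2 <= 100, ]
#' longAxis(disc, 4)   # close to 2 * 10 px * 4 um/px = 80 um
#' @export
longAxis <- function(pixelSet, pixelSizeUm = 1) {
  if (is.null(dim(pixelSet)) || nrow(pixelSet) == 0)
    stop("pixelSet must contain at least one pixel")
  r <- pixelSet[, 1]; cc <- pixelSet[, 2]
  murr <- mean((r - mean(r))^2) + 1 / 12
  mucc <- mean((cc - mean(cc))^2) + 1 / 12
  murc <- mean((r - mean(r)) * (cc - mean(cc)))
  lmax <- (murr + mucc) / 2 + sqrt(((murr - mucc) / 2)^2 + murc^2)
  4 * sqrt(lmax) * pixelSizeUm
}

# TRUE when the points are (numerically) collinear.
isCollinear <- function(p, tol = 1e-9) {
  if (nrow(p) < 3) return(TRUE)
  ctr <- scale(p, scale = FALSE)
  sv <- svd(ctr, nu = 0, nv = 0)$d
  sv[2] <= tol * max(sv[1], 1)
}

#' Mean Delaunay inter-cell distance
#'
#' Triangulates the cell centroids (Delaunay) and returns the mean length of
#' the unique triangulation edges --- the colony's characteristic cell
#' spacing. Two points, or a collinear set, fall back to the mean of
#' consecutive pairwise distances along the line.
#'
#' @param centroidsUm numeric n x 2 matrix (n >= 2) of centroids in
#'   micrometres.
#' @return mean edge length in micrometres.
#' @examples
#' tri <- cbind(c(0, 4, 2), c(0, 0, 3))
#' intercellDistance(tri)   # (4 + 2 * sqrt(13)) / 3
#' @export
intercellDistance <- function(centroidsUm) {
  stopIfNot2col(centroidsUm, "centroidsUm")
  n <- nrow(centroidsUm)
  if (n < 2) stop("need at least 2 points")
  if (n == 2 || isCollinear(centroidsUm)) {
    # order along the principal direction, average consecutive gaps
    ctr <- scale(centroidsUm, scale = FALSE)
    dir <- svd(ctr, nu = 0, nv = 2)$v[, 1]
    proj <- ctr %*% dir
    o <- order(proj)
    p <- centroidsUm[o, , drop = FALSE]
    return(mean(sqrt(rowSums((p[-1, , drop = FALSE] -
                              p[-n, , drop = FALSE])^2))))
  }
  edges <- delaunayEdges(centroidsUm)
  mean(sqrt((centroidsUm[edges[, 1], 1] - centroidsUm[edges[, 2], 1])^2 +
            (centroidsUm[edges[, 1], 2] - centroidsUm[edges[, 2], 2])^2))
}

# Unique Delaunay edges as a 2-column index matrix (i < j), via deldir.
delaunayEdges <- function(p) {
  dd <- deldir::deldir(p[, 1], p[, 2], suppressMsge = TRUE)
  e <- cbind(pmin(dd$delsgs$ind1, dd$delsgs$ind2),
             pmax(dd$delsgs$ind1, dd$delsgs$ind2))
  unique(e)
}

#' Colony morphometrics at a reference frame
#'
#' For each confirmed colony present at the frame, computes the mean cell
#' long axis (over the member objects' pixel sets, which must have been
#' retained by \code{\link{detectCells}} for that frame) and the mean
#' Delaunay inter-cell distance of the member centroids.
#'
#' @param colonySet a \linkS4class{ColonySet}.
#' @param detections the \linkS4class{DetectionSet} the colonies came from.
#' @param frame 0-based frame index; default the last frame present.
#' @param includeMerged include merged colonies (default FALSE).
#' @return data.frame: colonyId, frame, meanLongAxisUm, meanIntercellDistanceUm,
#'   nCells (distance NA when a colony has fewer than 2 cells at the frame).
#' @export
colonyMorphometrics <- function(colonySet, detections, frame = NULL,
                                includeMerged = FALSE) {
  cells <- colonySet@cells
  if (is.null(frame)) frame <- max(cells$frame)
  key <- paste0("f", frame)
  if (!key %in% names(detections@pixelSets))
    stop("pixel sets for frame ", frame, " were not retained; ",
         "pass keepPixelFrames to detectCells()")
  px <- detections@pixelSets[[key]]
  cols <- colonySet@colonies
  keep <- cols$colonyId[!is.na(cols$confirmedFrame) &
                          (includeMerged | !cols$merged)]
  fc <- cells[cells$frame == frame & cells$colonyId %in% keep, , drop = FALSE]
  ids <- sort(unique(fc$colonyId))
  out <- lapply(ids, function(i) {
    m <- fc[fc$colonyId == i, , drop = FALSE]
    axes <- vapply(m$obj, function(o)
      longAxis(px[[o]], detections@pixelSizeUm), numeric(1))
    pts <- cbind(m$xUm, m$yUm)
    data.frame(colonyId = i, frame = frame,
               meanLongAxisUm = mean(axes),
               meanIntercellDistanceUm =
                 if (nrow(pts) >= 2) intercellDistance(pts) else NA_real_,
               nCells = nrow(m))
  })
  if (!length(out))
    return(data.frame(colonyId = integer(0), frame = integer(0),
                      meanLongAxisUm = numeric(0),
                      meanIntercellDistanceUm = numeric(0),
                      nCells = integer(0)))
  do.call(rbind, out)
}
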