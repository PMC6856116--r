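# Growth-curve classification and early-day prediction of final counts.

#' Construct a GrowthCurveSet
#'
#' @param counts colony x day numeric matrix (days 1..ncol).
#' @param colonyId integer ids, one per row.
#' @param confirmedFrame optional per-colony confirmation frames.
#' @param refFrames optional per-day 0-based reference frame indices.
#' @return a \linkS4class{GrowthCurveSet}.
#' @export
GrowthCurveSet <- function(counts, colonyId = seq_len(nrow(counts)),
                           confirmedFrame = NA, refFrames = NA) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  days <- seq_len(ncol(counts))
  colnames(counts) <- paste0("day", days)
  rowDf <- S4Vectors::DataFrame(colonyId = colonyId,
                                confirmedFrame = confirmedFrame)
  colDf <- S4Vectors::DataFrame(day = days, refFrame = refFrames)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts, sqrtCounts = sqrt(counts)),
    rowData = rowDf, colData = colDf)
  new("GrowthCurveSet", se)
}

#' Extract the count matrix of a GrowthCurveSet
#'
#' @param x a \linkS4class{GrowthCurveSet}.
#' @return the colony x day count matrix.
#' @export
growthCounts <- function(x) {
  SummarizedExperiment::assay(x, "counts")
}

# Workhorse: complete-linkage clustering of sqrt-transformed curves.
clusterCurveMatrix <- function(counts, k) {
  n <- nrow(counts)
  if (k > n) stop("k (", k, ") exceeds the number of colonies (", n, ")")
  if (k < 1) stop("k must be >= 1")
  hc <- hclust(dist(sqrt(counts)), method = "complete")
  raw <- cutree(hc, k = k)
  # order groups by descending mean final-day count: group 1 grows largest
  finals <- tapply(counts[, ncol(counts)], raw, mean)
  rank <- match(names(sort(finals, decreasing = TRUE)), names(finals))
  labels <- match(raw, as.integer(names(finals)[rank]))
  list(labels = labels, hclust = hc)
}

#' @describeIn clusterCurves cluster the curves of a GrowthCurveSet;
#'   labels are stored in \code{rowData(x)$cluster}, the dendrogram in
#'   \code{metadata(x)$hclust}.
#' @param kGroups number of groups to cut the dendrogram into.
#' @export
setMethod("clusterCurves", "GrowthCurveSet", function(x, kGroups = 7, ...) {
  res <- clusterCurveMatrix(growthCounts(x), kGroups)
  SummarizedExperiment::rowData(x)$cluster <- res$labels
  S4Vectors::metadata(x)$hclust <- res$hclust
  S4Vectors::metadata(x)$kGroups <- kGroups
  x
})

#' @describeIn clusterCurves cluster the rows of a colony x day count
#'   matrix; returns list(labels, hclust). Curves are square-root
#'   transformed before Euclidean distances are taken (the transform damps
#'   the dominance of the largest colonies), and clustering is
#'   agglomerative with complete linkage (furthest neighbour). Labels are
#'   renumbered so group 1 has the largest mean final-day count.
#' @export
setMethod("clusterCurves", "matrix", function(x, kGroups = 7, ...) {
  clusterCurveMatrix(x, kGroups)
})

# Workhorse: per-day squared Pearson correlation with the final day.
predictDay14Matrix <- function(counts) {
  D <- ncol(counts)
  if (nrow(counts) < 3) stop("need at least 3 colonies")
  if (var(counts[, D]) == 0) stop("final-day counts have zero variance")
  r2 <- vapply(seq_len(D), function(d) {
    if (var(counts[, d]) == 0) return(NA_real_)
    cor(counts[, d], counts[, D])^2
  }, numeric(1))
  if (anyNA(r2))
    warning("R2 undefined on day(s) ",
            paste(which(is.na(r2)), collapse = ", "),
            ": predictor column has zero variance")
  names(r2) <- paste0("day", seq_len(D))
  r2
}

#' @describeIn predictDay14 per-day R2 for a GrowthCurveSet; also stored in
#'   \code{metadata(x)$r2ByDay} of the returned set when assigned back.
#' @export
setMethod("predictDay14", "GrowthCurveSet", function(x, ...) {
  predictDay14Matrix(growthCounts(x))
})

#' @describeIn predictDay14 per-day R2 for a colony x day count matrix:
#'   for each day d, the squared Pearson correlation (equivalently the OLS
#'   coefficient of determination) between the day-d and final-day counts
#'   across colonies, on the raw count scale. The final day's R2 is 1 by
#'   definition; days with constant counts yield NA with a warning.
#' @export
setMethod("predictDay14", "matrix", function(x, ...) {
  predictDay14Matrix(x)
})

#' Validate detected counts against reference counts
#'
#' Ordinary least-squares agreement between paired per-colony counts from
#' two sources (e.g. phase-contrast detection vs nuclear-stain reference, or
#' a pipeline run vs simulation truth), on the raw count scale.
#'
#' @param detectedCounts numeric vector of counts from the method under test.
#' @param truthCounts numeric vector of reference counts, same length, n >= 3.
#' @return list: \code{r2} (squared Pearson correlation),
#'   \code{meanRelativeError} (mean of |detected - truth| / truth over pairs
#'   with truth > 0), \code{n}.
#' @examples
#' validateCounts(c(9, 18, 36), c(10, 20, 40))
#' @export
validateCounts <- function(detectedCounts, truthCounts) {
  if (length(detectedCounts) != length(truthCounts))
    stop("detected and truth counts must have the same length")
  if (length(truthCounts) < 3) stop("need at least 3 paired counts")
  pos <- truthCounts > 0
  list(r2 = cor(detectedCounts, truthCounts)^2,
       meanRelativeError = mean(abs(detectedCounts[pos] - truthCounts[pos]) /
                                  truthCounts[pos]),
       n = length(truthCounts))
}
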