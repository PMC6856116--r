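# Point-set geometry behind the colony definition.

#' Can some k points of a set be enclosed by a circle of a given diameter?
#'
#' Decides whether a point set contains at least \code{k} points whose
#' minimum enclosing circle has diameter at most \code{diameter} --- the
#' geometric core of the colony confirmation rule (at least 4 cells within
#' a 320 um diameter). Equivalently: does a circle of radius
#' \code{diameter / 2} exist that covers at least \code{k} of the points?
#'
#' Uses the classical candidate-circle argument: any circle of radius r
#' covering two or more points can be translated until two covered points
#' lie on its boundary, so it suffices to test circles centred at each
#' point and at the two intersections of radius-r circles around each pair
#' of points closer than 2r.
#'
#' @param points numeric n x 2 matrix of coordinates (any length unit).
#' @param diameter maximum enclosing-circle diameter, same unit.
#' @param k minimum number of points to enclose.
#' @return TRUE if some k-subset fits within the diameter (boundary
#'   inclusive), FALSE otherwise.
#' @examples
#' sq <- cbind(c(0, 40, 0, 40), c(0, 0, 40, 40))
#' fitsWithinDiameter(sq, 320, 4)   # 40-um square easily fits
#' @export
fitsWithinDiameter <- function(points, diameter, k) {
  stopIfNot2col(points)
  n <- nrow(points)
  if (n < k) return(FALSE)
  if (k <= 1) return(n >= k)
  r <- diameter / 2
  r2 <- r * r
  # comparison slack only (candidates are built with the exact radius, so
  # boundary points sit at r2 up to rounding; the slack absorbs that)
  tol <- 1e-9 * max(1, r2)

  covers <- function(cx, cy) {
    sum((points[, 1] - cx)^2 + (points[, 2] - cy)^2 <= r2 + tol) >= k
  }
  # circles centred on the points themselves (handles clusters hugging one point)
  for (i in seq_len(n)) if (covers(points[i, 1], points[i, 2])) return(TRUE)
  # circles with two points on the boundary
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      dx <- points[j, 1] - points[i, 1]
      dy <- points[j, 2] - points[i, 2]
      d2 <- dx * dx + dy * dy
      if (d2 > 4 * (r2 + tol) || d2 == 0) next
      mx <- (points[i, 1] + points[j, 1]) / 2
      my <- (points[i, 2] + points[j, 2]) / 2
      h <- sqrt(max(0, r2 - d2 / 4))
      d <- sqrt(d2)
      ux <- -dy / d; uy <- dx / d
      if (covers(mx + h * ux, my + h * uy)) return(TRUE)
      if (covers(mx - h * ux, my - h * uy)) return(TRUE)
    }
  }
  FALSE
}

# Single-linkage grouping at a strict distance cutoff: two points belong to
# the same group iff they are connected by a chain of pairs closer than
# `cutoff`. Returns an integer membership vector with groups numbered in
# order of first appearance.
singleLinkageGroups <- function(points, cutoff) {
  stopIfNot2col(points)
  n <- nrow(points)
  if (n == 0) return(integer(0))
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  d2 <- crossDist2(points, points)
  cut2 <- cutoff^2
  for (i in seq_len(n - 1L)) {
    js <- which(d2[i, (i + 1L):n] < cut2) + i
    for (j in js) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}
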