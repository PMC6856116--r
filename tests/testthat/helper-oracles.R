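# Independent brute-force oracles used to cross-check the geometric and
# clustering implementations. These deliberately share no code with the
# package internals.

# Minimum enclosing circle by exhaustive candidate enumeration: every pair's
# diameter circle and every triple's circumcircle; the smallest one covering
# all points wins. Returns the radius.
mecRadiusOracle <- function(p) {
  n <- nrow(p)
  eps <- 1e-9
  if (n == 1) return(0)
  covers <- function(cx, cy, r) {
    all((p[, 1] - cx)^2 + (p[, 2] - cy)^2 <= (r + eps)^2)
  }
  best <- Inf
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    cx <- (p[i, 1] + p[j, 1]) / 2
    cy <- (p[i, 2] + p[j, 2]) / 2
    r <- sqrt((p[i, 1] - cx)^2 + (p[i, 2] - cy)^2)
    if (r < best && covers(cx, cy, r)) best <- r
  }
  if (n >= 3) {
    for (i in seq_len(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
      cc <- circumcenterOracle(p[i, ], p[j, ], p[k, ])
      if (is.null(cc)) next
      r <- sqrt((p[i, 1] - cc[1])^2 + (p[i, 2] - cc[2])^2)
      if (r < best && covers(cc[1], cc[2], r)) best <- r
    }
  }
  best
}

circumcenterOracle <- function(a, b, c) {
  d <- 2 * (a[1] * (b[2] - c[2]) + b[1] * (c[2] - a[2]) + c[1] * (a[2] - b[2]))
  if (abs(d) < 1e-12) return(NULL)
  ux <- ((a[1]^2 + a[2]^2) * (b[2] - c[2]) + (b[1]^2 + b[2]^2) * (c[2] - a[2]) +
           (c[1]^2 + c[2]^2) * (a[2] - b[2])) / d
  uy <- ((a[1]^2 + a[2]^2) * (c[1] - b[1]) + (b[1]^2 + b[2]^2) * (a[1] - c[1]) +
           (c[1]^2 + c[2]^2) * (b[1] - a[1])) / d
  c(ux, uy)
}

# Does some k-subset fit in a circle of the given diameter? (enumerates all
# subsets and takes each subset's exact minimum enclosing circle)
subsetFitsOracle <- function(p, diameter, k) {
  n <- nrow(p)
  if (n < k) return(FALSE)
  any(apply(utils::combn(n, k), 2, function(idx) {
    2 * mecRadiusOracle(p[idx, , drop = FALSE]) <= diameter + 1e-9
  }))
}

# Delaunay edge set by the empty-circumcircle definition: a triangle is
# Delaunay iff no other point lies strictly inside its circumcircle.
delaunayEdgesOracle <- function(p) {
  n <- nrow(p)
  stopifnot(n >= 3)
  edges <- matrix(integer(0), 0, 2)
  for (i in seq_len(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
    cc <- circumcenterOracle(p[i, ], p[j, ], p[k, ])
    if (is.null(cc)) next
    r2 <- (p[i, 1] - cc[1])^2 + (p[i, 2] - cc[2])^2
    others <- setdiff(seq_len(n), c(i, j, k))
    d2 <- (p[others, 1] - cc[1])^2 + (p[others, 2] - cc[2])^2
    if (all(d2 >= r2 * (1 - 1e-9)))
      edges <- rbind(edges, c(i, j), c(j, k), c(i, k))
  }
  unique(edges[order(edges[, 1], edges[, 2]), , drop = FALSE])
}

# Naive agglomerative complete-linkage clustering: start from singletons and
# repeatedly merge the pair of clusters with the smallest maximum pairwise
# member distance, until k clusters remain. Returns a partition vector.
completeLinkageOracle <- function(x, k) {
  n <- nrow(x)
  d <- as.matrix(dist(x))
  clusters <- as.list(seq_len(n))
  while (length(clusters) > k) {
    best <- c(NA, NA); bestD <- Inf
    m <- length(clusters)
    for (a in seq_len(m - 1)) for (b in (a + 1):m) {
      dd <- max(d[clusters[[a]], clusters[[b]]])
      if (dd < bestD) { bestD <- dd; best <- c(a, b) }
    }
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  part <- integer(n)
  for (g in seq_along(clusters)) part[clusters[[g]]] <- g
  part
}

# TRUE when two partitions are identical up to label permutation.
samePartition <- function(a, b) {
  tab <- table(a, b)
  all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1)
}

# Small rendered scene shared by detection/tracking tests: a few stationary
# cells and teleporting debris on a gradient background.
makeTinyScene <- function(seed = 11, nColonies = 3, days = 2,
                          shape = c(300L, 300L), debris = 3) {
  cfg <- simConfig(nColonies = nColonies, seed = seed, durationDays = days,
                   frameShape = shape, debrisCount = debris)
  truth <- simulateColonies(cfg)
  seqs <- suppressWarnings(renderSequence(truth))
  list(cfg = cfg, truth = truth, seqs = seqs)
}
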