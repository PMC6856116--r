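# Internal helpers shared across modules.

# Evaluate `code` under a local RNG stream seeded with `seed`, restoring the
# caller's RNG state afterwards so package functions never disturb it.
withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Index (1-based, into the frame list) of the reference frame for day d:
# the last frame within each 24-h window, i.e. the frame at t = 24 d h.
dayReferenceFrame <- function(day, frameIntervalH) {
  as.integer(round(day * 24 / frameIntervalH)) + 1L
}

# Squared Euclidean distances between rows of a (n x 2) and b (m x 2).
crossDist2 <- function(a, b) {
  outer(a[, 1], b[, 1], "-")^2 + outer(a[, 2], b[, 2], "-")^2
}

stopIfNot2col <- function(p, what = "points") {
  if (!is.matrix(p) || ncol(p) != 2 || !is.numeric(p))
    stop(what, " must be a numeric matrix with 2 columns (x, y)")
}
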