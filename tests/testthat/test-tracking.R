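# Helper: build a DetectionSet from a list of per-frame centroid matrices.
detFromCentroids <- function(perFrame) {
  rows <- do.call(rbind, lapply(seq_along(perFrame), function(f) {
    p <- perFrame[[f]]
    if (!nrow(p)) return(NULL)
    data.frame(frame = f - 1L, obj = seq_len(nrow(p)), x = p[, 1], y = p[, 2],
               area = 25L, minRow = floor(p[, 2]), minCol = floor(p[, 1]),
               maxRow = ceiling(p[, 2]), maxCol = ceiling(p[, 1]))
  }))
  new("DetectionSet", objects = rows, pixelSets = list(),
      pixelFrames = numeric(0), pixelSizeUm = 4)
}

test_that("stationary objects form single tracks, fast movers fragment", {
  still <- detFromCentroids(replicate(5, cbind(50, 50), simplify = FALSE))
  tr <- linkObjects(still, gatePx = 10)
  expect_identical(length(tr), 1L)
  expect_identical(nrow(observations(tr)), 5L)

  jump <- detFromCentroids(lapply(0:4, function(f) cbind(10 + 50 * f, 10)))
  trj <- linkObjects(jump, gatePx = 10)
  expect_identical(length(trj), 5L)
  expect_true(all(table(observations(trj)$track) == 1))
})

test_that("greedy linking matches optimal assignment for separated objects", {
  two <- detFromCentroids(replicate(3, rbind(c(10, 10), c(110, 10)),
                                    simplify = FALSE))
  tr <- linkObjects(two, gatePx = 10)
  expect_identical(length(tr), 2L)
  ob <- observations(tr)
  # each track keeps a constant position: no cross-links
  for (t in unique(ob$track))
    expect_identical(length(unique(ob$x[ob$track == t])), 1L)
})

test_that("no object is claimed by two tracks", {
  set.seed(99)
  perFrame <- lapply(1:6, function(f) cbind(runif(12, 0, 200), runif(12, 0, 200)))
  tr <- linkObjects(detFromCentroids(perFrame), gatePx = 15)
  ob <- observations(tr)
  expect_false(anyDuplicated(ob[, c("frame", "obj")]) > 0)
  # every detected object appears in exactly one track
  expect_identical(nrow(ob), 6L * 12L)
})

test_that("persistence classification separates living cells from noise", {
  still4 <- detFromCentroids(replicate(4, cbind(50, 50), simplify = FALSE))
  tr <- classifyTracks(linkObjects(still4, 10), minFrames = 3, maxStepPx = 10)
  expect_identical(as.character(trackLabels(tr)), "living")

  one <- detFromCentroids(list(cbind(50, 50)))
  tr1 <- classifyTracks(linkObjects(one, 10), minFrames = 3, maxStepPx = 10)
  expect_identical(as.character(trackLabels(tr1)), "noise")

  # a track drifting faster than maxStep but within the gate stays noise
  drift <- detFromCentroids(lapply(0:3, function(f) cbind(50 + 8 * f, 50)))
  trd <- classifyTracks(linkObjects(drift, 10), minFrames = 3, maxStepPx = 5)
  expect_identical(as.character(trackLabels(trd)), "noise")
})

test_that("raising minFrames never converts noise into living", {
  set.seed(12)
  perFrame <- lapply(1:8, function(f)
    cbind(c(20, 60, 100) + rnorm(3, 0, 1), c(20, 20, 20)))
  base <- linkObjects(detFromCentroids(perFrame), gatePx = 10)
  for (mf in 3:7) {
    lo <- trackLabels(classifyTracks(base, minFrames = mf, maxStepPx = 10))
    hi <- trackLabels(classifyTracks(base, minFrames = mf + 1, maxStepPx = 10))
    expect_true(all(which(hi == "living") %in% which(lo == "living")))
  }
})

test_that("teleporting debris is rejected on rendered sequences", {
  sc <- makeTinyScene(seed = 23, nColonies = 3, days = 2,
                      shape = c(400L, 400L), debris = 10)
  det <- detectCells(sc$seqs, keepPixelFrames = integer(0))
  tracks <- classifyTracks(linkObjects(det, 10), minFrames = 3, maxStepPx = 10)
  ob <- observations(tracks)
  labs <- trackLabels(tracks)

  # majority-debris tracks must all be noise (jump = 4x the gate)
  deb <- sc$truth@debris
  isDebrisObs <- vapply(seq_len(nrow(ob)), function(i) {
    dd <- deb[deb$frame == ob$frame[i], ]
    any((dd$x - ob$x[i])^2 + (dd$y - ob$y[i])^2 <= 25)
  }, logical(1))
  debShare <- tapply(isDebrisObs, ob$track, mean)
  debrisTracks <- as.integer(names(debShare)[debShare > 0.5])
  expect_true(all(labs[debrisTracks] == "noise"))

  # most cells are recovered as living
  nCells <- sum(sc$truth@cells$birthH <= 0)
  liv <- livingCellsAtFrame(tracks, 0)
  tc <- sc$truth@cells[sc$truth@cells$birthH <= 0, ]
  d2 <- outer(liv$x, tc$x, "-")^2 + outer(liv$y, tc$y, "-")^2
  expect_gte(sum(apply(d2, 2, min) <= 64), ceiling(0.9 * nCells))
})
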