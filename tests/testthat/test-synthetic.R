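test_that("growth-curve simulation honours degenerate division settings", {
  # no divisions ever: every colony stays at 1 cell
  cfg <- simConfig(nColonies = 6, seed = 3,
                   divisionIntervalH = c(large = Inf, medium = Inf, small = Inf))
  gc <- simulateGrowthCurves(cfg)
  expect_true(all(gc$counts == 1))

  # deterministic division every 24 h, no lag: 2, 4, 8, 16 on days 1..4
  cfg2 <- simConfig(nColonies = 1, seed = 3, durationDays = 4,
                    groupMix = c(large = 1, medium = 0, small = 0),
                    divisionIntervalH = c(large = 24, medium = 72, small = 144),
                    lagH = c(large = 0, medium = 0, small = 0))
  gc2 <- simulateGrowthCurves(cfg2, stochastic = FALSE)
  expect_equal(unname(gc2$counts[1, ]), c(2, 4, 8, 16))
})

test_that("simulation is deterministic given the seed", {
  cfg <- simConfig(nColonies = 30, seed = 17)
  a <- simulateGrowthCurves(cfg)
  b <- simulateGrowthCurves(cfg)
  expect_identical(a, b)

  cfgR <- simConfig(nColonies = 2, seed = 9, durationDays = 2,
                    frameShape = c(256L, 256L), debrisCount = 2)
  t1 <- simulateColonies(cfgR)
  t2 <- simulateColonies(cfgR)
  expect_identical(t1@cells, t2@cells)
  expect_identical(t1@debris, t2@debris)
  s1 <- suppressWarnings(renderSequence(t1))
  s2 <- suppressWarnings(renderSequence(t2))
  expect_identical(s1@frames, s2@frames)
})

test_that("counts are conserved between cell records and daily matrices", {
  cfg <- simConfig(nColonies = 5, seed = 21, durationDays = 5,
                   frameShape = c(512L, 512L), debrisCount = 0)
  tr <- simulateColonies(cfg)
  for (d in 1:5) {
    perColony <- vapply(tr@colonies$colonyId, function(i)
      sum(tr@cells$colonyId == i & tr@cells$birthH <= 24 * d), integer(1))
    expect_equal(unname(tr@dailyCounts[, d]), perColony)
  }
  # non-decreasing (no death is simulated)
  expect_true(all(apply(tr@dailyCounts, 1, function(r) all(diff(r) >= 0))))
  # every cell maps to exactly one colony
  expect_true(all(tr@cells$colonyId %in% tr@colonies$colonyId))
  expect_false(anyDuplicated(tr@cells$cellId) > 0)
})

test_that("rendering draws dark interiors, bright rims, gradient background", {
  cfg <- simConfig(nColonies = 0, seed = 5, durationDays = 1,
                   frameShape = c(200L, 200L), debrisCount = 0, noiseSd = 0)
  trEmpty <- simulateColonies(cfg)
  seqEmpty <- renderSequence(trEmpty)
  # background-only frames are identical over time and smooth
  expect_identical(seqEmpty@frames[[1]], seqEmpty@frames[[5]])
  bgAmp <- diff(range(seqEmpty@frames[[1]]))
  expect_gt(bgAmp, 5)
  expect_lt(bgAmp, 2 * cfg@backgroundGradientAmplitude)

  cfg2 <- simConfig(nColonies = 2, seed = 5, durationDays = 1,
                    frameShape = c(300L, 300L), debrisCount = 0, noiseSd = 0)
  tr <- simulateColonies(cfg2)
  seqs <- suppressWarnings(renderSequence(tr))
  bg <- renderSequence(
    new("SimTruth", cells = tr@cells[0, ], colonies = tr@colonies[0, ],
        debris = tr@debris[0, ], dailyCounts = tr@dailyCounts[0, , drop = FALSE],
        mergeEvents = tr@mergeEvents, config = cfg2),
    cfg2)
  f <- seqs@frames[[1]]; b <- bg@frames[[1]]
  for (i in seq_len(nrow(tr@cells))) {
    cc <- tr@cells[i, ]
    r0 <- round(cc$y) + 1L; c0 <- round(cc$x) + 1L
    # interior centre darker than the local background, rim above brighter
    expect_lt(f[r0, c0], b[r0, c0])
    rimR <- r0 - round(cc$minorAxisPx / 2 + 1.5)
    expect_gt(max(f[max(rimR, 1):r0, c0]), b[r0, c0])
  }
})

test_that("one stationary cell is recoverable from the rendered frames", {
  cfg <- simConfig(nColonies = 1, seed = 13, durationDays = 1,
                   frameShape = c(200L, 200L), debrisCount = 0, noiseSd = 0,
                   divisionIntervalH = c(large = Inf, medium = Inf, small = Inf))
  tr <- simulateColonies(cfg)
  seqs <- suppressWarnings(renderSequence(tr))
  for (fi in c(1, 3, 5)) {
    f <- seqs@frames[[fi]]
    bg <- colonytrack:::blockMedianBackground(f, 51)
    # darkest blob centroid (oracle: direct argmin filtering) vs truth
    dk <- bg - f
    idx <- which(dk > max(dk) / 2, arr.ind = TRUE)
    cy <- mean(idx[, 1]) - 1; cx <- mean(idx[, 2]) - 1
    expect_lt(sqrt((cx - tr@cells$x[1])^2 + (cy - tr@cells$y[1])^2), 2)
  }
})

test_that("debris teleports at least the configured jump between frames", {
  cfg <- simConfig(nColonies = 1, seed = 7, durationDays = 2,
                   frameShape = c(400L, 400L), debrisCount = 4,
                   debrisJumpPx = 20)
  tr <- simulateColonies(cfg)
  deb <- tr@debris
  for (id in unique(deb$debrisId)) {
    d <- deb[deb$debrisId == id, ]
    d <- d[order(d$frame), ]
    jumps <- sqrt(diff(d$x)^2 + diff(d$y)^2)
    expect_true(all(jumps >= 20))
  }
})

test_that("invalid configurations are rejected", {
  expect_error(simConfig(nColonies = 2, groupMix = c(large = 0.5, medium = 0.4,
                                                     small = 0.2)),
               "sum to 1")
  expect_error(simConfig(nColonies = 2, frameIntervalH = 7), "divide 24")
  expect_error(simConfig(nColonies = -1), "counts")
})
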