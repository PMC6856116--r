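# Helper: a CellTracks with every track labelled living, from (track, frame,
# x, y) rows given in px.
livingTracks <- function(df) {
  df <- df[order(df$track, df$frame), ]
  df$obj <- stats::ave(df$frame, df$frame, FUN = seq_along)
  new("CellTracks",
      observations = df[, c("track", "frame", "obj", "x", "y")],
      labels = factor(rep("living", max(df$track)),
                      levels = c("living", "noise", "undecided")),
      maxStepPx = rep(0, max(df$track)))
}

# Helper: a ColonySet built directly from per-frame colony memberships
# (list frame -> list colonyId -> n x 2 um coordinates).
colonySetFrom <- function(memberships, config = colonyConfig()) {
  rows <- do.call(rbind, lapply(seq_along(memberships), function(fi) {
    fr <- memberships[[fi]]
    do.call(rbind, lapply(names(fr), function(id) {
      p <- fr[[id]]
      data.frame(frame = fi - 1L, colonyId = as.integer(id),
                 track = seq_len(nrow(p)), obj = seq_len(nrow(p)),
                 xUm = p[, 1], yUm = p[, 2])
    }))
  }))
  ids <- sort(unique(rows$colonyId))
  new("ColonySet", cells = rows,
      colonies = data.frame(colonyId = ids, firstFrame = 0,
                            confirmedFrame = 0, merged = FALSE,
                            mergedFrame = NA_real_),
      config = config, pixelSizeUm = 4)
}

test_that("colony confirmation follows the minimum-cells-within-diameter rule", {
  cfg <- colonyConfig()
  sq <- cbind(c(0, 40, 0, 40), c(0, 0, 40, 40))
  g <- groupCells(sq, cfg)
  expect_identical(max(g$membership), 1L)
  expect_true(g$confirmed[1])

  tri <- cbind(c(0, 10, 5), c(0, 0, 8))
  g3 <- groupCells(tri, cfg)
  expect_false(any(g3$confirmed))      # below minCells

  # 150-um spacing exceeds the 100-um single-linkage cutoff: 4 groups
  line <- cbind(c(0, 150, 300, 450), rep(0, 4))
  gl <- groupCells(line, cfg)
  expect_identical(max(gl$membership), 4L)
  expect_false(any(gl$confirmed))

  # chained at 90 um: one group; four consecutive points span 270 um < 320,
  # so the chain is confirmed
  line2 <- cbind(c(0, 90, 180, 270, 360), rep(0, 5))
  gl2 <- groupCells(line2, cfg)
  expect_identical(max(gl2$membership), 1L)
  expect_true(gl2$confirmed[1])
  # confirmation decision matches the brute-force oracle on random sets
  set.seed(5)
  for (rep in 1:20) {
    p <- cbind(runif(8, 0, 500), runif(8, 0, 500))
    g <- groupCells(p, cfg)
    for (grp in seq_len(max(g$membership))) {
      pts <- p[g$membership == grp, , drop = FALSE]
      expect_identical(g$confirmed[grp], subsetFitsOracle(pts, 320, 4))
    }
  }
})

test_that("colony identity persists through growth and split artifacts", {
  # one colony growing 4 -> 8 cells with stationary members
  base <- expand.grid(x = c(0, 5, 10, 15), y = c(0, 5)) * 1  # px; 4 um/px
  rows <- do.call(rbind, lapply(0:4, function(f) {
    n <- min(4 + f, 8)
    data.frame(track = seq_len(n), frame = f, x = base$x[seq_len(n)],
               y = base$y[seq_len(n)])
  }))
  cs <- trackColonies(livingTracks(rows), pixelSizeUm = 4)
  expect_identical(nrow(colonyInfo(cs)), 1L)
  expect_identical(colonyInfo(cs)$confirmedFrame, 0)

  # two colonies far apart keep distinct stable ids
  rows2 <- do.call(rbind, lapply(0:3, function(f) rbind(
    data.frame(track = 1:4, frame = f, x = c(0, 5, 0, 5), y = c(0, 0, 5, 5)),
    data.frame(track = 5:8, frame = f, x = 200 + c(0, 5, 0, 5),
               y = c(0, 0, 5, 5)))))
  cs2 <- trackColonies(livingTracks(rows2), pixelSizeUm = 4)
  expect_identical(nrow(colonyInfo(cs2)), 2L)
  cc <- cs2@cells
  expect_identical(length(unique(cc$colonyId[cc$xUm < 100])), 1L)
  expect_identical(length(unique(cc$colonyId[cc$xUm > 100])), 1L)

  # one frame missing a member: id retained via the remaining members
  rows3 <- do.call(rbind, lapply(0:4, function(f) {
    keep <- if (f == 2) 1:3 else 1:4
    data.frame(track = keep, frame = f, x = c(0, 5, 0, 5)[keep],
               y = c(0, 0, 5, 5)[keep])
  }))
  cs3 <- trackColonies(livingTracks(rows3), pixelSizeUm = 4)
  expect_identical(nrow(colonyInfo(cs3)), 1L)
})

test_that("merge flags flip exactly at the strict 100-um boundary", {
  mk <- function(gapUm) {
    a <- cbind(c(0, 30, 0, 30), c(0, 0, 30, 30))
    b <- a; b[, 1] <- b[, 1] + 30 + gapUm   # closest cells gapUm apart
    colonySetFrom(list(list(`1` = a, `2` = b)))
  }
  m99 <- detectMerges(mk(99))
  expect_true(all(colonyInfo(m99)$merged))
  expect_equal(colonyInfo(m99)$mergedFrame, c(0, 0))

  m100 <- detectMerges(mk(100))
  expect_false(any(colonyInfo(m100)$merged))

  # three colonies: A-B merge, C stays clear and unflagged
  a <- cbind(c(0, 30), c(0, 0)); b <- a; b[, 1] <- b[, 1] + 99
  cc <- a; cc[, 1] <- cc[, 1] + 2000
  m3 <- detectMerges(colonySetFrom(list(list(`1` = a, `2` = b, `3` = cc))))
  expect_identical(colonyInfo(m3)$merged, c(TRUE, TRUE, FALSE))
})

test_that("merged colonies flag from first violation and stay flagged", {
  a <- cbind(c(0, 30), c(0, 0))
  farB <- cbind(c(500, 530), c(0, 0))
  nearB <- cbind(c(80, 110), c(0, 0))     # 50 um from a's closest cell
  cs <- colonySetFrom(list(
    list(`1` = a, `2` = farB),
    list(`1` = a, `2` = nearB),
    list(`1` = a, `2` = farB)))
  m <- detectMerges(cs)
  expect_true(all(colonyInfo(m)$merged))
  expect_equal(colonyInfo(m)$mergedFrame, c(1, 1))
})

test_that("growth curves count living members at day reference frames", {
  # constant colony of 4 cells over 2 days at 6-h frames
  sq <- data.frame(x = c(0, 5, 0, 5), y = c(0, 0, 5, 5))
  rows <- do.call(rbind, lapply(0:8, function(f)
    data.frame(track = 1:4, frame = f, x = sq$x, y = sq$y)))
  cs <- detectMerges(trackColonies(livingTracks(rows), pixelSizeUm = 4))
  gc <- buildGrowthCurves(cs, durationDays = 2, frameIntervalH = 6)
  expect_equal(unname(growthCounts(gc)[1, ]), c(4, 4))

  # doubling each day: 4 at day 1, 8 at day 2
  rows2 <- do.call(rbind, lapply(0:8, function(f) {
    n <- if (f < 4) 2 else if (f < 8) 4 else 8
    data.frame(track = seq_len(n), frame = f,
               x = (seq_len(n) - 1) %% 4 * 5, y = (seq_len(n) - 1) %/% 4 * 5)
  }))
  cs2 <- detectMerges(trackColonies(livingTracks(rows2), pixelSizeUm = 4))
  gc2 <- buildGrowthCurves(cs2, durationDays = 2, frameIntervalH = 6)
  expect_equal(unname(growthCounts(gc2)[1, ]), c(4, 8))

  # a missing reference-frame observation carries the last known count
  rows3 <- rows[rows$frame != 8, ]
  cs3 <- detectMerges(trackColonies(livingTracks(rows3), pixelSizeUm = 4))
  expect_warning(gc3 <- buildGrowthCurves(cs3, 2, 6), "nearest known")
  expect_equal(unname(growthCounts(gc3)[1, ]), c(4, 4))
})

test_that("excluding merged colonies does not alter remaining counts", {
  a <- cbind(c(0, 30, 0, 30), c(0, 0, 30, 30))
  b <- a; b[, 1] <- b[, 1] + 95          # merges with a
  cfar <- a; cfar[, 1] <- cfar[, 1] + 3000
  frames <- lapply(1:9, function(f) list(`1` = a, `2` = b, `3` = cfar))
  withB <- detectMerges(colonySetFrom(frames))
  gcWith <- buildGrowthCurves(withB, 2, 6)
  framesNoB <- lapply(1:9, function(f) list(`1` = a, `3` = cfar))
  noB <- detectMerges(colonySetFrom(framesNoB))
  gcNo <- buildGrowthCurves(noB, 2, 6)
  # colony 3 appears in both and with identical counts
  rdW <- SummarizedExperiment::rowData(gcWith)
  rdN <- SummarizedExperiment::rowData(gcNo)
  expect_true(3 %in% rdW$colonyId && 3 %in% rdN$colonyId)
  expect_equal(growthCounts(gcWith)[rdW$colonyId == 3, ],
               growthCounts(gcNo)[rdN$colonyId == 3, ])
  # merged colonies are absent from the curve set
  expect_false(any(c(1, 2) %in% rdW$colonyId))
})
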