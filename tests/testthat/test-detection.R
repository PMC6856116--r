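test_that("background correction fixes flat and ramped illumination", {
  # flat frame is a fixed point
  f <- matrix(117, 80, 80)
  expect_equal(correctBackground(f, 8), f)

  # pure linear ramp flattens to < 1% of its amplitude
  ramp <- matrix(rep(seq(0, 60, length.out = 200), each = 200), 200, 200)
  out <- correctBackground(ramp, 25)
  expect_lt(sd(out), 0.01 * 60)

  # a dark disc on a ramp keeps its contrast against the local background
  m <- matrix(rep(seq(100, 160, length.out = 200), each = 200), 200, 200)
  ctr <- c(100, 100); rad <- 6
  idx <- which((row(m) - ctr[1])^2 + (col(m) - ctr[2])^2 <= rad^2)
  m[idx] <- m[idx] - 30
  out <- correctBackground(m, 25)
  ring <- which((row(m) - ctr[1])^2 + (col(m) - ctr[2])^2 > (rad + 3)^2 &
                  (row(m) - ctr[1])^2 + (col(m) - ctr[2])^2 <= (rad + 8)^2)
  contrastBefore <- mean(m[ring]) - mean(m[idx])
  contrastAfter <- mean(out[ring]) - mean(out[idx])
  expect_lt(abs(contrastAfter - contrastBefore) / contrastBefore, 0.1)

  expect_error(correctBackground(matrix(0, 30, 30), 20), "too large")
})

test_that("shape restoration prefers dark interiors ringed by bright halos", {
  mkblob <- function(inner, rim) {
    m <- matrix(128, 120, 120)
    d2 <- (row(m) - 60)^2 + (col(m) - 60)^2
    m[d2 <= 64] <- 128 + inner
    m[d2 > 64 & d2 <= 121] <- 128 + rim
    m + matrix(rnorm(120 * 120, 0, 1), 120, 120)
  }
  set.seed(1)
  cell <- restoreCellShape(mkblob(-25, +25))
  inverted <- restoreCellShape(mkblob(+25, -25))
  expect_gt(max(cell), max(inverted))
  # response inside the cell dominates the far background
  inside <- cell[52:68, 52:68]
  far <- cell[c(1:20, 100:120), c(1:20, 100:120)]
  expect_gt(min(inside[9, 9]), max(far) * 2)

  # background-only frame: response stays below the detection floor
  set.seed(2)
  noise <- matrix(128 + rnorm(120 * 120, 0, 1.5), 120, 120)
  expect_lt(max(restoreCellShape(noise)), 8)
})

test_that("binarization extracts area-filtered 8-connected objects", {
  resp <- matrix(0, 100, 100)
  expect_identical(nrow(binarizeAndExtract(resp)$objects), 0L)

  # two discs of radius 5, 50 px apart: two objects of area ~ pi * 25
  d2a <- (row(resp) - 30)^2 + (col(resp) - 30)^2
  d2b <- (row(resp) - 30)^2 + (col(resp) - 80)^2
  resp[d2a <= 25 | d2b <= 25] <- 20
  ex <- binarizeAndExtract(resp, thresholdMethod = "fixed", threshold = 10,
                           minAreaPx = 20)
  expect_identical(nrow(ex$objects), 2L)
  expect_true(all(abs(ex$objects$area - pi * 25) / (pi * 25) < 0.15))
  # pixel sets are consistent with centroids and areas
  expect_equal(vapply(ex$pixelSets, nrow, integer(1)), ex$objects$area)
  expect_equal(mean(ex$pixelSets[[1]][, 2]), ex$objects$x[1])

  # a 10-px object dies to the area filter
  small <- matrix(0, 50, 50); small[20, 20:29] <- 20
  expect_identical(
    nrow(binarizeAndExtract(small, thresholdMethod = "fixed", threshold = 10,
                            minAreaPx = 20)$objects), 0L)

  # diagonal connectivity: a diagonal chain is one object
  diag <- matrix(0, 60, 60)
  for (i in 1:30) diag[i + 10, i + 10] <- 20
  exd <- binarizeAndExtract(diag, thresholdMethod = "fixed", threshold = 10,
                            minAreaPx = 20)
  expect_identical(nrow(exd$objects), 1L)
})

test_that("raising the minimum area never increases the object count", {
  set.seed(8)
  resp <- matrix(0, 150, 150)
  for (k in 1:12) {
    ctr <- runif(2, 15, 135); rad <- runif(1, 2, 7)
    resp[(row(resp) - ctr[1])^2 + (col(resp) - ctr[2])^2 <= rad^2] <- 20
  }
  counts <- vapply(c(5, 10, 20, 40, 80), function(a)
    nrow(binarizeAndExtract(resp, thresholdMethod = "fixed", threshold = 10,
                            minAreaPx = a)$objects), integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("segmentation is translation-equivariant on a rendered cell", {
  sc <- makeTinyScene(seed = 31, nColonies = 1, days = 1,
                      shape = c(220L, 220L), debris = 0)
  f <- sc$seqs@frames[[1]]
  run <- function(m) {
    d <- detectCells(ImageSequence(list(m), 4, 6), kernelRadiusPx = 25)
    detectedObjects(d)
  }
  o1 <- run(f)
  shifted <- matrix(min(f), nrow(f), ncol(f))
  dr <- 7; dc <- 11
  shifted[(1 + dr):nrow(f), (1 + dc):ncol(f)] <-
    f[1:(nrow(f) - dr), 1:(ncol(f) - dc)]
  # fill the vacated border with the frame's own edge rows/cols
  shifted[1:dr, ] <- shifted[dr + 1, ][col(shifted[1:dr, , drop = FALSE])]
  shifted[, 1:dc] <- shifted[, dc + 1][row(shifted[, 1:dc, drop = FALSE])]
  o2 <- run(shifted)
  expect_identical(nrow(o1), nrow(o2))
  o1 <- o1[order(o1$x), ]; o2 <- o2[order(o2$x), ]
  expect_true(all(abs(o2$x - o1$x - dc) <= 0.5))
  expect_true(all(abs(o2$y - o1$y - dr) <= 0.5))
})

test_that("detection recovers rendered cells with high precision and recall", {
  sc <- makeTinyScene(seed = 47, nColonies = 3, days = 3,
                      shape = c(420L, 420L), debris = 0)
  det <- detectCells(sc$seqs, keepPixelFrames = integer(0))
  ob <- detectedObjects(det)
  for (f in c(0, 6, 12)) {
    tc <- sc$truth@cells[sc$truth@cells$birthH <= f * 6, ]
    d <- ob[ob$frame == f, ]
    d2 <- outer(d$x, tc$x, "-")^2 + outer(d$y, tc$y, "-")^2
    expect_gte(mean(apply(d2, 1, min) <= 64), 0.9)  # precision
    expect_gte(mean(apply(d2, 2, min) <= 64), 0.9)  # recall
  }
})
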