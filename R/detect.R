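# Per-frame segmentation of phase-contrast frames: background correction,
# cell-shape restoration from the dark-interior / bright-halo signature,
# and binarization into connected objects.

#' Flatten the background brightness gradient of a frame
#'
#' Estimates the smooth background on a coarse grid of square blocks of
#' side \code{2 * kernelRadiusPx + 1}: each block contributes its median
#' gray level (robust to dark cell interiors and bright halo rims alike,
#' which together stay well under half the pixels even inside a dense
#' colony), and the grid is interpolated bilinearly back to full
#' resolution. Returns \code{frame - background + mean(background)},
#' clipped to the input range. A linear illumination ramp is reproduced
#' exactly by the block medians, so ramps flatten to numerical noise.
#'
#' @param frame numeric matrix of gray levels.
#' @param kernelRadiusPx background neighbourhood radius in px; must exceed
#'   the largest cell radius and the block must fit inside the frame.
#' @return numeric matrix, same shape and range as the input.
#' @examples
#' f <- matrix(100, 64, 64)
#' all(correctBackground(f, 8) == 100)
#' @export
correctBackground <- function(frame, kernelRadiusPx = 25) {
  r <- as.integer(kernelRadiusPx)
  bs <- 2L * r + 1L
  if (bs >= min(dim(frame)))
    stop("kernelRadiusPx too large for frame of size ",
         paste(dim(frame), collapse = "x"))
  lo <- min(frame); hi <- max(frame)
  bg <- blockMedianBackground(frame, bs)
  out <- frame - bg + mean(bg)
  pmin(pmax(out, lo), hi)
}

# Median of each bs x bs block, interpolated bilinearly to full size.
blockMedianBackground <- function(m, bs) {
  H <- nrow(m); W <- ncol(m)
  rb <- blockBounds(H, bs)
  cb <- blockBounds(W, bs)
  coarse <- matrix(0, nrow(rb), nrow(cb))
  for (i in seq_len(nrow(rb)))
    for (j in seq_len(nrow(cb)))
      coarse[i, j] <- median(m[rb[i, 1]:rb[i, 2], cb[j, 1]:cb[j, 2]])
  rowI <- interpWeights((rb[, 1] + rb[, 2]) / 2, H)
  colI <- interpWeights((cb[, 1] + cb[, 2]) / 2, W)
  # interpolate along rows, then columns
  tall <- coarse[rowI$lo, , drop = FALSE] * (1 - rowI$w) +
    coarse[rowI$hi, , drop = FALSE] * rowI$w
  tall[, colI$lo, drop = FALSE] * rep(1 - colI$w, each = H) +
    tall[, colI$hi, drop = FALSE] * rep(colI$w, each = H)
}

# Start/end indices of blocks of size bs covering 1..n (last block absorbs
# the remainder so no block is smaller than bs).
blockBounds <- function(n, bs) {
  starts <- seq(1L, max(n - bs + 1L, 1L), by = bs)
  ends <- pmin(starts + bs - 1L, n)
  ends[length(ends)] <- n
  cbind(starts, ends)
}

# For each target coordinate 1..n, the bracketing block centres and the
# interpolation weight of the upper one; border bands extrapolate linearly
# from the two nearest centres so a pure ramp stays exact to the frame edge.
interpWeights <- function(centers, n) {
  x <- seq_len(n)
  if (length(centers) == 1)
    return(list(lo = rep(1L, n), hi = rep(1L, n), w = rep(0, n)))
  lo <- findInterval(x, centers)
  lo <- pmin(pmax(lo, 1L), length(centers) - 1L)
  hi <- lo + 1L
  w <- (x - centers[lo]) / (centers[hi] - centers[lo])
  list(lo = lo, hi = hi, w = w)
}

#' Restore cell bodies from a background-corrected frame
#'
#' Phase-contrast cells appear as dark interiors surrounded by a bright halo
#' rim. The response map combines both cues: the darkness of each pixel
#' below the background level (smoothed at \code{interiorSigmaPx}), boosted
#' where the pixel lies inside a region enclosed by bright halo rims.
#' Pixels brighter than the background contribute nothing, so an
#' inverted-contrast blob scores lower than a true cell.
#'
#' @param frame background-corrected numeric matrix.
#' @param haloSigmaPx smoothing scale (px) for the halo-enclosure cue.
#' @param interiorSigmaPx smoothing scale (px) for the darkness cue.
#' @param haloK rim detection threshold in robust standard deviations above
#'   the background level.
#' @param haloBoost multiplicative weight of the halo-enclosure cue.
#' @return non-negative numeric matrix (gray-level units), high inside cells.
#' @export
restoreCellShape <- function(frame, haloSigmaPx = 2, interiorSigmaPx = 2,
                             haloK = 6, haloBoost = 1) {
  m <- median(frame)
  darkness <- pmax(m - frame, 0)
  dsm <- EBImage::gblur(darkness, sigma = interiorSigmaPx)
  s <- mad(frame)
  if (s == 0) s <- 1
  rims <- frame > m + haloK * s
  enclosed <- EBImage::fillHull(rims) & !rims
  encSm <- EBImage::gblur(enclosed * 1.0, sigma = haloSigmaPx)
  resp <- dsm * (1 + haloBoost * pmin(encSm, 1))
  pmax(resp, 0)
}

# Merge 4-connected labels that touch diagonally, yielding 8-connected
# components (EBImage::bwlabel is 4-connected).
label8 <- function(mask) {
  lab <- EBImage::bwlabel(mask)
  n <- max(lab)
  if (n <= 1) return(lab)
  H <- nrow(lab); W <- ncol(lab)
  a1 <- lab[-H, -W]; b1 <- lab[-1, -1]   # NW-SE diagonal pairs
  a2 <- lab[-H, -1]; b2 <- lab[-1, -W]   # NE-SW diagonal pairs
  pairs <- rbind(cbind(a1[a1 > 0 & b1 > 0 & a1 != b1], b1[a1 > 0 & b1 > 0 & a1 != b1]),
                 cbind(a2[a2 > 0 & b2 > 0 & a2 != b2], b2[a2 > 0 & b2 > 0 & a2 != b2]))
  if (!nrow(pairs)) return(lab)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (k in seq_len(nrow(pairs))) {
    ra <- find(pairs[k, 1]); rb <- find(pairs[k, 2])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  roots <- vapply(seq_len(n), find, integer(1))
  remap <- match(roots, sort(unique(roots)))
  lab[lab > 0] <- remap[lab[lab > 0]]
  lab
}

#' Binarize a response map and extract objects
#'
#' Thresholds the restored-shape response (Otsu by default, with a fixed
#' gray-level floor so empty frames stay empty) and extracts 8-connected
#' components of at least \code{minAreaPx} pixels. Objects are returned
#' sorted by bounding-box (minRow, minCol); coordinates are 0-based,
#' x = column, y = row.
#'
#' @param response non-negative numeric matrix from
#'   \code{\link{restoreCellShape}}.
#' @param thresholdMethod "otsu" or "fixed".
#' @param threshold fixed threshold (gray levels) when
#'   \code{thresholdMethod = "fixed"}.
#' @param minAreaPx minimum object area in pixels.
#' @param thresholdFloor lower bound applied to the Otsu threshold
#'   (gray levels); guards against noise-only frames.
#' @param frameIndex 0-based frame index recorded on each object.
#' @param splitTouching split touching cells by watershedding the response
#'   map inside the mask (two cells whose bodies abut segment as one
#'   connected component otherwise).
#' @param splitTolerance watershed tolerance (response units): minimum
#'   peak-to-saddle drop for two catchment basins to stay separate objects.
#' @return list with \code{objects} (data.frame: frame, obj, x, y, area,
#'   minRow, minCol, maxRow, maxCol) and \code{pixelSets} (list of n x 2
#'   matrices of 0-based (row, col), parallel to objects).
#' @export
binarizeAndExtract <- function(response, thresholdMethod = c("otsu", "fixed"),
                               threshold = NULL, minAreaPx = 20,
                               thresholdFloor = 8, frameIndex = 0L,
                               splitTouching = FALSE, splitTolerance = 8) {
  thresholdMethod <- match.arg(thresholdMethod)
  stopifnot(all(is.finite(response)))
  mx <- max(response)
  if (thresholdMethod == "fixed") {
    if (is.null(threshold)) stop("fixed thresholding needs `threshold`")
    th <- threshold
  } else {
    th <- if (mx <= 0) Inf else
      EBImage::otsu(response / mx, range = c(0, 1)) * mx
    th <- max(th, thresholdFloor)
  }
  mask <- response > th
  empty <- list(objects = data.frame(frame = integer(0), obj = integer(0),
                                     x = numeric(0), y = numeric(0),
                                     area = integer(0), minRow = integer(0),
                                     minCol = integer(0), maxRow = integer(0),
                                     maxCol = integer(0)),
                pixelSets = list())
  if (!any(mask)) return(empty)
  lab <- if (splitTouching) {
    w <- EBImage::watershed(response * mask, tolerance = splitTolerance,
                            ext = 1)
    as.matrix(EBImage::imageData(w))
  } else {
    label8(mask)
  }
  idx <- which(lab > 0)
  comp <- lab[idx]
  rows <- ((idx - 1L) %% nrow(lab))        # 0-based row
  cols <- ((idx - 1L) %/% nrow(lab))       # 0-based col
  areas <- tabulate(comp)
  keep <- which(areas >= minAreaPx)
  if (!length(keep)) return(empty)
  ord <- order(comp)
  comp <- comp[ord]; rows <- rows[ord]; cols <- cols[ord]
  bnd <- c(0L, cumsum(areas))
  objs <- lapply(keep, function(k) {
    sel <- (bnd[k] + 1L):bnd[k + 1L]
    r <- rows[sel]; cc <- cols[sel]
    list(x = mean(cc), y = mean(r), area = length(sel),
         minRow = min(r), minCol = min(cc), maxRow = max(r), maxCol = max(cc),
         px = cbind(row = r, col = cc))
  })
  df <- data.frame(frame = frameIndex,
                   obj = NA_integer_,
                   x = vapply(objs, `[[`, numeric(1), "x"),
                   y = vapply(objs, `[[`, numeric(1), "y"),
                   area = vapply(objs, `[[`, integer(1), "area"),
                   minRow = vapply(objs, `[[`, numeric(1), "minRow"),
                   minCol = vapply(objs, `[[`, numeric(1), "minCol"),
                   maxRow = vapply(objs, `[[`, numeric(1), "maxRow"),
                   maxCol = vapply(objs, `[[`, numeric(1), "maxCol"))
  o <- order(df$minRow, df$minCol)
  df <- df[o, , drop = FALSE]
  df$obj <- seq_len(nrow(df))
  rownames(df) <- NULL
  list(objects = df, pixelSets = lapply(objs, `[[`, "px")[o])
}

#' Detect candidate cells in every frame of a sequence
#'
#' Runs background correction, shape restoration and binarization on each
#' frame. Pixel sets (needed for the long-axis statistic) are retained only
#' for the frames in \code{keepPixelFrames} to bound memory.
#'
#' @param seq an \linkS4class{ImageSequence}.
#' @param kernelRadiusPx background-estimation disc radius (px).
#' @param haloSigmaPx,interiorSigmaPx,haloK,haloBoost see
#'   \code{\link{restoreCellShape}}.
#' @param thresholdMethod,threshold,minAreaPx,thresholdFloor,splitTouching,splitTolerance
#'   see \code{\link{binarizeAndExtract}}.
#' @param keepPixelFrames 0-based frame indices whose pixel sets to retain;
#'   NULL keeps all.
#' @param verbose log per-frame object counts.
#' @return a \linkS4class{DetectionSet}.
#' @export
detectCells <- function(seq, kernelRadiusPx = 25, haloSigmaPx = 2,
                        interiorSigmaPx = 2, haloK = 6, haloBoost = 1,
                        thresholdMethod = "otsu", threshold = NULL,
                        minAreaPx = 20, thresholdFloor = 8,
                        splitTouching = FALSE, splitTolerance = 8,
                        keepPixelFrames = NULL, verbose = FALSE) {
  stopifnot(is(seq, "ImageSequence"))
  nF <- length(seq@frames)
  keepAll <- is.null(keepPixelFrames)
  objs <- vector("list", nF)
  px <- list()
  for (f in seq_len(nF)) {
    corrected <- correctBackground(seq@frames[[f]], kernelRadiusPx)
    resp <- restoreCellShape(corrected, haloSigmaPx, interiorSigmaPx,
                             haloK, haloBoost)
    ext <- binarizeAndExtract(resp, thresholdMethod, threshold, minAreaPx,
                              thresholdFloor, frameIndex = f - 1L,
                              splitTouching = splitTouching,
                              splitTolerance = splitTolerance)
    objs[[f]] <- ext$objects
    if (keepAll || (f - 1L) %in% keepPixelFrames)
      px[[paste0("f", f - 1L)]] <- ext$pixelSets
    if (verbose)
      message(sprintf("frame %d: %d objects", f - 1L, nrow(ext$objects)))
  }
  new("DetectionSet",
      objects = do.call(rbind, objs),
      pixelSets = px,
      pixelFrames = if (keepAll) seq_len(nF) - 1 else
        intersect(keepPixelFrames, seq_len(nF) - 1),
      pixelSizeUm = seq@pixelSizeUm)
}
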