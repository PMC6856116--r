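# Synthetic colony time-lapse generator: growth-curve simulation, cell
# placement with ground truth, and phase-contrast-like rendering.

#' Build a simulation configuration
#'
#' @param nColonies number of colonies.
#' @param seed integer seed driving every stochastic step.
#' @param frameIntervalH hours between frames (must divide 24).
#' @param durationDays culture duration in days.
#' @param pixelSizeUm micrometres per pixel.
#' @param frameShape c(height, width) in pixels.
#' @param groupMix named proportions of the large/medium/small archetypes.
#' @param divisionIntervalH named mean waiting time between divisions (h).
#' @param lagH named mean lag before the first division (h).
#' @param debrisCount teleporting debris objects per frame.
#' @param debrisJumpPx minimum per-frame debris displacement (px).
#' @param backgroundGradientAmplitude background gradient amplitude (gray levels).
#' @param cellContrast interior darkness below local background (gray levels).
#' @param haloContrast rim brightness above local background (gray levels).
#' @param noiseSd additive Gaussian noise sd (gray levels).
#' @param cellSpacingPx minimum cell centre spacing within a colony (px).
#' @param jitterPx per-frame rendered centroid jitter (px); 0 disables.
#' @return a validated \linkS4class{SimConfig}.
#' @examples
#' cfg <- simConfig(nColonies = 5, seed = 1)
#' @export
simConfig <- function(nColonies = 20,
                      seed = 1,
                      frameIntervalH = 6,
                      durationDays = 14,
                      pixelSizeUm = 4,
                      frameShape = c(1024L, 1024L),
                      groupMix = c(large = 0.15, medium = 0.55, small = 0.30),
                      divisionIntervalH = c(large = 54, medium = 72, small = 144),
                      lagH = c(large = 24, medium = 48, small = 72),
                      debrisCount = 10,
                      debrisJumpPx = 40,
                      backgroundGradientAmplitude = 20,
                      cellContrast = 25,
                      haloContrast = 25,
                      noiseSd = 1.5,
                      cellSpacingPx = 16,
                      jitterPx = 0) {
  new("SimConfig",
      nColonies = nColonies, seed = seed, frameIntervalH = frameIntervalH,
      durationDays = durationDays, pixelSizeUm = pixelSizeUm,
      frameShape = frameShape, groupMix = groupMix,
      divisionIntervalH = divisionIntervalH, lagH = lagH,
      debrisCount = debrisCount, debrisJumpPx = debrisJumpPx,
      backgroundGradientAmplitude = backgroundGradientAmplitude,
      cellContrast = cellContrast, haloContrast = haloContrast,
      noiseSd = noiseSd, cellSpacingPx = cellSpacingPx, jitterPx = jitterPx)
}

nFramesOf <- function(config) {
  as.integer(config@durationDays * 24 / config@frameIntervalH) + 1L
}

timestampsOf <- function(config) {
  (seq_len(nFramesOf(config)) - 1) * config@frameIntervalH
}

# Birth times and parents for one colony. The founder is cell 1, born at 0.
# Divisions follow a branching (Yule-type) process: after the colony lag,
# each cell waits an exponential time with the archetype mean, then splits
# into itself plus a daughter. `stochastic = FALSE` makes every cell divide
# exactly every `tau` hours after the lag (synchronous doubling).
simulateBirths <- function(tau, lag, tEnd, stochastic = TRUE, maxCells = 50000L) {
  birth <- 0
  parent <- 0L
  if (!is.finite(tau)) return(data.frame(birthH = birth, parent = parent))
  if (!stochastic) {
    epochs <- seq(lag + tau, tEnd, by = tau)
    for (t in epochs) {
      n <- length(birth)
      birth <- c(birth, rep(t, n))
      parent <- c(parent, seq_len(n))
      if (length(birth) > maxCells) stop("simulated colony exceeded maxCells")
    }
    return(data.frame(birthH = birth, parent = parent))
  }
  nextDiv <- lag + rexp(1, rate = 1 / tau)
  while (TRUE) {
    i <- which.min(nextDiv)
    t <- nextDiv[i]
    if (t > tEnd) break
    birth <- c(birth, t)
    parent <- c(parent, i)
    nextDiv[i] <- t + rexp(1, rate = 1 / tau)
    nextDiv <- c(nextDiv, t + rexp(1, rate = 1 / tau))
    if (length(birth) > maxCells) stop("simulated colony exceeded maxCells")
  }
  data.frame(birthH = birth, parent = parent)
}

#' Simulate per-colony daily growth curves
#'
#' Draws an archetype for each colony, simulates its division process, and
#' tabulates the cell count at each day's reference frame (the last frame of
#' each 24-h window). Counts start at 1 cell per colony and are
#' non-decreasing (no cell death is modelled).
#'
#' @param config a \linkS4class{SimConfig}.
#' @param stochastic if FALSE, cells divide deterministically every
#'   \code{divisionIntervalH} hours after the lag (useful for exact checks).
#' @return list with \code{counts} (nColonies x durationDays integer matrix)
#'   and \code{archetype} (factor per colony).
#' @examples
#' gc <- simulateGrowthCurves(simConfig(nColonies = 10, seed = 7))
#' dim(gc$counts)
#' @export
simulateGrowthCurves <- function(config, stochastic = TRUE) {
  validObject(config)
  withSeed(config@seed, {
    arch <- drawArchetypes(config)
    tEnd <- config@durationDays * 24
    counts <- matrix(0L, config@nColonies, config@durationDays,
                     dimnames = list(NULL, paste0("day", seq_len(config@durationDays))))
    for (i in seq_len(config@nColonies)) {
      a <- as.character(arch[i])
      lag <- colonyLag(config@lagH[[a]], stochastic)
      b <- simulateBirths(config@divisionIntervalH[[a]], lag, tEnd, stochastic)
      counts[i, ] <- vapply(seq_len(config@durationDays),
                            function(d) sum(b$birthH <= 24 * d), integer(1))
    }
    list(counts = counts, archetype = arch)
  })
}

drawArchetypes <- function(config) {
  factor(sample(names(config@groupMix), config@nColonies, replace = TRUE,
                prob = config@groupMix),
         levels = names(config@groupMix))
}

# Colony lag: gamma-distributed around the archetype mean (shape 4) so
# colonies start dividing at staggered but not wildly dispersed times.
colonyLag <- function(meanLag, stochastic = TRUE) {
  if (!stochastic || meanLag == 0) return(meanLag)
  rgamma(1, shape = 4, scale = meanLag / 4)
}

# Cell body ellipses: lognormal long axis around 40 um (10 px at 4 um/px),
# clamped to 32-48 um so no interior falls below the detectable area.
drawCellShape <- function(n) {
  major <- pmin(pmax(rlnorm(n, log(10), 0.12), 8), 12)
  minor <- major * runif(n, 0.55, 0.8)
  data.frame(majorAxisPx = major, minorAxisPx = minor,
             thetaRad = runif(n, 0, pi))
}

# Place a daughter near its mother: candidate spots on rings around the
# mother, then around other colony cells (nearest the mother first); at the
# first ring offering free spots (>= `spacing` px from every existing
# cell), take the one closest to the colony centroid, which keeps colonies
# compact discs rather than sprawling arms. Ring radii are capped at
# 1.3 x spacing so nearest-neighbour spacings never exceed the colony
# grouping cutoff (colonies stay single-linkage-connected at 100 um).
placeDaughter <- function(pos, mother, spacing) {
  ctr <- colMeans(pos)
  dm <- (pos[, 1] - pos[mother, 1])^2 + (pos[, 2] - pos[mother, 2])^2
  anchors <- pos[order(dm), , drop = FALSE]
  for (aIdx in seq_len(nrow(anchors))) {
    anchor <- anchors[aIdx, ]
    for (mult in c(1, 1.15, 1.3)) {
      rad <- spacing * mult
      ang <- runif(1, 0, 2 * pi) + seq(0, 2 * pi, length.out = 25)[-25]
      cand <- cbind(anchor[1] + rad * cos(ang), anchor[2] + rad * sin(ang))
      free <- vapply(seq_len(nrow(cand)), function(k) {
        all((pos[, 1] - cand[k, 1])^2 + (pos[, 2] - cand[k, 2])^2 >=
              (spacing - 1e-9)^2)
      }, logical(1))
      if (any(free)) {
        cand <- cand[free, , drop = FALSE]
        d2c <- (cand[, 1] - ctr[1])^2 + (cand[, 2] - ctr[2])^2
        return(cand[which.min(d2c), ])
      }
    }
  }
  stop("could not place daughter cell; colony too crowded")
}

#' Simulate colonies with cell positions and full ground truth
#'
#' Simulates each colony's division process, places cells in the frame
#' (daughters appear about one cell spacing from their mothers; colonies are
#' laid out so that no two come within the merge distance), draws per-cell
#' ellipse shapes, and generates teleporting debris positions for every
#' frame. The result carries everything needed both to render images
#' (\code{\link{renderSequence}}) and to score a pipeline run against truth.
#'
#' @param config a \linkS4class{SimConfig}.
#' @return a \linkS4class{SimTruth}.
#' @examples
#' tr <- simulateColonies(simConfig(nColonies = 3, seed = 2, durationDays = 3,
#'                                  frameShape = c(360L, 360L), debrisCount = 2))
#' head(tr@cells)
#' @export
simulateColonies <- function(config) {
  validObject(config)
  withSeed(config@seed, {
    arch <- drawArchetypes(config)
    tEnd <- config@durationDays * 24
    spacing <- config@cellSpacingPx

    perColony <- vector("list", config@nColonies)
    lags <- numeric(config@nColonies)
    for (i in seq_len(config@nColonies)) {
      a <- as.character(arch[i])
      lags[i] <- colonyLag(config@lagH[[a]])
      b <- simulateBirths(config@divisionIntervalH[[a]], lags[i], tEnd)
      pos <- matrix(0, nrow(b), 2)  # local coords, founder at origin
      if (nrow(b) > 1) {
        for (j in 2:nrow(b)) {
          pos[j, ] <- placeDaughter(pos[seq_len(j - 1), , drop = FALSE],
                                    b$parent[j], spacing)
        }
      }
      perColony[[i]] <- cbind(b, x = pos[, 1], y = pos[, 2])
    }

    radii <- vapply(perColony, function(cc) {
      max(sqrt(cc$x^2 + cc$y^2)) + 10
    }, numeric(1))
    centers <- placeColonies(radii, config@frameShape, clearancePx = 30)

    cells <- if (config@nColonies == 0) {
      data.frame(cellId = integer(0), colonyId = integer(0),
                 birthH = numeric(0), x = numeric(0), y = numeric(0),
                 majorAxisPx = numeric(0), minorAxisPx = numeric(0),
                 thetaRad = numeric(0))
    } else {
      cc <- do.call(rbind, lapply(seq_len(config@nColonies), function(i) {
        ci <- perColony[[i]]
        data.frame(colonyId = i, birthH = ci$birthH,
                   x = ci$x + centers[i, 1], y = ci$y + centers[i, 2])
      }))
      cbind(cellId = seq_len(nrow(cc)), cc, drawCellShape(nrow(cc)))
    }

    colonies <- data.frame(colonyId = seq_len(config@nColonies),
                           archetype = as.character(arch),
                           founderX = centers[, 1], founderY = centers[, 2],
                           lagH = lags)

    daily <- matrix(0L, config@nColonies, config@durationDays,
                    dimnames = list(NULL,
                                    paste0("day", seq_len(config@durationDays))))
    for (i in seq_len(config@nColonies))
      daily[i, ] <- vapply(seq_len(config@durationDays), function(d)
        sum(cells$colonyId == i & cells$birthH <= 24 * d), integer(1))

    debris <- simulateDebris(config, cells, timestampsOf(config))

    new("SimTruth", cells = cells, colonies = colonies, debris = debris,
        dailyCounts = daily,
        mergeEvents = data.frame(frame = integer(0), colonyA = integer(0),
                                 colonyB = integer(0)),
        config = config)
  })
}

# Layout of colony centres, largest first: centres should stay clear of
# the frame border and of each other by the sum of final radii plus a
# merge clearance (> the 100-um merge rule at the default pixel size).
# When a crowded draw makes full clearance impossible, the centre with the
# largest minimum margin is used instead: the colonies involved may
# eventually merge, which the analysis pipeline detects and excludes, just
# as it would in a real culture.
placeColonies <- function(radii, frameShape, clearancePx = 30,
                          maxAttempts = 400L) {
  n <- length(radii)
  centers <- matrix(NA_real_, n, 2)
  ord <- order(radii, decreasing = TRUE)
  H <- frameShape[1]; W <- frameShape[2]
  for (i in ord) {
    margin <- min(radii[i] + 6, (min(H, W) - 2) / 2)
    best <- NULL
    bestMargin <- -Inf
    placed <- which(!is.na(centers[, 1]))
    for (att in seq_len(maxAttempts)) {
      cand <- c(runif(1, margin, W - margin), runif(1, margin, H - margin))
      m <- if (!length(placed)) Inf else
        min(sqrt((centers[placed, 1] - cand[1])^2 +
                 (centers[placed, 2] - cand[2])^2) -
              (radii[placed] + radii[i] + clearancePx))
      if (m > bestMargin) {
        bestMargin <- m
        best <- cand
        if (m >= 0) break
      }
    }
    centers[i, ] <- best
  }
  centers
}

# Debris teleports: fresh uniform position every frame, at least
# `debrisJumpPx` from its previous position and 20 px clear of any cell
# alive in that frame (so persistence, not appearance, distinguishes it).
simulateDebris <- function(config, cells, tsH) {
  nDeb <- config@debrisCount
  if (nDeb == 0)
    return(data.frame(frame = integer(0), debrisId = integer(0),
                      x = numeric(0), y = numeric(0),
                      majorAxisPx = numeric(0), minorAxisPx = numeric(0),
                      thetaRad = numeric(0)))
  H <- config@frameShape[1]; W <- config@frameShape[2]
  shapes <- drawCellShape(nDeb)
  out <- vector("list", length(tsH))
  prev <- matrix(NA_real_, nDeb, 2)
  for (f in seq_along(tsH)) {
    alive <- cells[cells$birthH <= tsH[f], c("x", "y"), drop = FALSE]
    posf <- matrix(NA_real_, nDeb, 2)
    for (k in seq_len(nDeb)) {
      for (att in 1:2000) {
        cand <- c(runif(1, 8, W - 8), runif(1, 8, H - 8))
        if (!is.na(prev[k, 1]) &&
            sum((cand - prev[k, ])^2) < config@debrisJumpPx^2) next
        if (nrow(alive) &&
            min((alive$x - cand[1])^2 + (alive$y - cand[2])^2) < 20^2) next
        posf[k, ] <- cand
        break
      }
      if (is.na(posf[k, 1])) stop("could not place debris; frame too crowded")
    }
    prev <- posf
    out[[f]] <- data.frame(frame = f - 1L, debrisId = seq_len(nDeb),
                           x = posf[, 1], y = posf[, 2],
                           majorAxisPx = shapes$majorAxisPx,
                           minorAxisPx = shapes$minorAxisPx,
                           thetaRad = shapes$thetaRad)
  }
  do.call(rbind, out)
}

# Smooth low-frequency background: a tilted plane plus one sinusoid, with
# stated peak-to-peak amplitude, constant across frames (illumination
# gradients do not flicker).
makeBackground <- function(config) {
  H <- config@frameShape[1]; W <- config@frameShape[2]
  A <- config@backgroundGradientAmplitude
  th <- runif(1, 0, 2 * pi)
  ph <- runif(1, 0, 2 * pi)
  r <- matrix(seq_len(H) - 1, H, W)
  cc <- matrix(seq_len(W) - 1, H, W, byrow = TRUE)
  u <- (cos(th) * cc / W + sin(th) * r / H)
  128 + 0.3 * A * u + 0.2 * A * sin(2 * pi * (cc / W + r / H) / 2 + ph)
}

# Linear pixel indices of one ellipse: interior (darker) and 2-px rim
# (brighter); `clipped` reports truncation at the frame border.
ellipseIndices <- function(x, y, a, b, theta, H, W) {
  ext <- ceiling(a + 2.5)
  r0 <- floor(y - ext); r1 <- ceiling(y + ext)
  c0 <- floor(x - ext); c1 <- ceiling(x + ext)
  clipped <- r0 < 0 || c0 < 0 || r1 > H - 1 || c1 > W - 1
  rr <- max(r0, 0):min(r1, H - 1)
  cc <- max(c0, 0):min(c1, W - 1)
  if (!length(rr) || !length(cc))
    return(list(dark = integer(0), bright = integer(0), clipped = TRUE))
  dx <- matrix(cc - x, length(rr), length(cc), byrow = TRUE)
  dy <- matrix(rr - y, length(rr), length(cc))
  xr <- dx * cos(theta) + dy * sin(theta)
  yr <- -dx * sin(theta) + dy * cos(theta)
  uIn <- (xr / a)^2 + (yr / b)^2
  uOut <- (xr / (a + 2))^2 + (yr / (b + 2))^2
  lin <- outer(rr + 1L, (cc) * H, "+")   # 1-based linear index into H x W
  list(dark = lin[uIn <= 1], bright = lin[uOut <= 1 & uIn > 1],
       clipped = clipped)
}

#' Render a synthetic sequence as phase-contrast-like images
#'
#' Draws every cell as an ellipse whose interior is darker than the local
#' background and whose 2-px rim is brighter (the halo), on a smooth
#' low-frequency brightness gradient; debris is drawn identically but
#' teleports between frames. Additive Gaussian noise completes the frame.
#' Deterministic given the configuration seed.
#'
#' @param truth a \linkS4class{SimTruth} from \code{\link{simulateColonies}}.
#' @param config the simulation configuration; defaults to the one in truth.
#' @return an \linkS4class{ImageSequence} of integer gray levels in 0..255.
#' @examples
#' cfg <- simConfig(nColonies = 2, seed = 3, durationDays = 2,
#'                  frameShape = c(256L, 256L), debrisCount = 1)
#' seqs <- renderSequence(simulateColonies(cfg))
#' length(seqs@frames)
#' @export
renderSequence <- function(truth, config = truth@config) {
  validObject(config)
  tsH <- timestampsOf(config)
  withSeed(config@seed + 1L, {
    bg <- makeBackground(config)
    H <- config@frameShape[1]; W <- config@frameShape[2]
    frames <- vector("list", length(tsH))
    anyClipped <- FALSE
    for (f in seq_along(tsH)) {
      alive <- truth@cells[truth@cells$birthH <= tsH[f], , drop = FALSE]
      deb <- truth@debris[truth@debris$frame == f - 1L, , drop = FALSE]
      xs <- c(alive$x, deb$x)
      ys <- c(alive$y, deb$y)
      if (config@jitterPx > 0 && nrow(alive)) {
        jit <- function(n) pmin(pmax(rnorm(n, 0, config@jitterPx / 2),
                                     -config@jitterPx), config@jitterPx)
        xs[seq_len(nrow(alive))] <- alive$x + jit(nrow(alive))
        ys[seq_len(nrow(alive))] <- alive$y + jit(nrow(alive))
      }
      as_ <- c(alive$majorAxisPx, deb$majorAxisPx) / 2
      bs_ <- c(alive$minorAxisPx, deb$minorAxisPx) / 2
      ths <- c(alive$thetaRad, deb$thetaRad)
      darkIdx <- vector("list", length(xs))
      brightIdx <- vector("list", length(xs))
      for (i in seq_along(xs)) {
        e <- ellipseIndices(xs[i], ys[i], as_[i], bs_[i], ths[i], H, W)
        darkIdx[[i]] <- e$dark
        brightIdx[[i]] <- e$bright
        anyClipped <- anyClipped || e$clipped
      }
      darkIdx <- unique(unlist(darkIdx))
      brightIdx <- setdiff(unique(unlist(brightIdx)), darkIdx)
      img <- bg
      img[brightIdx] <- img[brightIdx] + config@haloContrast
      img[darkIdx] <- bg[darkIdx] - config@cellContrast
      if (config@noiseSd > 0)
        img <- img + matrix(rnorm(H * W, 0, config@noiseSd), H, W)
      frames[[f]] <- matrix(as.integer(round(pmin(pmax(img, 0), 255))), H, W)
    }
    if (anyClipped)
      warning("some objects extended beyond the frame and were clipped")
    ImageSequence(frames, pixelSizeUm = config@pixelSizeUm,
                  frameIntervalH = config@frameIntervalH, timestampsH = tsH)
  })
}

#' Construct an ImageSequence
#'
#' @param frames list of numeric matrices (grayscale, identical dimensions).
#' @param pixelSizeUm micrometres per pixel.
#' @param frameIntervalH hours between frames.
#' @param timestampsH hours since seeding; defaults to multiples of
#'   \code{frameIntervalH} starting at 0.
#' @return an \linkS4class{ImageSequence}.
#' @export
ImageSequence <- function(frames, pixelSizeUm = 4, frameIntervalH = 6,
                          timestampsH = NULL) {
  if (is.null(timestampsH))
    timestampsH <- (seq_along(frames) - 1) * frameIntervalH
  new("ImageSequence", frames = frames, pixelSizeUm = pixelSizeUm,
      frameIntervalH = frameIntervalH, timestampsH = timestampsH)
}
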