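---
title: "Counting cells per colony in time-lapse phase-contrast imaging: methods and design"
author: "colonytrack"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting cells per colony in time-lapse phase-contrast imaging: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(colonytrack)
```

# The problem

Mesenchymal stromal cells (MSCs) seeded at clonal density (tens of cells
per cm²) grow into discrete colonies over about two weeks. Clinical
expansion protocols need the final cell yield, and the yield is the sum of
per-colony growth, so two practical questions drive this package:

1. Can individual cells be counted per colony, every six hours for
   fourteen days, from *label-free* phase-contrast images — despite image
   noise (tissue fragments, red blood cells) as large as the cells
   themselves?
2. How early in culture does the distribution of cells per colony predict
   the final, day-14 distribution?

`colonytrack` implements the full analysis chain: per-frame cell
segmentation, debris rejection by temporal persistence, colony definition
under explicit geometric rules, per-colony daily growth curves and shape
statistics, complete-linkage classification of the curves, and the
day-by-day coefficient of determination against day 14. A ground-truthed
synthetic image generator makes every stage testable without microscopy
data.

# Cell detection

Phase-contrast optics render a fibroblast-like cell as a **dark interior
surrounded by a bright halo rim** on a slowly varying background. Detection
uses exactly these two cues.

**Background correction** (`correctBackground`). The illumination gradient
is estimated on a coarse grid: the frame is tiled into square blocks of
side `2 * kernelRadiusPx + 1` (default 51 px = 204 µm, several times the
cell diameter), each block contributes its median gray level, and the grid
is interpolated bilinearly back to full resolution (border bands
extrapolate linearly). The block median is robust to both polarities of
the cell signature — interiors (dark) and rims (bright) together stay well
under half the pixels even inside a dense colony — and reproduces a linear
ramp exactly. We first implemented the textbook alternative, grayscale
morphological opening/closing with a large disc, and found it biased near
colonies: closing-then-opening lets halo plateaus survive into the
background estimate, which turns whole colonies into one giant "dark"
region after subtraction; the opposite order biases dark. The block-median
estimator has neither failure mode and is an order of magnitude faster.

**Shape restoration** (`restoreCellShape`). The response map is

> smoothed darkness below the background level × (1 + halo-enclosure boost)

where darkness is `max(0, median(frame) − frame)` smoothed with a Gaussian
(`interiorSigmaPx`, default 2 px), and the boost marks pixels enclosed by
bright rims (pixels above `median + haloK · MAD`, filled with a hull
operation). Because the boost is multiplicative on darkness, a region can
only respond if it is actually darker than the background: bright-interior
(inverted-contrast) blobs score strictly lower than true cells, and halo
arcs between adjacent cells cannot bridge two cells into one detection.

**Binarization** (`binarizeAndExtract`). Otsu's threshold on the response
map, floored at `thresholdFloor` (8 gray levels) so noise-only frames stay
empty, followed by 8-connected component extraction with a minimum area of
`minAreaPx` (20 px ≈ 320 µm² at 4 µm/px). The pipeline additionally
watershed-splits touching cells inside the binary mask
(`splitTouching = TRUE`, tolerance 8 response units): two abutting cell
bodies otherwise segment as a single component and every count in that
colony runs one low for the rest of the culture. The plain
connected-component behaviour remains the function's default and is what
the unit tests pin down.

# Debris rejection by temporal persistence

Primary cultures contain debris the same size as cells, so size filters
cannot help. What distinguishes debris is **motion**: cells adhere and
stay put between 6-h frames, debris drifts. Objects are linked between
consecutive frames by greedy nearest-neighbour assignment within a gate
(`gatePx`, 10 px = 40 µm), ties broken by distance then bounding-box
order; each object joins at most one track. A track is classified
**living** when it contains at least `minFrames = 3` observations in
consecutive frames whose successive displacements are all at most
`maxStepPx = 10` px; everything else is **noise**. The source method
states the rule qualitatively ("same position in several frames"); the
two numbers are our quantification and are exposed in the configuration.

Two consequences are worth knowing. First, classification is offline: a
daughter cell born mid-sequence is confirmed by its *later* frames, so
mid-culture counts are unbiased. Second, cells born within the last
`minFrames − 1` frames of the sequence can never be confirmed, so the
final day's counts run slightly low in fast-growing colonies. This
end-of-observation bias is inherent to any persistence rule, and we do not
work around it; the synthetic-recovery results quantify it.

Greedy (rather than globally optimal) linking is adequate at
clonal-density sparsity, where the nearest candidate is almost always the
same cell; it is a documented limitation for dense fields.

# Colony model

A **colony** is confirmed when it contains at least `minCells = 4` cells
within a circle of diameter `colonyDiameterUm = 320` µm (80 px). Cells are
grouped per frame by single linkage at the merge cutoff
`mergeDistanceUm = 100` µm, so distinct groups are ≥ 100 µm apart by
construction. Confirmation asks whether **some** 4-subset of a group fits
in a 320-µm circle — equivalently, whether a 160-µm-radius circle covering
≥ 4 members exists. We decide this exactly with the classical candidate
set (circles centred at each point and at the two intersections of
radius-r circles around each pair), with the numerical tolerance applied
in the coverage comparison only — candidates are constructed at the exact
radius, so boundary points sit on the circle up to rounding and an
inflated construction radius would silently consume the tolerance. The
320-µm rule is treated as a confirmation threshold, not a hard boundary:
once confirmed, a colony keeps all its single-linkage members as it grows.

**Identity over time** is propagated by track overlap: each frame's groups
continue every colony they share cell tracks with. The mapping is
deliberately many-to-one in both directions: several groups may continue
one colony (a transient segmentation dropout can split a group for one
frame, and the fragments must not found phantom colonies), and one group
may continue several colonies — which is precisely a **fusion**. Fused
colonies record the union membership, so the merge detector sees their
cross-distance collapse.

**Merging**: if the closest cells of two colonies come strictly within
100 µm, both are flagged merged from that frame onward and excluded from
growth analysis entirely (clonality is lost; there is no un-merging).
The boundary is strict: 99 µm merges, exactly 100 µm does not.

**Growth curves**: entry (c, d) is the number of living cells of colony c
at the day-d reference frame, defined once for all modules as the last
frame of each 24-h window (frame index 4·d at 6-h intervals). Whether the
source protocol used one frame per day or an aggregate of the four daily
frames is not stated; the last frame is the natural "state at the end of
day d". Counts are reported from day 1 for the founding lineage of every
eventually-confirmed colony.

# Morphometrics

Two per-colony shape statistics at the day-14 reference frame (the frame
is selectable):

* **Mean cell long axis** — the major axis of the ellipse with the same
  normalized second central moments as the cell's pixel region,
  `4·sqrt(λmax)` with the 1/12 pixel-extent correction on the diagonal
  moments (the regionprops convention; the discretization is stated
  because different conventions differ by a few percent on small
  regions). A single pixel gives 4·sqrt(1/12) ≈ 1.155 px.
* **Mean inter-cell distance** — the mean length of the unique edges of
  the Delaunay triangulation of the member centroids (via `deldir`).
  Two-point and collinear colonies fall back to the mean of consecutive
  gaps along the line, where a triangulation does not exist. Exactly
  cocircular 4-point sets admit two triangulations whose diagonals differ;
  the library's tie-break is accepted and test fixtures avoid exact
  cocircularity.

# Growth-curve classification and prediction

Counts are **square-root transformed** (damping the dominance of the
largest colonies) and clustered by agglomerative **complete linkage**
(furthest neighbour) on Euclidean distances — `hclust`'s textbook variant,
cut to `kGroups`. The default `kGroups = 7` mirrors the named groups of
the source study (large-1/2, medium-1..4, small); the study does not state
its cut criterion, so k is a parameter. Labels are renumbered by
descending group mean day-14 count so group 1 is always the
largest-growing — an arbitrary convention that makes runs comparable.

**Prediction**: for each day d, the coefficient of determination (squared
Pearson correlation, equal to the OLS R²) between day-d and day-14 counts
across colonies, on the **raw count scale** — following the source's
statement that regression preceded any log transformation — with the same
convention used for the detection-vs-reference count validation
(`validateCounts`). Days with constant counts yield `NA` with a warning;
day 14 against itself is 1 by definition.

# The synthetic generator

`simulateColonies` + `renderSequence` emulate the imaging experiment the
package targets: 6-h frames for 14 days at 4 µm/px (57 frames), cells with
dark elliptical bodies and 2-px bright halo rims on a smooth gradient
background (default amplitude 20 gray levels) with Gaussian pixel noise
(sd 1.5), and teleporting debris the same size as cells.

Choices a user should know, with reasons:

* **Division model**: each colony draws an archetype
  (`large`/`medium`/`small`, default mix 0.15/0.55/0.30); after a
  gamma-distributed lag (shape 4, mean `lagH` = 24/48/72 h), each cell
  divides after an exponential waiting time with mean `divisionIntervalH`
  = 54/72/144 h. These means were set analytically so that expected
  day-14 colony sizes span roughly 6–300 cells, the range over which the
  three named size classes separate; they are an *effective* constant
  rate absorbing the real culture's early acceleration and late
  contact-inhibition, not a mechanistic cell-cycle model.
* **Geometry**: daughters appear at about one cell spacing
  (`cellSpacingPx` = 16 px = 64 µm) from their mothers, at the free ring
  position closest to the colony centroid, giving compact disc-like
  colonies. Ring radii are capped at 1.3 × spacing so nearest-neighbour
  spacings never exceed the 100-µm grouping cutoff — simulated colonies
  are connected by construction. Cell long axes are lognormal around
  40 µm clamped to 32–48 µm, so no cell body falls below the detector's
  20-px² minimum area; both constraints restate the biology the detector
  is specified for (fibroblast-like MSCs) rather than tuning.
* **Colony layout**: founders are placed largest-first with clearance
  (sum of final radii + 120 µm) when space allows; in crowded draws the
  placement maximizes the minimum clearance margin instead of failing, so
  occasional genuine merges occur and exercise the exclusion path — as
  they do in real wells.
* **Debris**: positions are resampled every frame (≥ `debrisJumpPx` =
  40 px from the previous position, ≥ 20 px from any cell), making debris
  maximally non-persistent. Real debris drifts with some correlation;
  teleportation is the clean worst case for a persistence filter and the
  honest best case for rejecting one. Debris is *rendered identically to
  cells*, so nothing but temporal behaviour distinguishes it.
* **Not modelled**: cell death, migration out of the colony (an optional
  ≤ 1 px frame jitter exists but defaults off), cell flattening/shape
  change, focus drift, vignetting, and the partial overlap of crowded
  monolayers. Passing the synthetic recovery therefore shows the chain is
  correct *under its own assumptions* — stationary, non-overlapping,
  halo-rimmed cells — not that it will segment arbitrary real cultures.

# Problem sizes and numerical choices

The validation suite uses: 200 random point sets (≤ 12 points) for the
colony-confirmation oracle, 50 sets (≤ 8) each for the clustering and
Delaunay oracles, one rendered 20-colony 1024×1024, 57-frame experiment
for end-to-end recovery, and 140 simulated colonies for the prediction
analysis — sizes at which the brute-force oracles are exact and the whole
suite runs in minutes on one CPU. Determinism: every stochastic step in
the package derives from a configuration seed through a local RNG stream
that restores the caller's state; reruns are bit-identical, which the
output tests assert file-by-file.

Tolerances: the confirmation decision uses a relative slack of 1e-9 on
squared radii in comparisons only (see above); Delaunay oracle agreement
requires identical edge sets; moment-based axes are compared at 2% against
continuous ideals to absorb rasterization.

# Known limitations

* Final-frame counts run low in fast-growing colonies (persistence cannot
  confirm the newest daughters); day-14 agreement with truth is
  correspondingly below the mid-culture agreement.
* Greedy linking and the 10-px gate assume near-stationary cells; motile
  cell types need a different tracker.
* A debris particle that lands within the link gate of a cell that
  appears in the next frame can head that cell's track; rejection is
  therefore evaluated per track (majority of observations), not per
  observation.
* The detector is specified for dark-interior/bright-rim phase-contrast
  cells; other modalities (fluorescence, DIC) violate its response model.

# A minimal session

```{r example, eval = FALSE}
cfg <- simConfig(nColonies = 20, seed = 1)
truth <- simulateColonies(cfg)
seqs <- renderSequence(truth)
res <- runPipeline(seqs, pipelineConfig())
growthCounts(res$curves)          # colony x day counts
res$r2ByDay                       # prediction profile
colonyInfo(res$colonies)          # confirmation and merge status
scoreAgainstTruth(res, truth)     # recovery metrics vs ground truth
writeOutputs(res, "out", overlays = TRUE)
```
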