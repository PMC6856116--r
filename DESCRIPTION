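Package: colonytrack
Title: Colony Growth Analysis from Time-Lapse Phase-Contrast Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects living cells in time-lapse phase-contrast image
    sequences, rejecting debris by temporal persistence, groups cells into
    colonies under explicit geometric rules (minimum cell number within a
    fixed diameter, merge exclusion below a minimum spacing), extracts
    per-colony daily growth curves and colony morphometrics (cell long
    axis from second central moments, mean Delaunay inter-cell distance),
    classifies growth curves by complete-linkage hierarchical clustering,
    and quantifies how early-day colony counts predict end-of-culture
    counts. Includes a ground-truthed synthetic image and growth-curve
    simulator so the full pipeline can be exercised and validated without
    microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    EBImage,
    deldir,
    SummarizedExperiment,
    S4Vectors,
    jsonlite,
    yaml,
    tiff,
    png
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: CellBiology, Software, Visualization, SingleCell
RoxygenNote: 7.3.3
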