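Package: DeformCyto
Title: Multi-Sample Deformability Cytometry Image Analysis
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end analysis of multi-sample deformability cytometry
    recordings: brightfield frame stacks of cells transiting a linear
    microchannel are segmented with subpixel iso-contour measurement,
    linked into per-cell tracks, and reduced to the deformation index
    DI = 1 - 2*sqrt(pi*A)/p per frame. Per-cell readouts (undeformed
    diameter, confinement, maximum DI before channel exit) feed a
    population layer with confinement gating, one-tailed Mann-Whitney
    comparisons, nonparametric dose-response minimum-effective-dose
    calls, pressure-response fits, density contours and bead-based
    manifold quality control. A ground-truthed synthetic renderer
    (rigid beads and bullet-shaped deformable cells with log-normal
    deformability) makes the whole pipeline testable without
    experimental video.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    grDevices,
    utils,
    tools,
    Rcpp,
    EBImage,
    tiff,
    MASS,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pracma
Config/testthat/edition: 3
biocViews: CellBiology, Software, SingleCell, Visualization
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'DeformCyto-package.R'
    'RcppExports.R'
    'geometry.R'
    'metrics.R'
    'shapes.R'
    'synthesize.R'
    'segment.R'
    'track.R'
    'summarize.R'
    'stats.R'
    'pipeline.R'
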