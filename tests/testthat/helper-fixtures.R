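# Shared synthetic fixtures, built once per test run and cached. All seeds
# fixed; sensor crops are kept small (48 rows cover the channel, its walls
# and the cell envelope) so rendered runs stay fast.

.fx <- new.env(parent = emptyenv())

testGeom <- function(margin = 5) channelGeometry(roiMarginWidths = margin)

testAcq <- function(rows = 48L, cols = 440L)
    acquisitionConfig(imageShapePx = c(rows, cols))

# One rendered bead recording (12 beads), reused by segmentation, tracking
# and per-cell summary tests.
beadRun <- function() {
    if (is.null(.fx$beadRun)) {
        geom <- testGeom(); acq <- testAcq()
        truth <- sampleTransits(beadSpec(arrivalRatePerS = 150), geom, acq,
                                durationS = 0.09, seed = 42, nCells = 12)
        bg <- estimateBackground(truth)
        obs <- segmentStack(truth, geom, acq, background = bg)
        ts <- linkTracks(obs, geom, acq)
        .fx$beadRun <- list(geom = geom, acq = acq, truth = truth, bg = bg,
                            obs = obs, tracks = ts,
                            cells = summarizeCells(ts, "beads"))
    }
    .fx$beadRun
}

# One rendered deformable-cell recording (10 cells) with planted DI.
cellRun <- function() {
    if (is.null(.fx$cellRun)) {
        geom <- testGeom(); acq <- testAcq()
        truth <- sampleTransits(populationSpec(arrivalRatePerS = 150),
                                geom, acq, durationS = 0.08, seed = 11,
                                nCells = 10)
        bg <- estimateBackground(truth)
        obs <- segmentStack(truth, geom, acq, background = bg)
        ts <- linkTracks(obs, geom, acq)
        .fx$cellRun <- list(geom = geom, acq = acq, truth = truth, bg = bg,
                            obs = obs, tracks = ts,
                            cells = summarizeCells(ts, "cells"))
    }
    .fx$cellRun
}

# Analytic observation table for a single constant-velocity disk-shaped
# object: one row per frame, no rendering involved.
syntheticTrackObs <- function(x_positions, diameter_um = 15, y_um = 0,
                              frames = seq_along(x_positions),
                              coincident = FALSE, cell_id = 1L) {
    r <- diameter_um / 2
    data.frame(cell_id = cell_id, frame = frames, x_um = x_positions,
               y_um = y_um, area_um2 = pi * r^2, perimeter_um = 2 * pi * r,
               touches_border = FALSE, coincident = coincident,
               interpolated = FALSE)
}

# Log-normal DI_max sample mimicking a gated population.
rlnormDi <- function(n, median = 0.1, sigma = 0.35)
    stats::rlnorm(n, log(median), sigma)

# Wrap bare di_max values into a SamplePopulation (confinement mid-gate).
diPopulation <- function(di, id = "s", dose_um = NULL) {
    rec <- data.frame(sample_id = id, cell_id = seq_along(di), dc_um = 17,
                      confinement = 0.9, di_max = di,
                      velocity_mps = 0.3, n_frames_used = 10L,
                      reject_reason = NA_character_)
    md <- list(sample_id = id)
    if (!is.null(dose_um)) md$dose_um <- dose_um
    assemblePopulation(rec, metadata = md)
}
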