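## Synthetic ground-truthed recordings. Cells (or rigid beads) arrive as a
## Poisson process, transit the ROI at constant velocity, and carry a planted
## DI(x) profile: zero before the test section, a jump at the entrance, a
## linear rise to the per-cell maximum reached before the exit, then an
## exponential relaxation after exit. Shapes realising each DI come from the
## bullet family; rendering is supersampled so boundary discretisation, not
## renderer artifacts, dominates downstream measurement error.

## Fixture constants not exposed as population parameters: fraction of DI_max
## attained in the entrance jump, position of the DI maximum, post-exit
## relaxation length, per-cell velocity jitter, optical contrast and noise.
.syn <- list(
    jump_frac = 0.45,        # DI at x=0+ as a fraction of DI_max
    peak_frac = 0.85,        # DI_max reached at x = 0.85 L (held to L)
    relax_um = 60,           # post-exit exponential relaxation length (um)
    velocity_cv = 0.02,      # per-cell velocity jitter
    y_jitter_um = 1.0,       # transverse centroid jitter
    background = 30000,      # 16-bit background level
    contrast = 0.35,         # cell attenuation relative to background
    noise_sd_frac = 0.02,    # Gaussian sensor noise, fraction of 16-bit range
    grad_x = 0.06,           # illumination tilt across columns
    grad_y = 0.02,           # illumination tilt across rows
    wall_gap_um = 0.8,       # clearance between cell envelope and wall line
    wall_width_um = 1.5,
    n_vertices = 256L
)

#' Planted deformation-index profile
#'
#' The ground-truth DI of a synthetic cell as a function of centroid
#' position: 0 upstream of the test section, a jump to `0.45 * diMax` at the
#' entrance, a linear rise to `diMax` at `x = 0.85 L`, a plateau until the
#' exit, and exponential relaxation (length 60 um) downstream.
#'
#' @param x centroid x positions (um), vectorised.
#' @param diMax the cell's maximum DI (scalar or one value per `x`).
#' @param testLengthUm test-section length L (um).
#' @return ground-truth DI values.
#' @export
trueDiAt <- function(x, diMax, testLengthUm) {
    diMax <- rep_len(diMax, length(x))
    xp <- .syn$peak_frac * testLengthUm
    di <- numeric(length(x))
    rise <- x >= 0 & x < xp
    di[rise] <- diMax[rise] * (.syn$jump_frac +
        (1 - .syn$jump_frac) * x[rise] / xp)
    hold <- x >= xp & x <= testLengthUm
    di[hold] <- diMax[hold]
    post <- x > testLengthUm
    di[post] <- diMax[post] * exp(-(x[post] - testLengthUm) / .syn$relax_um)
    di
}

#' Sample ground-truth transits
#'
#' Draws the cells of one synthetic recording: Poisson arrivals (or exactly
#' `nCells` uniform arrivals), truncated-Normal diameters, log-normal per-cell
#' DI_max (zero for rigid beads), jittered velocities and transverse offsets.
#' Arrival time is the instant the centroid crosses the upstream ROI edge.
#'
#' @param spec a [PopulationSpec-class].
#' @param geom,acq geometry and acquisition configuration.
#' @param durationS recording duration (s).
#' @param seed integer seed; all randomness of the recording flows from it
#'   (cells first, then per-frame sensor noise on a derived stream).
#' @param nCells optional exact number of transits, overriding the Poisson
#'   draw (arrival times stay uniform over the duration).
#' @return an object of class `msdcTruth`: list with `cells` (data.frame:
#'   `cell_id`, `t_arrival_s`, `diameter_um`, `di_max`, `velocity_mps`,
#'   `y_um`, `frame_first`, `frame_last`), the configuration, `durationS`,
#'   `nFrames` and `seed`. Frame `f` is exposed at time `(f - 1) / fps`.
#' @export
sampleTransits <- function(spec, geom, acq, durationS, seed,
                           nCells = NULL) {
    stopifnot(is(spec, "PopulationSpec"), durationS > 0)
    validObject(spec)
    if (missing(seed) || is.null(seed))
        stop("a seed is mandatory for synthetic fixtures")
    set.seed(seed)
    fr <- coordinateFrame(geom, acq)
    n <- if (is.null(nCells)) stats::rpois(1, spec@arrivalRatePerS * durationS)
         else as.integer(nCells)
    t_arr <- sort(stats::runif(n, 0, durationS))
    ## truncate diameters at 3 sigma: keeps them positive and wall-safe
    sd_d <- spec@diameterCv * spec@diameterMeanUm
    d <- stats::rnorm(n, spec@diameterMeanUm, sd_d)
    d <- pmin(pmax(d, spec@diameterMeanUm - 3 * sd_d),
              spec@diameterMeanUm + 3 * sd_d)
    di_max <- if (spec@rigid || spec@diMaxMedian == 0) rep(0, n)
              else pmin(stats::rlnorm(n, log(spec@diMaxMedian),
                                      spec@diMaxLogSigma), 0.32)
    v <- spec@velocityMps * (1 + .syn$velocity_cv * stats::rnorm(n))
    y <- stats::runif(n, -.syn$y_jitter_um, .syn$y_jitter_um)
    ## hard-core exclusion: confined cells travel in single file and cannot
    ## interpenetrate, so successive arrivals are delayed until the trailing
    ## cell stays at least in point contact with its leader throughout the
    ## ROI (including worst-case catch-up from velocity jitter)
    if (n > 1L) {
        v_um <- v * 1e6
        roi_len <- fr$roi_length_um
        for (k in 2L:n) {
            contact <- (d[k - 1L] + d[k]) / 2 + 1
            closure <- max(0, (v_um[k] - v_um[k - 1L])) * roi_len / v_um[k]
            t_arr[k] <- max(t_arr[k],
                            t_arr[k - 1L] + (contact + closure) / v_um[k - 1L])
        }
    }
    fps <- acq@frameRateFps
    roi_time <- fr$roi_length_um * 1e-6 / v
    frame_first <- pmax(1L, as.integer(ceiling(t_arr * fps + 1e-9)) + 1L)
    frame_last <- as.integer(floor((t_arr + roi_time) * fps)) + 1L
    nFrames <- as.integer(ceiling(durationS * fps))
    frame_last <- pmin(frame_last, nFrames)
    cells <- data.frame(
        cell_id = seq_len(n), t_arrival_s = t_arr, diameter_um = d,
        di_max = di_max, velocity_mps = v, y_um = y,
        frame_first = frame_first, frame_last = frame_last)
    ## cells arriving too late to be exposed in any frame never exist
    cells <- cells[cells$frame_first <= cells$frame_last, , drop = FALSE]
    cells$cell_id <- seq_len(nrow(cells))
    structure(list(cells = cells, spec = spec, geometry = geom,
                   acquisition = acq, durationS = durationS,
                   nFrames = nFrames, seed = seed, frame = fr),
              class = "msdcTruth")
}

## centroid x (um) of cell i at frame f (1-based)
.truthX <- function(truth, i, f) {
    cell <- truth$cells[i, ]
    t <- (f - 1) / truth$acquisition@frameRateFps
    truth$frame$x_min + cell$velocity_mps * 1e6 * (t - cell$t_arrival_s)
}

#' Ground-truth records and co-occupancy
#'
#' `groundTruthRecords` returns one row per synthetic cell with its planted
#' diameter, DI_max, velocity and frames present in the ROI.
#' `truthCoincidence` returns, for every frame, the number of cells whose
#' centroid lies inside the test section, from which ground-truth coincidence
#' frames (count >= 2) follow.
#'
#' @param truth an `msdcTruth` object from [sampleTransits()].
#' @return see description.
#' @export
groundTruthRecords <- function(truth) {
    truth$cells[, c("cell_id", "diameter_um", "di_max", "velocity_mps",
                    "frame_first", "frame_last")]
}

#' @rdname groundTruthRecords
#' @export
truthCoincidence <- function(truth) {
    counts <- integer(truth$nFrames)
    L <- truth$geometry@testLengthUm
    for (i in seq_len(nrow(truth$cells))) {
        cell <- truth$cells[i, ]
        f <- cell$frame_first:cell$frame_last
        x <- .truthX(truth, i, f)
        f_in <- f[x >= 0 & x <= L]
        counts[f_in] <- counts[f_in] + 1L
    }
    counts
}

#' Render frames of a synthetic recording
#'
#' Rasterises the planted shapes into 16-bit brightfield-like frames: bright
#' background with a low-order illumination gradient, dark channel walls
#' along the test section, cells darker than background (trypan-blue-like
#' contrast), additive Gaussian sensor noise. Rasterisation is a supersampled
#' scanline fill (exact in x, 4 subsamples in y). Rendering any subset of
#' frames is bit-identical to rendering the full stack, so long recordings
#' can be processed in chunks.
#'
#' @param truth an `msdcTruth` from [sampleTransits()].
#' @param frames integer vector of frame indices (default all).
#' @return numeric array `[rows, cols, length(frames)]` with values in
#'   `[0, 65535]` (rounded to integers, stored as doubles).
#' @export
renderFrames <- function(truth, frames = seq_len(truth$nFrames)) {
    acq <- truth$acquisition
    fr <- truth$frame
    nr <- fr$nrow; nc <- fr$ncol; px <- fr$pixel_size_um
    base <- .syn$background
    col_c <- (seq_len(nc) - 0.5) / nc - 0.5
    row_c <- (seq_len(nr) - 0.5) / nr - 0.5
    bg <- base * (1 + outer(row_c * .syn$grad_y, col_c * .syn$grad_x, `+`))
    ## channel walls: dark bands along the test section only
    W2 <- truth$geometry@widthUm / 2
    y_px <- fr$rowToY(seq_len(nr) - 1L)
    wall_rows <- abs(y_px) >= W2 + .syn$wall_gap_um &
                 abs(y_px) <= W2 + .syn$wall_gap_um + .syn$wall_width_um
    x_px <- fr$colToX(seq_len(nc) - 1L)
    wall_cols <- x_px >= 0 & x_px <= truth$geometry@testLengthUm
    bg[wall_rows, wall_cols] <- bg[wall_rows, wall_cols] * 0.5

    cells <- truth$cells
    noise_sd <- .syn$noise_sd_frac * 65535
    out <- array(0, dim = c(nr, nc, length(frames)))
    ## which cells can appear in which frames
    for (k in seq_along(frames)) {
        f <- frames[k]
        img <- bg
        live <- which(cells$frame_first <= f & cells$frame_last >= f)
        for (i in live) {
            x <- .truthX(truth, i, f)
            di <- trueDiAt(x, cells$di_max[i], truth$geometry@testLengthUm)
            area <- pi * (cells$diameter_um[i] / 2)^2
            poly <- .shapeForDI(area, di, .syn$n_vertices)
            ## to continuous pixel coordinates (pixel j spans [j, j+1))
            pc <- cbind((poly[, 1] + x - fr$x_min) / px,
                        (poly[, 2] + cells$y_um[i] - fr$y_min) / px)
            j0 <- max(0L, floor(min(pc[, 1])) - 2L)
            j1 <- min(nc - 1L, ceiling(max(pc[, 1])) + 2L)
            i0 <- max(0L, floor(min(pc[, 2])) - 2L)
            i1 <- min(nr - 1L, ceiling(max(pc[, 2])) + 2L)
            if (j1 < j0 || i1 < i0) next
            cov <- cpp_polygon_coverage(pc[, 1] - j0, pc[, 2] - i0,
                                        i1 - i0 + 1L, j1 - j0 + 1L, 4L)
            rows <- (i0 + 1L):(i1 + 1L); colsx <- (j0 + 1L):(j1 + 1L)
            img[rows, colsx] <- img[rows, colsx] * (1 - .syn$contrast * cov)
        }
        ## per-frame noise stream keyed on frame index: chunk-independent
        set.seed((truth$seed + 7919L * (f %% 100000L)) %% .Machine$integer.max)
        img <- img + stats::rnorm(nr * nc, 0, noise_sd)
        out[, , k] <- round(pmin(pmax(img, 0), 65535))
    }
    out
}

#' Simulate a full transit recording
#'
#' Convenience wrapper: [sampleTransits()] then [renderFrames()].
#'
#' @inheritParams sampleTransits
#' @return list with `frames` (array) and `truth` (`msdcTruth`).
#' @examples
#' sim <- renderTransit(beadSpec(), channelGeometry(),
#'     acquisitionConfig(imageShapePx = c(64L, 440L)),
#'     durationS = 0.01, seed = 1)
#' dim(sim$frames)
#' @export
renderTransit <- function(spec, geom, acq, durationS, seed, nCells = NULL) {
    truth <- sampleTransits(spec, geom, acq, durationS, seed, nCells)
    list(frames = renderFrames(truth), truth = truth)
}

#' Analytic per-frame event table
#'
#' One row per (cell, frame) while the cell's centroid is inside the ROI,
#' with area, perimeter and DI computed exactly from the planted polygon —
#' no rendering or segmentation error. This is the entry point for testing
#' the statistics layer without images.
#'
#' @param truth an `msdcTruth` from [sampleTransits()].
#' @return data.frame with columns `cell_id`, `frame`, `x_um`, `y_um`,
#'   `area_um2`, `perimeter_um`, `di`.
#' @export
emitEventTable <- function(truth) {
    cells <- truth$cells
    L <- truth$geometry@testLengthUm
    rows <- vector("list", nrow(cells))
    for (i in seq_len(nrow(cells))) {
        f <- cells$frame_first[i]:cells$frame_last[i]
        if (length(f) == 0L) next
        x <- .truthX(truth, i, f)
        keep <- x >= truth$frame$x_min & x <= truth$frame$x_max
        f <- f[keep]; x <- x[keep]
        if (length(f) == 0L) next
        area0 <- pi * (cells$diameter_um[i] / 2)^2
        di <- trueDiAt(x, cells$di_max[i], L)
        ap <- vapply(di, function(d) {
            poly <- .shapeForDI(area0, d, .syn$n_vertices)
            c(polygonArea(poly), polygonPerimeter(poly))
        }, numeric(2))
        rows[[i]] <- data.frame(
            cell_id = cells$cell_id[i], frame = f, x_um = x,
            y_um = cells$y_um[i], area_um2 = ap[1, ], perimeter_um = ap[2, ],
            di = deformationIndex(ap[1, ], ap[2, ]))
    }
    out <- do.call(rbind, rows)
    if (is.null(out))
        out <- data.frame(cell_id = integer(0), frame = integer(0),
                          x_um = numeric(0), y_um = numeric(0),
                          area_um2 = numeric(0), perimeter_um = numeric(0),
                          di = numeric(0))
    rownames(out) <- NULL
    out
}
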