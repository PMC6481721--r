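#' Tracking parameters
#'
#' @param maxGap maximum number of consecutive missed frames tolerated
#'   before a track is terminated (default 2: single-frame segmentation
#'   dropouts do not split tracks).
#' @param nominalVelocityMps expected transit velocity; the matching window
#'   accepts x displacements in `[0, vMaxFactor * nominal] * dt`.
#' @param vMaxFactor upper velocity-gate factor (default 2).
#' @param entryZoneFrac fraction of the ROI length, measured from the
#'   upstream edge, in which unmatched observations may start new IDs; a
#'   cell is tagged when it first appears there, and segmentation flicker
#'   mid-channel cannot mint phantom cells.
#' @param upstreamTolUm small negative-displacement tolerance (default one
#'   pixel, 0.97 um) so centroid noise never violates the unidirectional
#'   flow constraint.
#' @param tieTolUm two candidates closer than this to the same track are
#'   tied; ties resolve by smallest area difference, then smallest ID.
#' @return parameter list for [linkTracks()].
#' @export
trackingParams <- function(maxGap = 2L, nominalVelocityMps = 0.3,
                           vMaxFactor = 2, entryZoneFrac = 0.25,
                           upstreamTolUm = 0.97, tieTolUm = 0.5) {
    list(maxGap = maxGap, nominalVelocityMps = nominalVelocityMps,
         vMaxFactor = vMaxFactor, entryZoneFrac = entryZoneFrac,
         upstreamTolUm = upstreamTolUm, tieTolUm = tieTolUm)
}

#' Link per-frame observations into cell tracks
#'
#' Greedy nearest-neighbour linking with velocity gating: an observation in
#' frame t+k (k <= maxGap + 1) can extend a track if its x displacement is
#' non-negative (within a one-pixel noise tolerance) and below
#' `vMaxFactor * nominalVelocityMps * dt`. Pairs are accepted in order of
#' centroid distance; ties resolve by area difference then track ID. New IDs
#' are assigned only to unmatched observations in the upstream entry zone —
#' a cell is tagged when it first appears in the ROI; mid-channel orphans
#' are dropped (counted in the result). At the analysed occupancy (one cell
#' in the test section at a time) greedy assignment is sufficient and
#' auditable; crowded frames are removed downstream by the coincidence rule.
#'
#' @param observations data.frame from [segmentStack()] (columns `frame`,
#'   `x_um`, `y_um`, `area_um2`, `perimeter_um`, `touches_border`, ...).
#' @param geom,acq geometry and acquisition configuration.
#' @param params list from [trackingParams()].
#' @return a [TrackSet-class]; its `observations` carry `cell_id` and a
#'   `coincident` column initialised by [flagCoincidence()], and the
#'   `tracks` table has `entered_roi`, `exited_roi`, `valid` flags plus the
#'   number of dropped orphan observations in `attr(,"n_dropped")`.
#' @export
linkTracks <- function(observations, geom, acq, params = trackingParams()) {
    fr <- coordinateFrame(geom, acq)
    fps <- acq@frameRateFps
    entry_max_x <- fr$x_min + params$entryZoneFrac * fr$roi_length_um
    exit_margin <- params$vMaxFactor * params$nominalVelocityMps * 1e6 / fps
    obs <- observations[order(observations$frame, observations$x_um), ,
                        drop = FALSE]
    n <- nrow(obs)
    cell_id <- rep(NA_integer_, n)
    if (n > 0L) {
        byframe <- split(seq_len(n), obs$frame)
        frames <- as.integer(names(byframe))
        ## active track state: id, last row index, last frame, and the
        ## estimated per-frame displacement used for ballistic prediction
        nominal_px <- params$nominalVelocityMps * 1e6 / fps
        act_id <- integer(0); act_row <- integer(0); act_f <- integer(0)
        act_vx <- numeric(0); act_vy <- numeric(0)
        next_id <- 1L
        for (fi in seq_along(frames)) {
            f <- frames[fi]
            ## retire tracks that gapped out
            keep <- f - act_f <= params$maxGap + 1L
            act_id <- act_id[keep]; act_row <- act_row[keep]
            act_f <- act_f[keep]
            act_vx <- act_vx[keep]; act_vy <- act_vy[keep]
            cand <- byframe[[fi]]
            if (length(act_id) > 0L && length(cand) > 0L) {
                pairs <- expand.grid(a = seq_along(act_id),
                                     c = seq_along(cand))
                dt <- (f - act_f[pairs$a]) / fps
                dx <- obs$x_um[cand[pairs$c]] - obs$x_um[act_row[pairs$a]]
                dy <- obs$y_um[cand[pairs$c]] - obs$y_um[act_row[pairs$a]]
                ok <- dx >= -params$upstreamTolUm &
                      dx <= params$vMaxFactor * params$nominalVelocityMps *
                            1e6 * dt
                pairs <- pairs[ok, , drop = FALSE]
                if (nrow(pairs) > 0L) {
                    ## nearest neighbour against the ballistic prediction:
                    ## matching against the last position alone seeds ID
                    ## swaps in cell trains whenever one member drops a
                    ## frame (a near-stationary wrong candidate outscores
                    ## the true one-frame-ahead continuation)
                    df_frames <- f - act_f[pairs$a]
                    ex <- dx[ok] - act_vx[pairs$a] * df_frames
                    ey <- dy[ok] - act_vy[pairs$a] * df_frames
                    dist <- sqrt(ex^2 + ey^2)
                    darea <- abs(obs$area_um2[cand[pairs$c]] -
                                 obs$area_um2[act_row[pairs$a]])
                    ord <- order(round(dist / params$tieTolUm), darea,
                                 act_id[pairs$a])
                    used_a <- logical(length(act_id))
                    used_c <- logical(length(cand))
                    for (m in ord) {
                        a <- pairs$a[m]; cc <- pairs$c[m]
                        if (used_a[a] || used_c[cc]) next
                        used_a[a] <- TRUE; used_c[cc] <- TRUE
                        cell_id[cand[cc]] <- act_id[a]
                        dfm <- f - act_f[a]
                        act_vx[a] <- (obs$x_um[cand[cc]] -
                                      obs$x_um[act_row[a]]) / dfm
                        act_vy[a] <- (obs$y_um[cand[cc]] -
                                      obs$y_um[act_row[a]]) / dfm
                        act_row[a] <- cand[cc]; act_f[a] <- f
                    }
                    cand <- cand[!used_c]
                }
            }
            ## unmatched observations: new IDs only in the entry zone
            if (length(cand) > 0L) {
                starts <- obs$x_um[cand] < entry_max_x
                for (cc in cand[starts]) {
                    cell_id[cc] <- next_id
                    act_id <- c(act_id, next_id)
                    act_row <- c(act_row, cc); act_f <- c(act_f, f)
                    act_vx <- c(act_vx, nominal_px)
                    act_vy <- c(act_vy, 0)
                    next_id <- next_id + 1L
                }
                ## mid-channel orphans stay NA and are dropped below
            }
        }
    }
    dropped <- is.na(cell_id)
    obs$cell_id <- cell_id
    obs <- obs[!dropped, , drop = FALSE]
    obs$coincident <- FALSE
    obs$interpolated <- FALSE
    obs <- obs[order(obs$cell_id, obs$frame),
               c("cell_id", setdiff(names(obs), "cell_id"))]
    rownames(obs) <- NULL
    ids <- unique(obs$cell_id)
    tracks <- data.frame(cell_id = ids,
                         n_obs = as.integer(table(obs$cell_id)[as.character(ids)]))
    first_x <- tapply(obs$x_um, obs$cell_id, function(x) x[1])
    last_x <- tapply(obs$x_um, obs$cell_id, function(x) x[length(x)])
    tracks$entered_roi <- as.numeric(first_x[as.character(ids)]) < entry_max_x
    tracks$exited_roi <- as.numeric(last_x[as.character(ids)]) >
        fr$x_max - exit_margin
    tracks$valid <- NA   # finalised by flagCoincidence()
    ts <- new("TrackSet", observations = obs, tracks = tracks,
              geometry = geom, acquisition = acq)
    ts <- flagCoincidence(ts)
    attr(ts@tracks, "n_dropped") <- sum(dropped)
    ts
}

#' Flag frames with multiple cells in the test section
#'
#' Frames in which two or more distinct tracks are inside the test section
#' (0 <= x <= L) are marked coincident on *all* involved tracks; those
#' observations are excluded from every DI summary (potential hydrodynamic
#' interaction between cells) but retained in the raw output. A track counts
#' as present on a frame it has no observation for (a gap of up to maxGap
#' frames) when its linearly interpolated position falls inside the section:
#' two near-coincident cells are often merged into a single segmented blob,
#' which silently removes one of them from the frame exactly when the rule
#' must fire.
#'
#' Two further per-observation quality flags are set here because they need
#' the whole track: `area_outlier` marks observations whose area deviates
#' from the track's median area by more than 40% — the signature of a merged
#' (doublet) blob or a gross mis-segmentation, analogous to doublet
#' exclusion in flow cytometry — and these are excluded from D_c and DI
#' summaries. Finally the per-track `valid` flag is set: entered and exited
#' the ROI, at least one usable pre-entry observation, and at least one
#' usable non-coincident in-test-section observation.
#'
#' @param ts a [TrackSet-class].
#' @return the updated `TrackSet`.
#' @export
flagCoincidence <- function(ts) {
    obs <- ts@observations
    L <- ts@geometry@testLengthUm
    in_sec <- obs$x_um >= 0 & obs$x_um <= L
    ## per-frame occupancy of the test section, counting gap frames at the
    ## track's interpolated position
    occ <- new.env(parent = emptyenv())
    bump <- function(f) {
        k <- as.character(f)
        occ[[k]] <- (occ[[k]] %||% 0L) + 1L
    }
    for (id in unique(obs$cell_id)) {
        sel <- which(obs$cell_id == id)
        f <- obs$frame[sel]; x <- obs$x_um[sel]
        for (fi in f[x >= 0 & x <= L]) bump(fi)
        gaps <- which(diff(f) > 1L)
        for (g in gaps) {
            miss <- (f[g] + 1L):(f[g + 1L] - 1L)
            xi <- x[g] + (miss - f[g]) * (x[g + 1L] - x[g]) / (f[g + 1L] - f[g])
            for (m in which(xi >= 0 & xi <= L)) bump(miss[m])
        }
    }
    counts <- unlist(as.list(occ))
    bad_frames <- as.integer(names(counts)[counts >= 2L])
    obs$coincident <- in_sec & obs$frame %in% bad_frames
    ## doublet / mis-segmentation flag: area far off the track median
    med <- tapply(obs$area_um2, obs$cell_id, stats::median)
    ref <- as.numeric(med[as.character(obs$cell_id)])
    obs$area_outlier <- abs(obs$area_um2 - ref) > 0.4 * ref
    ts@observations <- obs
    trk <- ts@tracks
    ## track-level area stability: a projected area drifting by more than
    ## 30% of its median over one transit signals an evolving merger with a
    ## second object (single particles and channel-confined cells hold their
    ## projected area far more tightly); such tracks are rejected wholesale
    ## because even their pre-entry reference is untrustworthy
    rng <- tapply(obs$area_um2[!obs$touches_border],
                  obs$cell_id[!obs$touches_border],
                  function(a) diff(range(a)) / stats::median(a))
    key <- as.character(trk$cell_id)
    trk$area_stable <- as.numeric(rng[key]) <= 0.3
    trk$area_stable[is.na(trk$area_stable)] <- FALSE
    usable <- !obs$touches_border & !obs$area_outlier
    pre_ok <- tapply(obs$x_um < 0 & usable, obs$cell_id, any)
    sec_ok <- tapply(in_sec & !obs$coincident & usable, obs$cell_id, any)
    trk$valid <- trk$entered_roi & trk$exited_roi & trk$area_stable &
        as.logical(pre_ok[key]) & as.logical(sec_ok[key])
    trk$valid[is.na(trk$valid)] <- FALSE
    ts@tracks <- trk
    ts
}

#' Transit velocity of one track
#'
#' Slope of the least-squares fit of centroid x (metres) against time
#' (seconds) over the non-coincident in-test-section observations; for a
#' two-point track this reduces to the endpoint difference. Fewer than two
#' usable observations give `NA` (undefined velocity).
#'
#' @param trackObs observations of a single cell (rows of a
#'   [TrackSet-class] observations table).
#' @param acq the [AcquisitionConfig-class].
#' @param testLengthUm test-section length L (um).
#' @return speed in m/s, or `NA_real_`.
#' @export
trackVelocity <- function(trackObs, acq, testLengthUm) {
    use <- trackObs$x_um >= 0 & trackObs$x_um <= testLengthUm &
           !trackObs$coincident
    o <- trackObs[use, , drop = FALSE]
    if (nrow(o) < 2L) return(NA_real_)
    t_s <- (o$frame - 1) / acq@frameRateFps
    stats::coef(stats::lm(I(o$x_um * 1e-6) ~ t_s))[[2]]
}
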