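#' Collapse a track into a per-cell record
#'
#' The three per-cell readouts: the undeformed diameter \eqn{D_c} is the
#' equivalent diameter of the *mean* area over all usable pre-entry
#' observations (x < 0, non-border, non-coincident) — averaging suppresses
#' single-frame segmentation noise; the deformability readout `di_max` is
#' the maximum DI over usable observations with centroid inside the test
#' section (0 <= x <= L), i.e. the maximum deformation before the cell
#' exits; the velocity comes from [trackVelocity()]. Confinement is
#' \eqn{D_c / D_h}. Artificially deforming in-section frames can never
#' change `dc_um`, and pre-entry frames can never change `di_max`.
#'
#' Tracks that fail a requirement produce a rejection record with a reason
#' (`"invalid_track"`, `"no_preentry"`, `"no_insection"`, `"coincidence"`)
#' rather than an error: the accept/reject accounting is deliberate QC
#' output.
#'
#' @param trackObs observations of one cell (rows of a [TrackSet-class]
#'   observations table).
#' @param valid logical: the track's validity flag.
#' @param geom,acq geometry and acquisition configuration.
#' @param sampleId sample identifier stored in the record.
#' @return one-row data.frame with `cell_id`, `dc_um`, `confinement`,
#'   `di_max`, `velocity_mps`, `n_frames_used`, `reject_reason` (`NA` when
#'   accepted).
#' @export
summarizeCell <- function(trackObs, valid, geom, acq, sampleId = "sample") {
    id <- trackObs$cell_id[1]
    rec <- function(reason, dc = NA_real_, conf = NA_real_, dimax = NA_real_,
                    v = NA_real_, nfr = 0L)
        data.frame(sample_id = sampleId, cell_id = id, dc_um = dc,
                   confinement = conf, di_max = dimax, velocity_mps = v,
                   n_frames_used = nfr, reject_reason = reason)
    if (!isTRUE(valid)) return(rec("invalid_track"))
    L <- geom@testLengthUm
    usable <- !trackObs$touches_border & !trackObs$interpolated
    if (!is.null(trackObs$area_outlier))
        usable <- usable & !trackObs$area_outlier
    pre <- usable & trackObs$x_um < 0 & !trackObs$coincident
    if (!any(pre)) return(rec("no_preentry"))
    in_sec <- trackObs$x_um >= 0 & trackObs$x_um <= L
    sec <- usable & in_sec & !trackObs$coincident
    if (!any(sec))
        return(rec(if (any(usable & in_sec)) "coincidence" else "no_insection"))
    dc <- equivalentDiameter(mean(trackObs$area_um2[pre]))
    di <- deformationIndex(trackObs$area_um2[sec], trackObs$perimeter_um[sec])
    rec(NA_character_, dc = dc, conf = dc / hydraulicDiameter(geom),
        dimax = max(di), v = trackVelocity(trackObs, acq, L),
        nfr = sum(pre) + sum(sec))
}

#' Summarise every track of a recording
#'
#' Applies [summarizeCell()] to each track of a [TrackSet-class] and splits
#' the results into accepted and rejected records.
#'
#' @param ts a [TrackSet-class].
#' @param sampleId sample identifier.
#' @return list with data.frames `records` (accepted) and `rejected`.
#' @export
summarizeCells <- function(ts, sampleId = "sample") {
    obs <- ts@observations
    trk <- ts@tracks
    res <- lapply(seq_len(nrow(trk)), function(i) {
        r <- summarizeCell(obs[obs$cell_id == trk$cell_id[i], , drop = FALSE],
                           trk$valid[i], ts@geometry, ts@acquisition, sampleId)
        if (identical(r$reject_reason, "invalid_track") &&
            isFALSE(trk$area_stable[i]))
            r$reject_reason <- "unstable_area"
        r
    })
    res <- do.call(rbind, res)
    if (is.null(res))
        res <- summarizeCell(data.frame(cell_id = integer(0)), FALSE,
                             ts@geometry, ts@acquisition, sampleId)[0, ]
    list(records = res[is.na(res$reject_reason), , drop = FALSE],
         rejected = res[!is.na(res$reject_reason), , drop = FALSE])
}

#' Assemble per-cell records into a sample population
#'
#' Bundles records sharing one sample identifier with their experimental
#' metadata (cell line, drug, dose, driving pressure, channel index).
#' Records from the two channels a sample is typically run in are merged
#' under the one sample ID. An empty record set is allowed (and flagged on
#' show), mixed sample IDs are an error.
#'
#' @param records accepted per-cell records (data.frame with a `sample_id`
#'   column, as from [summarizeCells()]).
#' @param rejected optional rejected records.
#' @param metadata named list of sample metadata.
#' @return a [SamplePopulation-class].
#' @export
assemblePopulation <- function(records, rejected = NULL, metadata = list()) {
    ids <- unique(records$sample_id)
    if (length(ids) > 1L)
        stop("records span multiple sample_ids: ",
             paste(ids, collapse = ", "))
    if (length(ids) == 0L) ids <- metadata$sample_id %||% "empty"
    if (is.null(rejected)) rejected <- records[0, ]
    new("SamplePopulation", sampleId = as.character(ids),
        records = records, rejected = rejected, metadata = metadata)
}

#' Per-cell records straight from an analytic event table
#'
#' Applies the per-cell summary rules (pre-entry D_c, in-section DI_max,
#' coincidence exclusion) to a synthetic event table from
#' [emitEventTable()], bypassing rendering and segmentation. Coincidence is
#' recomputed from the table itself.
#'
#' @param events event table (`cell_id`, `frame`, `x_um`, `area_um2`,
#'   `perimeter_um`).
#' @param geom the [ChannelGeometry-class].
#' @param sampleId sample identifier.
#' @return list with `records` and `rejected` data.frames.
#' @export
eventTableRecords <- function(events, geom, sampleId = "sample") {
    L <- geom@testLengthUm
    in_sec <- events$x_um >= 0 & events$x_um <= L
    tab <- table(events$frame[in_sec])
    bad <- as.integer(names(tab)[tab >= 2L])
    events$coincident <- in_sec & events$frame %in% bad
    dh <- hydraulicDiameter(geom)
    res <- lapply(split(events, events$cell_id), function(e) {
        pre <- e$x_um < 0
        sec <- e$x_um >= 0 & e$x_um <= L & !e$coincident
        reason <- if (!any(pre)) "no_preentry"
                  else if (!any(sec)) {
                      if (any(e$x_um >= 0 & e$x_um <= L)) "coincidence"
                      else "no_insection"
                  } else NA_character_
        if (!is.na(reason))
            return(data.frame(sample_id = sampleId, cell_id = e$cell_id[1],
                              dc_um = NA_real_, confinement = NA_real_,
                              di_max = NA_real_, velocity_mps = NA_real_,
                              n_frames_used = 0L, reject_reason = reason))
        dc <- equivalentDiameter(mean(e$area_um2[pre]))
        data.frame(sample_id = sampleId, cell_id = e$cell_id[1], dc_um = dc,
                   confinement = dc / dh,
                   di_max = max(deformationIndex(e$area_um2[sec],
                                                 e$perimeter_um[sec])),
                   velocity_mps = NA_real_,
                   n_frames_used = sum(pre) + sum(sec),
                   reject_reason = NA_character_)
    })
    res <- do.call(rbind, res)
    rownames(res) <- NULL
    list(records = res[is.na(res$reject_reason), , drop = FALSE],
         rejected = res[!is.na(res$reject_reason), , drop = FALSE])
}
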