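#' Run the full analysis pipeline on one recording
#'
#' Executes segment -> track -> per-cell summary -> gate for a single
#' channel/sample and (optionally) writes the standard artifact set to
#' `outDir`: `observations.csv`, `tracks.csv`, `cells.csv`, `rejected.csv`
#' and a `manifest.json` with the configuration snapshot, seed, input
#' checksum and per-stage row counts. Re-running with identical inputs and
#' seeds reproduces the per-cell CSV bit for bit.
#'
#' `input` may be a multi-page TIFF path, a frame array, an `msdcTruth`
#' object (frames are rendered on demand in chunks), or a per-frame event
#' table (data.frame or CSV path with columns `cell_id, frame, x_um,
#' area_um2, perimeter_um`) — in which case the imaging stages are skipped
#' and only the statistics layer runs.
#'
#' @param input see above.
#' @param geom,acq geometry and acquisition configuration.
#' @param sampleId sample identifier.
#' @param metadata named list of sample metadata (cell_line, drug, dose_um,
#'   pressure_kpa, channel_index, ...).
#' @param segParams,trkParams stage parameter lists.
#' @param gate confinement gate bounds, or `NULL` to skip gating.
#' @param outDir output directory, or `NULL` to skip writing.
#' @param seed seed recorded in the manifest (and the one the truth object
#'   was built with, for synthetic inputs).
#' @return list with `population` (ungated [SamplePopulation-class]),
#'   `gated` (or `NULL`), `tracks` ([TrackSet-class] or `NULL` for event
#'   tables) and `manifest`.
#' @export
runPipeline <- function(input, geom, acq, sampleId = "sample",
                        metadata = list(), segParams = segmentationParams(),
                        trkParams = trackingParams(), gate = c(0.85, 0.95),
                        outDir = NULL, seed = NULL) {
    is_events <- (is.data.frame(input) && "cell_id" %in% names(input)) ||
        (is.character(input) && length(input) == 1L &&
         grepl("\\.csv$", input, ignore.case = TRUE))
    input_sum <- if (is.character(input)) unname(tools::md5sum(input))
                 else NA_character_
    ts <- NULL
    if (is_events) {
        events <- if (is.character(input))
            utils::read.csv(input) else input
        sm <- eventTableRecords(events, geom, sampleId)
        counts <- list(frames = NA_integer_,
                       observations = nrow(events),
                       tracks = length(unique(events$cell_id)))
    } else {
        obs <- segmentStack(input, geom, acq, segParams)
        ts <- linkTracks(obs, geom, acq, trkParams)
        sm <- summarizeCells(ts, sampleId)
        counts <- list(frames = frameSource(input)$n,
                       observations = nrow(obs),
                       tracks = nrow(ts@tracks))
    }
    metadata$sample_id <- sampleId
    pop <- assemblePopulation(sm$records, sm$rejected, metadata)
    gated <- if (!is.null(gate)) confinementGate(pop, gate[1], gate[2])
             else NULL
    manifest <- list(
        sample_id = sampleId, seed = seed, input_md5 = input_sum,
        geometry = list(width_um = geom@widthUm, height_um = geom@heightUm,
                        test_length_um = geom@testLengthUm,
                        roi_margin_widths = geom@roiMarginWidths),
        acquisition = list(pixel_size_um = acq@pixelSizeUm,
                           frame_rate_fps = acq@frameRateFps,
                           driving_pressure_kpa = acq@drivingPressureKpa,
                           image_shape_px = as.integer(acq@imageShapePx)),
        gate = gate, counts = c(counts, list(
            cells_accepted = nrow(sm$records),
            cells_rejected = nrow(sm$rejected),
            cells_gated = if (is.null(gated)) NA_integer_
                          else nrow(cellRecords(gated)))),
        reject_reasons = as.list(table(sm$rejected$reject_reason)))
    if (!is.null(outDir)) {
        dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
        if (!is.null(ts)) {
            utils::write.csv(ts@observations,
                             file.path(outDir, "observations.csv"),
                             row.names = FALSE)
            utils::write.csv(ts@tracks, file.path(outDir, "tracks.csv"),
                             row.names = FALSE)
        }
        utils::write.csv(sm$records, file.path(outDir, "cells.csv"),
                         row.names = FALSE)
        utils::write.csv(sm$rejected, file.path(outDir, "rejected.csv"),
                         row.names = FALSE)
        jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                             auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }
    list(population = pop, gated = gated, tracks = ts, manifest = manifest)
}

#' Write a ground-truthed synthetic fixture bundle
#'
#' Renders a recording and writes it as a 16-bit multi-page TIFF together
#' with the ground-truth table, the analytic event table and a sidecar JSON
#' echoing every generation parameter. A seed is mandatory: fixtures must be
#' reproducible.
#'
#' @param spec a [PopulationSpec-class].
#' @param geom,acq geometry and acquisition configuration.
#' @param durationS recording duration (s).
#' @param seed integer seed (required).
#' @param outDir output directory (created if needed).
#' @param nCells optional exact transit count (see [sampleTransits()]).
#' @return invisibly, the paths written (`tiff`, `truth`, `events`,
#'   `sidecar`).
#' @export
simulateFixture <- function(spec, geom, acq, durationS, seed, outDir,
                            nCells = NULL) {
    if (missing(seed) || is.null(seed))
        stop("a seed is mandatory for synthetic fixtures")
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    truth <- sampleTransits(spec, geom, acq, durationS, seed, nCells)
    frames <- renderFrames(truth)
    pages <- lapply(seq_len(dim(frames)[3]),
                    function(k) frames[, , k] / 65535)
    paths <- list(tiff = file.path(outDir, "frames.tif"),
                  truth = file.path(outDir, "ground_truth.csv"),
                  events = file.path(outDir, "events.csv"),
                  sidecar = file.path(outDir, "generation.json"))
    tiff::writeTIFF(pages, paths$tiff, bits.per.sample = 16L,
                    compression = "none")
    utils::write.csv(groundTruthRecords(truth), paths$truth,
                     row.names = FALSE)
    utils::write.csv(emitEventTable(truth), paths$events, row.names = FALSE)
    jsonlite::write_json(list(
        seed = seed, duration_s = durationS, n_frames = truth$nFrames,
        population = list(
            n_cells = spec@nCells, diameter_mean_um = spec@diameterMeanUm,
            diameter_cv = spec@diameterCv, di_max_median = spec@diMaxMedian,
            di_max_log_sigma = spec@diMaxLogSigma,
            velocity_mps = spec@velocityMps,
            arrival_rate_per_s = spec@arrivalRatePerS, rigid = spec@rigid),
        geometry = list(width_um = geom@widthUm, height_um = geom@heightUm,
                        test_length_um = geom@testLengthUm,
                        roi_margin_widths = geom@roiMarginWidths),
        acquisition = list(pixel_size_um = acq@pixelSizeUm,
                           frame_rate_fps = acq@frameRateFps,
                           image_shape_px = as.integer(acq@imageShapePx))),
        paths$sidecar, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(paths)
}
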