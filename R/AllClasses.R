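#' Channel geometry
#'
#' Dimensions of the constricted test section of one microchannel and the
#' extent of the imaged region of interest (ROI). The coordinate frame used
#' throughout the package puts \eqn{x = 0} at the test-section entrance plane
#' and \eqn{x = L} at the exit plane, with flow in the +x direction; the ROI
#' spans `roiMarginWidths` channel widths upstream and downstream of the test
#' section. The hydraulic diameter \eqn{D_h = 2WH/(W+H)} is always derived,
#' never stored.
#'
#' @slot widthUm channel width W (um).
#' @slot heightUm channel height H (um).
#' @slot testLengthUm test-section length L (um).
#' @slot roiMarginWidths number of channel widths of ROI margin on each side
#'   of the test section (>= 0).
#'
#' @seealso [hydraulicDiameter()], [coordinateFrame()]
#' @export
setClass("ChannelGeometry",
    representation(
        widthUm = "numeric",
        heightUm = "numeric",
        testLengthUm = "numeric",
        roiMarginWidths = "numeric"
    )
)

setValidity("ChannelGeometry", function(object) {
    msg <- NULL
    for (sl in c("widthUm", "heightUm", "testLengthUm")) {
        v <- slot(object, sl)
        if (length(v) != 1L || !is.finite(v) || v <= 0)
            msg <- c(msg, sprintf("'%s' must be a single positive number", sl))
    }
    m <- object@roiMarginWidths
    if (length(m) != 1L || !is.finite(m) || m < 0)
        msg <- c(msg, "'roiMarginWidths' must be a single number >= 0")
    if (is.null(msg)) TRUE else msg
})

#' @describeIn ChannelGeometry-class Constructor. Defaults are the
#'   near-square test-section dimensions of the reference device
#'   (W = 18 um, H = 19.8 um, L = 230 um, ROI margin of five channel widths).
#' @param widthUm,heightUm,testLengthUm,roiMarginWidths see slots.
#' @export
channelGeometry <- function(widthUm = 18, heightUm = 19.8,
                            testLengthUm = 230, roiMarginWidths = 5) {
    new("ChannelGeometry", widthUm = widthUm, heightUm = heightUm,
        testLengthUm = testLengthUm, roiMarginWidths = roiMarginWidths)
}

#' @export
setMethod("hydraulicDiameter", "ChannelGeometry", function(object) {
    2 * object@widthUm * object@heightUm / (object@widthUm + object@heightUm)
})

setMethod("show", "ChannelGeometry", function(object) {
    cat("ChannelGeometry:",
        sprintf("W = %g um, H = %g um, L = %g um", object@widthUm,
                object@heightUm, object@testLengthUm), "\n")
    cat(sprintf("  hydraulic diameter D_h = %.3f um; ROI margin = %g widths\n",
                hydraulicDiameter(object), object@roiMarginWidths))
})

#' Acquisition configuration
#'
#' Optical and camera parameters of a recording. Defaults match the reference
#' high-speed setup: effective pixel size 0.97 um at 20x magnification,
#' 15000 frames/s, 1 us exposure, sensor crop of 464 x 504 pixels, and a
#' driving pressure of 15 kPa.
#'
#' @slot pixelSizeUm effective pixel size (um/px).
#' @slot frameRateFps frame rate (frames per second).
#' @slot drivingPressureKpa driving pressure (kPa), >= 0.
#' @slot exposureUs exposure time (us).
#' @slot imageShapePx integer vector `c(rows, cols)` of the sensor crop.
#' @export
setClass("AcquisitionConfig",
    representation(
        pixelSizeUm = "numeric",
        frameRateFps = "numeric",
        drivingPressureKpa = "numeric",
        exposureUs = "numeric",
        imageShapePx = "integer"
    )
)

setValidity("AcquisitionConfig", function(object) {
    msg <- NULL
    if (object@pixelSizeUm <= 0) msg <- c(msg, "'pixelSizeUm' must be > 0")
    if (object@frameRateFps <= 0) msg <- c(msg, "'frameRateFps' must be > 0")
    if (object@drivingPressureKpa < 0)
        msg <- c(msg, "'drivingPressureKpa' must be >= 0")
    if (length(object@imageShapePx) != 2L || any(object@imageShapePx < 1L))
        msg <- c(msg, "'imageShapePx' must be two positive integers (rows, cols)")
    if (is.null(msg)) TRUE else msg
})

#' @describeIn AcquisitionConfig-class Constructor with reference-setup
#'   defaults.
#' @param pixelSizeUm,frameRateFps,drivingPressureKpa,exposureUs,imageShapePx
#'   see slots.
#' @export
acquisitionConfig <- function(pixelSizeUm = 0.97, frameRateFps = 15000,
                              drivingPressureKpa = 15, exposureUs = 1,
                              imageShapePx = c(464L, 504L)) {
    new("AcquisitionConfig", pixelSizeUm = pixelSizeUm,
        frameRateFps = frameRateFps, drivingPressureKpa = drivingPressureKpa,
        exposureUs = exposureUs, imageShapePx = as.integer(imageShapePx))
}

setMethod("show", "AcquisitionConfig", function(object) {
    cat(sprintf(
        "AcquisitionConfig: %.3g um/px, %g fps, %g kPa, %d x %d px\n",
        object@pixelSizeUm, object@frameRateFps, object@drivingPressureKpa,
        object@imageShapePx[1], object@imageShapePx[2]))
})

#' Synthetic population specification
#'
#' Parameters of a simulated cell or bead population. Diameters are drawn
#' Normal(diameterMeanUm, cv * mean); per-cell maximum deformation indices are
#' log-normal, \eqn{\log DI_{max} \sim N(\log(median), \sigma)}, matching the
#' non-normal (log-normal) deformability distributions seen in gated
#' populations. Rigid beads (`rigid = TRUE`) have `diMaxMedian = 0` and never
#' deform.
#'
#' @slot nCells default number of cells for event-table generation.
#' @slot diameterMeanUm mean undeformed diameter (um).
#' @slot diameterCv coefficient of variation of diameter, in [0, 0.5].
#' @slot diMaxMedian population median of the per-cell maximum DI.
#' @slot diMaxLogSigma log-normal shape parameter of DI_max.
#' @slot velocityMps transit velocity (m/s).
#' @slot arrivalRatePerS Poisson arrival rate of cells at the ROI (1/s).
#' @slot rigid logical; TRUE for rigid beads.
#' @export
setClass("PopulationSpec",
    representation(
        nCells = "integer",
        diameterMeanUm = "numeric",
        diameterCv = "numeric",
        diMaxMedian = "numeric",
        diMaxLogSigma = "numeric",
        velocityMps = "numeric",
        arrivalRatePerS = "numeric",
        rigid = "logical"
    )
)

setValidity("PopulationSpec", function(object) {
    msg <- NULL
    if (object@diameterMeanUm <= 0) msg <- c(msg, "'diameterMeanUm' must be > 0")
    if (object@diameterCv < 0 || object@diameterCv > 0.5)
        msg <- c(msg, "'diameterCv' must be in [0, 0.5]")
    if (object@diMaxMedian < 0) msg <- c(msg, "'diMaxMedian' must be >= 0")
    if (object@rigid && object@diMaxMedian != 0)
        msg <- c(msg, "rigid populations must have diMaxMedian = 0")
    if (object@velocityMps <= 0) msg <- c(msg, "'velocityMps' must be > 0")
    if (object@arrivalRatePerS <= 0)
        msg <- c(msg, "'arrivalRatePerS' must be > 0")
    if (is.null(msg)) TRUE else msg
})

#' @describeIn PopulationSpec-class Constructor for a deformable cell
#'   population. Defaults emulate an epithelial cancer-cell sample sized to
#'   centre the 0.85-0.95 confinement gate: 17 um mean diameter (5% CV),
#'   median DI_max 0.10 with log-sigma 0.35, 0.3 m/s transit velocity and
#'   100 cells/s arrival rate.
#' @param nCells,diameterMeanUm,diameterCv,diMaxMedian,diMaxLogSigma see slots.
#' @param velocityMps,arrivalRatePerS,rigid see slots.
#' @export
populationSpec <- function(nCells = 200L, diameterMeanUm = 17,
                           diameterCv = 0.05, diMaxMedian = 0.10,
                           diMaxLogSigma = 0.35, velocityMps = 0.3,
                           arrivalRatePerS = 100, rigid = FALSE) {
    if (rigid) diMaxMedian <- 0
    new("PopulationSpec", nCells = as.integer(nCells),
        diameterMeanUm = diameterMeanUm, diameterCv = diameterCv,
        diMaxMedian = diMaxMedian, diMaxLogSigma = diMaxLogSigma,
        velocityMps = velocityMps, arrivalRatePerS = arrivalRatePerS,
        rigid = rigid)
}

#' @describeIn PopulationSpec-class Rigid polystyrene-bead population
#'   (manufacturer distribution: 15.13 um mean diameter, 6% CV).
#' @export
beadSpec <- function(nCells = 500L, diameterMeanUm = 15.13,
                     diameterCv = 0.06, velocityMps = 0.3,
                     arrivalRatePerS = 100) {
    populationSpec(nCells = nCells, diameterMeanUm = diameterMeanUm,
                   diameterCv = diameterCv, diMaxMedian = 0,
                   diMaxLogSigma = 0, velocityMps = velocityMps,
                   arrivalRatePerS = arrivalRatePerS, rigid = TRUE)
}

setMethod("show", "PopulationSpec", function(object) {
    cat(sprintf(
        "PopulationSpec: %s, D = %g um (CV %.0f%%), DI_max median %g, v = %g m/s, rate %g/s\n",
        if (object@rigid) "rigid beads" else "deformable cells",
        object@diameterMeanUm, 100 * object@diameterCv, object@diMaxMedian,
        object@velocityMps, object@arrivalRatePerS))
})

#' Linked cell tracks
#'
#' Result of linking per-frame observations into per-cell tracks. The
#' `observations` table holds one row per (cell, frame) with the measured
#' shape quantities; the `tracks` table holds one row per cell with validity
#' flags. A track is `valid` when the cell both entered and exited the ROI
#' with at least one usable pre-entry observation (x < 0) and at least one
#' non-coincident observation inside the test section.
#'
#' @slot observations data.frame with columns `cell_id`, `frame`, `x_um`,
#'   `y_um`, `area_um2`, `perimeter_um`, `touches_border`, `coincident`,
#'   `interpolated`.
#' @slot tracks data.frame with columns `cell_id`, `n_obs`, `entered_roi`,
#'   `exited_roi`, `valid`.
#' @slot geometry the [ChannelGeometry-class] used.
#' @slot acquisition the [AcquisitionConfig-class] used.
#' @export
setClass("TrackSet",
    representation(
        observations = "data.frame",
        tracks = "data.frame",
        geometry = "ChannelGeometry",
        acquisition = "AcquisitionConfig"
    )
)

setValidity("TrackSet", function(object) {
    need_obs <- c("cell_id", "frame", "x_um", "y_um", "area_um2",
                  "perimeter_um", "touches_border", "coincident")
    need_trk <- c("cell_id", "n_obs", "entered_roi", "exited_roi", "valid")
    msg <- NULL
    if (!all(need_obs %in% names(object@observations)))
        msg <- c(msg, "observations table missing required columns")
    if (!all(need_trk %in% names(object@tracks)))
        msg <- c(msg, "tracks table missing required columns")
    if (is.null(msg)) TRUE else msg
})

setMethod("show", "TrackSet", function(object) {
    cat(sprintf("TrackSet: %d tracks (%d valid), %d observations\n",
                nrow(object@tracks), sum(object@tracks$valid),
                nrow(object@observations)))
})

#' Gated or ungated sample population
#'
#' A collection of per-cell records for one sample (one cell line / drug /
#' dose / pressure condition, possibly pooled over the two channels a sample
#' is run in). The `records` data.frame carries one row per accepted cell:
#' `cell_id`, `dc_um` (undeformed diameter), `confinement` (Dc/Dh), `di_max`,
#' `velocity_mps`, `n_frames_used`. Rejected cells are kept in `rejected`
#' with their reasons: the accept/reject accounting is the pipeline's main QC
#' surface.
#'
#' @slot sampleId sample identifier.
#' @slot records accepted per-cell records (data.frame).
#' @slot rejected rejected per-cell records with a `reject_reason` column.
#' @slot metadata free-form list (cell_line, drug, dose_um, pressure_kpa,
#'   channel_index, gate bounds once gated, ...).
#' @export
setClass("SamplePopulation",
    representation(
        sampleId = "character",
        records = "data.frame",
        rejected = "data.frame",
        metadata = "list"
    )
)

setValidity("SamplePopulation", function(object) {
    msg <- NULL
    if (length(object@sampleId) != 1L)
        msg <- c(msg, "'sampleId' must be a single string")
    if (nrow(object@records) > 0) {
        need <- c("cell_id", "dc_um", "confinement", "di_max")
        if (!all(need %in% names(object@records)))
            msg <- c(msg, "records missing required columns")
        else if (any(object@records$confinement <= 0))
            msg <- c(msg, "confinement must be strictly positive")
    }
    if (is.null(msg)) TRUE else msg
})

setMethod("show", "SamplePopulation", function(object) {
    gate <- object@metadata$gate
    cat(sprintf("SamplePopulation '%s': n = %d accepted, %d rejected%s\n",
                object@sampleId, nrow(object@records), nrow(object@rejected),
                if (is.null(gate)) "" else
                    sprintf(", gated to (%g, %g)", gate[1], gate[2])))
    if (nrow(object@records) > 0)
        cat(sprintf("  median DI_max = %.4f, median Dc = %.2f um\n",
                    stats::median(object@records$di_max),
                    stats::median(object@records$dc_um)))
})

#' @export
setMethod("sampleId", "SamplePopulation", function(object) object@sampleId)

#' @export
setMethod("cellRecords", "SamplePopulation", function(object) object@records)

#' @export
setMethod("sampleMetadata", "SamplePopulation", function(object) object@metadata)

#' @export
setMethod("diMax", "SamplePopulation", function(object) object@records$di_max)
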