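#' Coordinate frame of the imaged region of interest
#'
#' Fixes the mapping between pixel indices and physical micrometre
#' coordinates. The x axis runs along the flow with \eqn{x = 0} at the
#' test-section entrance and \eqn{x = L} at the exit; the ROI spans
#' \eqn{[-mW, L + mW]} where `m` is the geometry's ROI margin in channel
#' widths. The y axis is transverse with \eqn{y = 0} on the channel
#' centreline. Pixels follow a 0-based, pixel-centre convention: column `j`
#' is centred at \eqn{x_{min} + (j + 0.5) \cdot px}, so subpixel centroids
#' are meaningful.
#'
#' @param geom a [ChannelGeometry-class].
#' @param acq an [AcquisitionConfig-class].
#' @return a list with `x_min`, `x_max`, `y_min`, `y_max` (um), `nrow`,
#'   `ncol`, `pixel_size_um`, `roi_length_um`, and converter functions
#'   `colToX`, `xToCol`, `rowToY`, `yToRow` (0-based fractional indices).
#' @examples
#' fr <- coordinateFrame(channelGeometry(), acquisitionConfig())
#' fr$roi_length_um  # 230 + 2 * 5 * 18 = 410
#' @export
coordinateFrame <- function(geom, acq) {
    stopifnot(is(geom, "ChannelGeometry"), is(acq, "AcquisitionConfig"))
    validObject(geom); validObject(acq)
    px <- acq@pixelSizeUm
    m <- geom@roiMarginWidths
    x_min <- -m * geom@widthUm
    x_max <- geom@testLengthUm + m * geom@widthUm
    roi_len <- x_max - x_min
    nr <- acq@imageShapePx[1]
    nc <- acq@imageShapePx[2]
    if (roi_len > nc * px + 1e-9)
        stop(sprintf(
            "ROI length %.1f um exceeds image extent %.1f um at %.3g um/px",
            roi_len, nc * px, px))
    y_min <- -nr * px / 2
    list(
        x_min = x_min, x_max = x_max,
        y_min = y_min, y_max = y_min + nr * px,
        nrow = nr, ncol = nc,
        pixel_size_um = px, roi_length_um = roi_len,
        colToX = function(j) x_min + (j + 0.5) * px,
        xToCol = function(x) (x - x_min) / px - 0.5,
        rowToY = function(i) y_min + (i + 0.5) * px,
        yToRow = function(y) (y - y_min) / px - 0.5
    )
}

#' Read or write an analysis configuration file
#'
#' One JSON or YAML file carries both the channel geometry and the
#' acquisition parameters under the keys
#' `geometry.{width_um,height_um,test_length_um,roi_margin_widths}` and
#' `acquisition.{pixel_size_um,frame_rate_fps,driving_pressure_kpa,`
#' `exposure_us,image_shape_px}`. Missing keys fall back to the reference
#' defaults, so a partial file is valid.
#'
#' @param path file path; format chosen by extension (`.json`, `.yaml`/`.yml`).
#' @return `readAnalysisConfig`: a list with elements `geometry`
#'   ([ChannelGeometry-class]) and `acquisition` ([AcquisitionConfig-class]).
#' @export
readAnalysisConfig <- function(path) {
    ext <- tolower(tools::file_ext(path))
    raw <- switch(ext,
        json = jsonlite::read_json(path, simplifyVector = TRUE),
        yaml = ,
        yml = yaml::read_yaml(path),
        stop("config must be .json or .yaml/.yml"))
    g <- raw$geometry %||% list()
    a <- raw$acquisition %||% list()
    geom <- channelGeometry(
        widthUm = g$width_um %||% 18,
        heightUm = g$height_um %||% 19.8,
        testLengthUm = g$test_length_um %||% 230,
        roiMarginWidths = g$roi_margin_widths %||% 5)
    acq <- acquisitionConfig(
        pixelSizeUm = a$pixel_size_um %||% 0.97,
        frameRateFps = a$frame_rate_fps %||% 15000,
        drivingPressureKpa = a$driving_pressure_kpa %||% 15,
        exposureUs = a$exposure_us %||% 1,
        imageShapePx = unlist(a$image_shape_px) %||% c(464L, 504L))
    list(geometry = geom, acquisition = acq)
}

#' @rdname readAnalysisConfig
#' @param geom a [ChannelGeometry-class] to serialise.
#' @param acq an [AcquisitionConfig-class] to serialise.
#' @export
writeAnalysisConfig <- function(geom, acq, path) {
    cfg <- list(
        geometry = list(
            width_um = geom@widthUm, height_um = geom@heightUm,
            test_length_um = geom@testLengthUm,
            roi_margin_widths = geom@roiMarginWidths),
        acquisition = list(
            pixel_size_um = acq@pixelSizeUm,
            frame_rate_fps = acq@frameRateFps,
            driving_pressure_kpa = acq@drivingPressureKpa,
            exposure_us = acq@exposureUs,
            image_shape_px = as.integer(acq@imageShapePx)))
    ext <- tolower(tools::file_ext(path))
    if (ext == "json") {
        jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA)
    } else {
        yaml::write_yaml(cfg, path)
    }
    invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
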