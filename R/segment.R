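#' Equivalent circular diameter
#'
#' Diameter of the circle with the same projected area as the object,
#' \eqn{D = 2\sqrt{A/\pi}}. The undeformed cell diameter \eqn{D_c} is this
#' quantity computed from pre-entry frames.
#'
#' @param areaUm2 projected area (um^2), > 0; vectorised.
#' @return diameter (um).
#' @examples
#' equivalentDiameter(pi * 7.5^2)  # 15
#' @export
equivalentDiameter <- function(areaUm2) {
    if (any(areaUm2 <= 0)) stop("area must be positive")
    2 * sqrt(areaUm2 / pi)
}

#' Segmentation parameters
#'
#' @param gaussianSigmaPx Gaussian smoothing of the background-subtracted
#'   difference image, in pixels.
#' @param threshold fixed binarisation threshold on the normalised (0-1)
#'   difference image; `NULL` (default) uses Otsu's method with a floor of
#'   `minThresholdFrac`.
#' @param minThresholdFrac lower bound on the automatic threshold, as a
#'   fraction of the 16-bit dynamic range; keeps Otsu from chasing noise on
#'   frames with faint or no objects.
#' @param minDiameterUm components with equivalent diameter below this are
#'   discarded as debris (default 7 um, far below any cell of interest and
#'   far below the 0.85 confinement gate, so it cannot bias gated
#'   populations).
#' @param maxSingleDiameterUm blobs with equivalent diameter above this are
#'   treated as touching objects and split on the distance-map watershed
#'   (default 20 um, just above the channel height: no single
#'   channel-confined object can project a larger equivalent diameter,
#'   while any merge of two gateable cells always does).
#' @param contourSigmaPx Gaussian smoothing applied to the image the
#'   subpixel contour is extracted from. Curvature-dependent contour bias
#'   grows as sigma^2 (an iso-level on a smoothed edge shifts inward by
#'   ~kappa sigma^2/2), so this is kept well below the binarisation
#'   smoothing; default 0.6 px.
#' @param contourSource where the subpixel 0.5 iso-contour is taken:
#'   `"difference"` (default) contours the lightly smoothed difference
#'   image, restricted to the component's neighbourhood, at half the
#'   component's plateau amplitude; `"mask"` smooths the binarised
#'   component mask and contours it at 0.5, depending only on the binary
#'   mask but inheriting the full binarisation smoothing bias.
#' @param blankMinPixels frames with fewer than this many pixels above
#'   `1.25 * minThresholdFrac` are declared blank and skipped.
#' @return list of parameters for [segmentFrame()].
#' @export
segmentationParams <- function(gaussianSigmaPx = 1, threshold = NULL,
                               minThresholdFrac = 0.08, minDiameterUm = 7,
                               maxSingleDiameterUm = 20,
                               contourSigmaPx = 0.6,
                               contourSource = c("difference", "mask"),
                               blankMinPixels = 10L) {
    list(gaussianSigmaPx = gaussianSigmaPx, threshold = threshold,
         minThresholdFrac = minThresholdFrac, minDiameterUm = minDiameterUm,
         maxSingleDiameterUm = maxSingleDiameterUm,
         contourSigmaPx = contourSigmaPx,
         contourSource = match.arg(contourSource),
         blankMinPixels = blankMinPixels)
}

## Uniform access to frames from an array, a multi-page TIFF or a synthetic
## ground-truth object (rendered on demand, so long recordings never need to
## be held in memory).
frameSource <- function(x) {
    if (inherits(x, "msdcTruth")) {
        list(n = x$nFrames, read = function(idx) renderFrames(x, idx))
    } else if (is.array(x) && length(dim(x)) == 3L) {
        list(n = dim(x)[3], read = function(idx) x[, , idx, drop = FALSE])
    } else if (is.matrix(x)) {
        a <- array(x, dim = c(dim(x), 1L))
        list(n = 1L, read = function(idx) a[, , idx, drop = FALSE])
    } else if (is.character(x) && length(x) == 1L) {
        pages <- tiff::readTIFF(x, all = TRUE, info = FALSE)
        if (is.matrix(pages)) pages <- list(pages)
        list(n = length(pages),
             read = function(idx) {
                 out <- array(0, dim = c(dim(pages[[1]]), length(idx)))
                 for (k in seq_along(idx))
                     out[, , k] <- pages[[idx[k]]] * 65535
                 out
             })
    } else stop("unsupported frame source")
}

#' Estimate the static background of a recording
#'
#' Per-pixel temporal median over a strided subsample of frames (at most
#' `nSample`, evenly spaced). Transiting cells are sparse in time, so the
#' median recovers the illumination field — including any static gradient
#' and the channel walls — which is then subtracted before binarisation.
#'
#' @param x frame stack: 3-D array `[rows, cols, frames]`, a multi-page TIFF
#'   path, or an `msdcTruth` object.
#' @param nSample maximum number of frames used (default 64).
#' @return background image (matrix, same units as the frames).
#' @export
estimateBackground <- function(x, nSample = 64L) {
    src <- frameSource(x)
    if (src$n < 25L)
        stop("need >= 25 frames to estimate a temporal-median background; ",
             "pass a static background image instead")
    idx <- unique(round(seq(1L, src$n, length.out = min(nSample, src$n))))
    stack <- src$read(idx)
    apply(stack, c(1, 2), stats::median)
}

#' Segment one frame into object observations
#'
#' The measurement chain is: absolute background-subtracted difference,
#' Gaussian smoothing, global Otsu threshold (with floor, or a fixed
#' override), morphological closing (3x3 disc) and hole filling, connected
#' components, size filter with watershed splitting of over-sized blobs —
#' then, for every surviving component, a *subpixel* closed contour is
#' extracted (marching-squares interpolation): by default the half-amplitude
#' iso-level of the lightly smoothed difference image restricted to the
#' component's neighbourhood (see [segmentationParams()] for the
#' mask-contour alternative), measured by the shoelace formula (area),
#' polygonal arc length (perimeter) and polygon first moments (centroid).
#' Pixel-edge perimeters
#' overestimate disk perimeters by up to ~27%, which would swamp the 0.024
#' bead DI error bound; the subpixel contour is what makes that calibration
#' contract attainable.
#'
#' Components touching the image border are measured but flagged
#' (`touches_border`), since their area and perimeter are truncated. A blank
#' frame yields an empty table, not an error.
#'
#' @param frame image matrix (16-bit scale).
#' @param background background matrix from [estimateBackground()].
#' @param geom,acq geometry and acquisition configuration (for the um
#'   mapping).
#' @param params list from [segmentationParams()].
#' @return data.frame with one row per detected object: `label`, `area_um2`,
#'   `perimeter_um`, `x_um`, `y_um`, `bbox_xmin`..`bbox_ymax`,
#'   `touches_border`, `n_pixels`.
#' @export
segmentFrame <- function(frame, background, geom, acq,
                         params = segmentationParams()) {
    stopifnot(all(dim(frame) == dim(background)))
    fr <- coordinateFrame(geom, acq)
    px <- fr$pixel_size_um
    empty <- .emptyObs()
    d <- abs(frame - background) / 65535
    ## cheap blank-frame screen before any filtering
    active <- d > 1.25 * params$minThresholdFrac
    if (sum(active) < params$blankMinPixels)
        return(empty)
    ## restrict filtering to the active column range (plus margin): objects
    ## occupy a small part of the long ROI, and the crop cuts the per-frame
    ## cost without changing what is measured
    nc_full <- ncol(frame)
    acols <- range(which(colSums(active) > 0L))
    c0 <- max(1L, acols[1] - 12L); c1 <- min(nc_full, acols[2] + 12L)
    col_off <- c0 - 1L
    d <- d[, c0:c1, drop = FALSE]
    ds <- EBImage::gblur(d, sigma = params$gaussianSigmaPx)
    thr <- params$threshold
    if (is.null(thr))
        thr <- max(EBImage::otsu(ds, range = c(0, 1)),
                   params$minThresholdFrac)
    mask <- ds > thr
    if (!any(mask)) return(empty)
    mask <- EBImage::closing(mask, EBImage::makeBrush(3, "disc"))
    mask <- EBImage::fillHull(mask)
    lab <- EBImage::bwlabel(mask)
    if (max(lab) == 0) return(empty)
    ## Blobs larger than any single channel-confined object (equivalent
    ## diameter above ~ the channel height) must be touching cells; split
    ## them on the distance-map watershed. Blobs a single object could
    ## produce are never split, so elongated cells cannot be cut in two.
    sizes <- tabulate(lab)
    big <- which(equivalentDiameter(pmax(sizes, 1L) * px^2) >
                 params$maxSingleDiameterUm)
    if (length(big) > 0L) {
        ws <- EBImage::imageData(EBImage::watershed(EBImage::distmap(mask),
                                                    tolerance = 1, ext = 1))
        inbig <- lab %in% big
        lab[inbig] <- max(lab) + ws[inbig]
    }
    labs <- sort(unique(lab[lab > 0L]))
    nlab <- length(labs)
    nr <- nrow(frame); nc <- ncol(d)
    dc_img <- NULL      # lazily smoothed contour image, shared by components
    out <- vector("list", nlab)
    for (k in seq_len(nlab)) {
        l <- labs[k]
        sel <- lab == l
        npix <- sum(sel)
        if (equivalentDiameter(npix * px^2) < params$minDiameterUm) next
        ij <- which(sel, arr.ind = TRUE)
        touches <- any(ij[, 1] == 1L) || any(ij[, 1] == nr) ||
                   any(ij[, 2] + col_off == 1L) ||
                   any(ij[, 2] + col_off == nc_full)
        ## crop with margin, pad with zeros so the iso-contour always closes
        pad <- 4L
        i0 <- max(1L, min(ij[, 1]) - pad); i1 <- min(nr, max(ij[, 1]) + pad)
        j0 <- max(1L, min(ij[, 2]) - pad); j1 <- min(nc, max(ij[, 2]) + pad)
        crop <- matrix(0, i1 - i0 + 3L, j1 - j0 + 3L)
        core <- 2:(i1 - i0 + 2L); corej <- 2:(j1 - j0 + 2L)
        if (params$contourSource == "difference") {
            ## contour the lightly smoothed difference at half the plateau
            ## amplitude, restricted to this component's neighbourhood so
            ## ramps of nearby objects cannot join the contour
            if (is.null(dc_img))
                dc_img <- EBImage::gblur(d, sigma = params$contourSigmaPx)
            dsc <- dc_img[i0:i1, j0:j1, drop = FALSE]
            near <- EBImage::dilate(sel[i0:i1, j0:j1],
                                    EBImage::makeBrush(5, "disc"))
            dsc[!near] <- 0
            ## a touching sibling from the watershed split shares an
            ## intensity ramp with this component; cut it at the split line
            labc <- lab[i0:i1, j0:j1]
            dsc[labc != l & labc != 0L] <- 0
            crop[core, corej] <- dsc
            level <- 0.5 * stats::quantile(dc_img[sel], 0.75, names = FALSE)
            level <- max(level, thr / 2)
        } else {
            crop[core, corej] <- sel[i0:i1, j0:j1] * 1.0
            crop <- EBImage::gblur(crop, sigma = max(params$contourSigmaPx, 1))
            level <- 0.5
        }
        cl <- grDevices::contourLines(seq_len(nrow(crop)), seq_len(ncol(crop)),
                                      crop, levels = level)
        if (length(cl) == 0L) next
        polys <- lapply(cl, function(g) cbind(g$x, g$y))
        areas <- vapply(polys, polygonArea, numeric(1))
        poly <- polys[[which.max(areas)]]
        ## crop index -> full-image matrix index -> physical um
        poly_i <- poly[, 1] - 1L + i0 - 1L   # 1-based row index, continuous
        poly_j <- poly[, 2] - 1L + j0 - 1L + col_off
        poly_um <- cbind(fr$x_min + (poly_j - 0.5) * px,
                         fr$y_min + (poly_i - 0.5) * px)
        a <- polygonArea(poly_um)
        if (a <= 0) next
        row <- function(poly, np) {
            pa <- polygonArea(poly)
            ctr <- polygonCentroid(poly)
            data.frame(
                label = k, area_um2 = pa,
                perimeter_um = polygonPerimeter(poly),
                x_um = ctr[1], y_um = ctr[2],
                bbox_xmin = min(poly[, 1]), bbox_xmax = max(poly[, 1]),
                bbox_ymin = min(poly[, 2]), bbox_ymax = max(poly[, 2]),
                touches_border = touches, n_pixels = np)
        }
        if (equivalentDiameter(a) > params$maxSingleDiameterUm) {
            ## contact train the watershed could not separate: divide at
            ## the half-area plane so both members stay trackable
            halves <- .splitPolyHalfArea(poly_um)
            out[[k]] <- rbind(row(halves[[1]], as.integer(round(npix / 2))),
                              row(halves[[2]], npix - as.integer(round(npix / 2))))
        } else {
            out[[k]] <- row(poly_um, npix)
        }
    }
    out <- do.call(rbind, out)
    if (is.null(out)) empty else out
}

#' Segment a whole recording
#'
#' Runs [segmentFrame()] over every frame of a stack, reading (or, for
#' synthetic truth objects, rendering) frames in chunks so arbitrarily long
#' recordings fit in memory.
#'
#' @inheritParams estimateBackground
#' @param geom,acq geometry and acquisition configuration.
#' @param params list from [segmentationParams()].
#' @param background optional background matrix; estimated from the stack
#'   when `NULL`.
#' @param frames optional subset of frame indices.
#' @param chunkSize frames read per chunk.
#' @return data.frame of observations with a leading `frame` column.
#' @export
segmentStack <- function(x, geom, acq, params = segmentationParams(),
                         background = NULL, frames = NULL,
                         chunkSize = 256L) {
    src <- frameSource(x)
    if (is.null(background)) background <- estimateBackground(x)
    if (is.null(frames)) frames <- seq_len(src$n)
    out <- list()
    for (start in seq(1L, length(frames), by = chunkSize)) {
        idx <- frames[start:min(start + chunkSize - 1L, length(frames))]
        stack <- src$read(idx)
        for (k in seq_along(idx)) {
            obs <- segmentFrame(stack[, , k], background, geom, acq, params)
            if (nrow(obs) > 0L)
                out[[length(out) + 1L]] <- cbind(frame = idx[k], obs)
        }
    }
    res <- do.call(rbind, out)
    if (is.null(res)) res <- cbind(frame = integer(0), .emptyObs())
    rownames(res) <- NULL
    res
}

.emptyObs <- function() {
    data.frame(label = integer(0), area_um2 = numeric(0),
               perimeter_um = numeric(0), x_um = numeric(0),
               y_um = numeric(0), bbox_xmin = numeric(0),
               bbox_xmax = numeric(0), bbox_ymin = numeric(0),
               bbox_ymax = numeric(0), touches_border = logical(0),
               n_pixels = integer(0))
}

## Sutherland-Hodgman clip of a closed polygon against the half-plane
## x <= xcut (side = -1) or x >= xcut (side = +1).
.clipPolyX <- function(xy, xcut, side) {
    n <- nrow(xy)
    keep <- function(x) if (side < 0) x <= xcut else x >= xcut
    out <- matrix(numeric(0), ncol = 2)
    for (k in seq_len(n)) {
        p <- xy[k, ]; q <- xy[if (k == n) 1L else k + 1L, ]
        pin <- keep(p[1]); qin <- keep(q[1])
        if (pin) out <- rbind(out, p)
        if (pin != qin) {
            t <- (xcut - p[1]) / (q[1] - p[1])
            out <- rbind(out, c(xcut, p[2] + t * (q[2] - p[2])))
        }
    }
    out
}

## Divide an over-sized contour (a contact train the watershed cannot
## separate: no distance-map basin exists when a cell nose rests on a flat
## rear) at the plane normal to the flow that halves its area. The halves
## exist for tracking and occupancy counting; their cut-edge shapes are
## removed from DI summaries by the coincidence rule.
.splitPolyHalfArea <- function(xy) {
    a <- polygonArea(xy)
    xr <- range(xy[, 1])
    xcut <- stats::uniroot(function(x)
        polygonArea(.clipPolyX(xy, x, -1)) - a / 2,
        interval = xr + c(1e-6, -1e-6) * diff(xr), tol = 1e-9)$root
    list(.clipPolyX(xy, xcut, -1), .clipPolyX(xy, xcut, 1))
}
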