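#' Deformation index
#'
#' The central shape readout: \deqn{DI = 1 - \frac{2\sqrt{\pi A}}{p}} where
#' \eqn{A} is the projected (cross-sectional) area and \eqn{p} the perimeter
#' of the cell outline. The DI of a perfect circle is zero and grows towards
#' one as the outline departs from circularity; it is scale invariant and
#' equals \eqn{1 - \sqrt{4\pi A / p^2}}, i.e. one minus the square root of
#' the usual circularity.
#'
#' By the isoperimetric inequality \eqn{p^2 \ge 4\pi A}, so DI is
#' non-negative for any true contour. Subpixel contour noise on near-perfect
#' disks can push the measured perimeter marginally below the bound; values
#' negative by less than `1e-9` are clamped to zero, larger violations raise
#' a "non-physical contour" error since they indicate a perimeter-estimator
#' bug rather than noise.
#'
#' @param areaUm2 projected area (um^2), > 0; vectorised.
#' @param perimeterUm perimeter (um), > 0; vectorised.
#' @return deformation index in `[0, 1)`.
#' @examples
#' deformationIndex(pi, 2 * pi)        # unit circle: 0
#' deformationIndex(1, 4)              # unit square: 1 - sqrt(pi)/2
#' @export
deformationIndex <- function(areaUm2, perimeterUm) {
    if (any(areaUm2 <= 0) || any(perimeterUm <= 0))
        stop("area and perimeter must be positive")
    di <- 1 - 2 * sqrt(pi * areaUm2) / perimeterUm
    bad <- di < -1e-9
    if (any(bad))
        stop(sprintf(
            "non-physical contour: perimeter^2 < 4*pi*area (DI = %.3g)",
            min(di)))
    pmax(di, 0)
}

#' Per-cell DI profile along the channel
#'
#' Raw (unsmoothed) deformation index as a function of centroid x position
#' for one track, using only usable observations: non-coincident,
#' non-border-touching, non-interpolated frames. Ordered by x.
#'
#' @param trackObs data.frame of one cell's observations (rows of a
#'   [TrackSet-class] observations table).
#' @return data.frame with columns `x_um`, `di`; zero rows when no
#'   observation is usable.
#' @export
diProfile <- function(trackObs) {
    use <- !trackObs$coincident & !trackObs$touches_border
    if (!is.null(trackObs$interpolated)) use <- use & !trackObs$interpolated
    if (!is.null(trackObs$area_outlier)) use <- use & !trackObs$area_outlier
    obs <- trackObs[use, , drop = FALSE]
    if (nrow(obs) == 0L)
        return(data.frame(x_um = numeric(0), di = numeric(0)))
    obs <- obs[order(obs$x_um), , drop = FALSE]
    data.frame(x_um = obs$x_um,
               di = deformationIndex(obs$area_um2, obs$perimeter_um))
}

#' Pooled moving-average DI profile
#'
#' Population-level DI(x) curve in the style of deformation-versus-position
#' plots: all (x, DI) points from all (already gated) cells are pooled,
#' binned in x, averaged per bin, and the bin means are smoothed with a
#' centred `window`-point moving average (three points by default); bins near
#' the ends use a symmetric shrunken window.
#'
#' @param profiles list of per-cell profiles as returned by [diProfile()], or
#'   a single data.frame with columns `x_um`, `di`.
#' @param window odd moving-average width in bins (default 3); `window = 1`
#'   returns the raw bin means.
#' @param binWidthUm x bin width in micrometres (default 10).
#' @return data.frame with `x_um` (bin centres), `mean_di`, `n` (points per
#'   bin).
#' @export
movingAverageProfile <- function(profiles, window = 3L, binWidthUm = 10) {
    stopifnot(window >= 1L, window %% 2L == 1L, binWidthUm > 0)
    if (is.data.frame(profiles)) profiles <- list(profiles)
    pooled <- do.call(rbind, profiles)
    if (is.null(pooled) || nrow(pooled) == 0L)
        return(data.frame(x_um = numeric(0), mean_di = numeric(0),
                          n = integer(0)))
    bin <- floor(pooled$x_um / binWidthUm)
    mean_di <- tapply(pooled$di, bin, mean)
    n <- as.integer(table(bin))
    centers <- (as.numeric(names(mean_di)) + 0.5) * binWidthUm
    ord <- order(centers)
    mean_di <- as.numeric(mean_di)[ord]; centers <- centers[ord]; n <- n[ord]
    half <- (window - 1L) %/% 2L
    k <- length(mean_di)
    sm <- vapply(seq_len(k), function(i) {
        h <- min(half, i - 1L, k - i)   # shrink symmetrically at the ends
        mean(mean_di[(i - h):(i + h)])
    }, numeric(1))
    data.frame(x_um = centers, mean_di = sm, n = n)
}
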