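#' @export
setMethod("confinementGate", "SamplePopulation",
    function(object, lo = 0.85, hi = 0.95) {
    stopifnot(lo > 0, lo < hi)
    rec <- object@records
    keep <- rec$confinement > lo & rec$confinement < hi   # strict open interval
    object@records <- rec[keep, , drop = FALSE]
    object@metadata$gate <- c(lo, hi)
    object
})

.tierLadder <- function(p) {
    if (p < 1e-5) "****"
    else if (p < 1e-4) "***"
    else if (p < 1e-3) "**"
    else if (p < 0.01) "*"
    else "ns"
}

#' One-tailed Mann-Whitney U comparison
#'
#' Rank-sum comparison of two deformability samples, used because gated
#' DI_max distributions are non-normal (log-normal). The U statistic counts
#' (a, b) pairs won by `a`, with midranks for ties. The p value is exact (full
#' enumeration of labellings) when `n1 * n2 <= 400` and there are no ties,
#' otherwise a normal approximation with tie and continuity corrections is
#' used. Significance tiers at level 0.01: `ns` (p > 0.01), `*` (p < 0.01),
#' `**` (p < 0.001), `***` (p < 0.0001), `****` (p < 0.00001); the most
#' extreme applicable tier wins. (The `*` rung is not used in the reference
#' figure captions, which jump from ns to `**`; it is defined here so the
#' ladder is total.)
#'
#' @param a,b numeric samples (e.g. gated per-cell DI_max values).
#' @param alternative direction of the alternative hypothesis for `b`
#'   relative to `a`: `"greater"` tests whether `b` tends to exceed `a`.
#' @return list of class `msdcComparison`: `u_statistic`, `p_value`, `tier`,
#'   `n1`, `n2`, `direction`, `exact`.
#' @examples
#' mannWhitneyOneTailed(c(1, 2, 3), c(4, 5, 6), "greater")$p_value  # 0.05
#' @export
mannWhitneyOneTailed <- function(a, b, alternative = c("greater", "less")) {
    alternative <- match.arg(alternative)
    if (length(a) < 1L || length(b) < 1L) stop("empty sample")
    ties <- any(duplicated(c(a, b)))
    exact <- !ties && length(a) * length(b) <= 400
    ## alternative is stated for b; wilcox.test states it for the first arg
    wt <- suppressWarnings(stats::wilcox.test(
        a, b,
        alternative = if (alternative == "greater") "less" else "greater",
        exact = exact, correct = TRUE))
    structure(list(u_statistic = unname(wt$statistic),
                   p_value = wt$p.value, tier = .tierLadder(wt$p.value),
                   n1 = length(a), n2 = length(b),
                   direction = alternative, exact = exact),
              class = "msdcComparison")
}

#' @export
print.msdcComparison <- function(x, ...) {
    cat(sprintf(
        "Mann-Whitney U = %g (n1 = %d, n2 = %d, b %s), p = %.3g [%s]%s\n",
        x$u_statistic, x$n1, x$n2, x$direction, x$p_value, x$tier,
        if (x$exact) " (exact)" else ""))
    invisible(x)
}

#' Dose-response analysis and minimum effective concentration
#'
#' For each drug dose the gated DI_max distribution is compared with the
#' untreated control. A change "in either direction" must be caught while
#' keeping the one-tailed testing convention, so each dose runs both
#' one-tailed Mann-Whitney tests against control and the more significant
#' tail wins, Bonferroni-corrected within the pair (each tail judged at
#' `alpha / 2`). `Cmin` is the smallest dose whose test passes; the
#' direction label is `"DI increases (softening)"` or
#' `"DI decreases (stiffening)"` from the winning tail, and `"No change"`
#' when no dose passes (Cmin = none). The response pattern over doses at and
#' above Cmin is classified by the same paired test between successive
#' doses: `"Monotonic increase"`, `"Monotonic decrease"`, `"No change"`, or
#' `"Non-monotonic"`.
#'
#' @param control a gated [SamplePopulation-class] (no drug).
#' @param doses list of gated `SamplePopulation`s; doses are taken from each
#'   population's `metadata$dose_um` and must be sorted ascending.
#' @param alpha significance level (default 0.01).
#' @return list with `cmin` (dose, or `NA` for none), `direction`,
#'   `pattern`, and `comparisons` (per-dose data.frame: dose, n, U, winning
#'   one-tailed p, tier, direction, significant).
#' @export
doseResponseCmin <- function(control, doses, alpha = 0.01) {
    if (length(doses) < 1L) stop("need at least one dose population")
    dvals <- vapply(doses, function(p) as.numeric(sampleMetadata(p)$dose_um),
                    numeric(1))
    if (any(is.na(dvals)) || is.unsorted(dvals, strictly = TRUE))
        stop("dose populations must carry metadata$dose_um, ascending")
    c_di <- diMax(control)
    pair <- function(x, y) {
        up <- mannWhitneyOneTailed(x, y, "greater")
        dn <- mannWhitneyOneTailed(x, y, "less")
        win <- if (up$p_value <= dn$p_value) up else dn
        list(win = win, sig = win$p_value < alpha / 2)
    }
    cmp <- lapply(doses, function(p) pair(c_di, diMax(p)))
    comparisons <- data.frame(
        dose_um = dvals,
        n = vapply(doses, function(p) length(diMax(p)), numeric(1)),
        u_statistic = vapply(cmp, function(z) z$win$u_statistic, numeric(1)),
        p_value = vapply(cmp, function(z) z$win$p_value, numeric(1)),
        tier = vapply(cmp, function(z) z$win$tier, character(1)),
        direction = vapply(cmp, function(z) z$win$direction, character(1)),
        significant = vapply(cmp, function(z) z$sig, logical(1)))
    hit <- which(comparisons$significant)
    if (length(hit) == 0L)
        return(list(cmin = NA_real_, direction = "No change",
                    pattern = "No change", comparisons = comparisons))
    i0 <- hit[1]
    direction <- if (comparisons$direction[i0] == "greater")
        "DI increases (softening)" else "DI decreases (stiffening)"
    ## successive-dose pattern at and above Cmin
    idx <- i0:length(doses)
    signs <- integer(0)
    if (length(idx) >= 2L) {
        for (k in seq_len(length(idx) - 1L)) {
            z <- pair(diMax(doses[[idx[k]]]), diMax(doses[[idx[k + 1L]]]))
            signs <- c(signs, if (!z$sig) 0L
                       else if (z$win$direction == "greater") 1L else -1L)
        }
    }
    pattern <- if (length(signs) == 0L || all(signs == 0L)) "No change"
        else if (any(signs > 0L) && any(signs < 0L)) "Non-monotonic"
        else if (all(signs >= 0L)) "Monotonic increase"
        else "Monotonic decrease"
    list(cmin = dvals[i0], direction = direction, pattern = pattern,
         comparisons = comparisons)
}

#' Linear DI-pressure response
#'
#' Ordinary least-squares fit of the gated mean DI against driving pressure
#' — deformation increases linearly with pressure over the working range.
#'
#' @param points data.frame with columns `pressure_kpa` and `mean_di`
#'   (>= 3 distinct pressures).
#' @return list with `slope` (DI per kPa), `intercept`, `r_squared`.
#' @export
pressureResponseFit <- function(points) {
    if (length(unique(points$pressure_kpa)) < 3L)
        stop("need >= 3 distinct pressures")
    fit <- stats::lm(mean_di ~ pressure_kpa, data = points)
    ## collinear input is legitimate; silence the perfect-fit note
    r2 <- suppressWarnings(summary(fit)$r.squared)
    list(slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         r_squared = r2)
}

#' Iso-density contour of a (confinement, DI) scatter
#'
#' Two-dimensional Gaussian kernel density estimate (Scott's bandwidth,
#' \eqn{\hat\sigma n^{-1/6}} per axis) of the per-cell scatter, returned as
#' the closed iso-contour(s) at `levelFraction` of the peak density — the
#' "50% maximal event density" outline drawn on scatter density plots.
#'
#' @param points data.frame or matrix with two columns (confinement, DI);
#'   >= 50 points.
#' @param levelFraction contour level as a fraction of the maximum density
#'   (default 0.5).
#' @param gridSize KDE grid resolution per axis.
#' @return list of closed contour polygons (data.frames with `x`, `y`),
#'   with the density grid in `attr(,"density")`.
#' @export
densityContour <- function(points, levelFraction = 0.5, gridSize = 128L) {
    points <- as.matrix(points)
    if (nrow(points) < 50L) stop("need >= 50 points")
    sx <- stats::sd(points[, 1]); sy <- stats::sd(points[, 2])
    if (sx == 0 || sy == 0) stop("degenerate point set")
    n <- nrow(points)
    ## MASS::kde2d uses h/4 as the kernel sd
    h <- 4 * c(sx, sy) * n^(-1 / 6)
    pad <- 3 * c(sx, sy)
    kd <- MASS::kde2d(points[, 1], points[, 2], h = h, n = gridSize,
                      lims = c(range(points[, 1]) + c(-1, 1) * pad[1],
                               range(points[, 2]) + c(-1, 1) * pad[2]))
    lev <- levelFraction * max(kd$z)
    cl <- grDevices::contourLines(kd$x, kd$y, kd$z, levels = lev)
    if (length(cl) == 0L) stop("no contour at the requested level")
    polys <- lapply(cl, function(g) data.frame(x = g$x, y = g$y))
    attr(polys, "density") <- kd
    polys
}

#' Manifold pressure-distribution quality control
#'
#' Verifies that the shared pressure source drives all channels equally:
#' rigid-bead velocities are summarised per channel and the maximum relative
#' deviation of any channel mean from the grand mean must stay within
#' `toleranceFraction` (default 3%). Channels with fewer than 20 beads are
#' warned about; channels with none are reported as failed coverage rather
#' than crashing the report.
#'
#' @param velocities named list: one numeric vector of bead velocities (m/s)
#'   per channel.
#' @param toleranceFraction allowed relative deviation of channel means.
#' @return list with `per_channel` (data.frame: channel, n, mean, sd,
#'   deviation, coverage_ok), `grand_mean`, `max_deviation`, `pass`.
#' @export
manifoldQC <- function(velocities, toleranceFraction = 0.03) {
    if (length(velocities) < 2L) stop("need >= 2 channels")
    ch <- names(velocities) %||% as.character(seq_along(velocities))
    n <- vapply(velocities, length, integer(1))
    if (any(n > 0L & n < 20L))
        warning("channels with fewer than 20 beads: ",
                paste(ch[n > 0L & n < 20L], collapse = ", "))
    mu <- vapply(velocities, function(v) if (length(v)) mean(v) else NA_real_,
                 numeric(1))
    sd_ <- vapply(velocities,
                  function(v) if (length(v) > 1L) stats::sd(v) else NA_real_,
                  numeric(1))
    grand <- mean(mu, na.rm = TRUE)
    dev <- abs(mu - grand) / grand
    per <- data.frame(channel = ch, n = n, mean_mps = mu, sd_mps = sd_,
                      deviation = dev, coverage_ok = n > 0L)
    maxdev <- if (all(is.na(dev))) NA_real_ else max(dev, na.rm = TRUE)
    list(per_channel = per, grand_mean = grand, max_deviation = maxdev,
         pass = all(per$coverage_ok) && !is.na(maxdev) &&
                maxdev <= toleranceFraction)
}

#' @export
setMethod("boxplotSummary", "numeric", function(object) {
    if (length(object) < 1L) stop("empty sample")
    q <- stats::quantile(object, c(0.1, 0.25, 0.5, 0.75, 0.9), type = 7,
                         names = FALSE)
    list(median = q[3], q25 = q[2], q75 = q[4], p10 = q[1], p90 = q[5],
         n = length(object))
})

#' @export
setMethod("boxplotSummary", "SamplePopulation", function(object) {
    di <- diMax(object)
    if (length(di) < 1L) stop("empty population")
    if (length(di) < 100L)
        warning(sprintf(
            "n = %d < 100: below the population floor used for boxplots",
            length(di)))
    boxplotSummary(di)
})
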