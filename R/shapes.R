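## Polygon primitives (shoelace area, arc-length perimeter, first-moment
## centroid) shared by the synthetic shape family, the event-table writer and
## the subpixel contour measurements.

#' Polygon measurements
#'
#' Area (shoelace formula), perimeter (polygonal arc length) and centroid
#' (first moments) of a closed polygon given as an n x 2 vertex matrix. The
#' closing edge from the last to the first vertex is implied.
#'
#' @param xy numeric matrix with columns x, y (um); vertices in order.
#' @return `polygonArea`: absolute enclosed area; `polygonPerimeter`: total
#'   edge length; `polygonCentroid`: length-2 numeric (x, y).
#' @examples
#' sq <- cbind(c(0, 1, 1, 0), c(0, 0, 1, 1))
#' polygonArea(sq)       # 1
#' polygonPerimeter(sq)  # 4
#' @export
polygonArea <- function(xy) {
    x <- xy[, 1]; y <- xy[, 2]
    xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
    abs(sum(x * yn - xn * y)) / 2
}

#' @rdname polygonArea
#' @export
polygonPerimeter <- function(xy) {
    x <- xy[, 1]; y <- xy[, 2]
    xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
    sum(sqrt((xn - x)^2 + (yn - y)^2))
}

#' @rdname polygonArea
#' @export
polygonCentroid <- function(xy) {
    x <- xy[, 1]; y <- xy[, 2]
    xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
    cr <- x * yn - xn * y
    a <- sum(cr) / 2
    if (abs(a) < .Machine$double.eps)
        return(c(mean(x), mean(y)))
    c(sum((x + xn) * cr), sum((y + yn) * cr)) / (6 * a)
}

## ---------------------------------------------------------------------------
## Bullet shape family.
##
## Unit-radius member with elongation parameter t >= 0 (counter-clockwise):
##   - front cap: semicircle of radius 1 centred at (+t/2, 0)
##   - body: straight top/bottom edges of length t at y = +-1
##   - rear cap: semi-ellipse centred at (-t/2, 0) with x-semi-axis 1/(1+t)
## At t = 0 the shape is a circle (DI = 0); as t grows the cell elongates and
## its rear flattens, and the polygon DI increases monotonically. The family
## is capped at t = 10 (DI ~ 0.34), beyond which shapes stop resembling
## channel-confined cells.

.bullet_t_max <- 10

#' Bullet polygon of the synthetic shape family
#'
#' Returns the unit-radius "bullet" (circular front cap, straight body,
#' flattened elliptical rear) with elongation parameter `t`, discretised to
#' approximately `nVertices` vertices allocated proportionally to arc length.
#' `t = 0` gives a regular polygon approximating the unit circle.
#'
#' @param t elongation parameter in `[0, 10]`.
#' @param nVertices target vertex count (>= 64).
#' @return n x 2 vertex matrix, centroid at the origin.
#' @export
bulletPolygon <- function(t, nVertices = 256L) {
    stopifnot(t >= 0, t <= .bullet_t_max, nVertices >= 64)
    a <- 1 / (1 + t)                     # rear x-semi-axis
    ## piece lengths (Ramanujan approximation is ample for allocation)
    L_front <- pi
    h <- ((a - 1) / (a + 1))^2
    L_rear <- pi * (a + 1) * (1 + 3 * h / (10 + sqrt(4 - 3 * h))) / 2
    L_edge <- t
    L_tot <- L_front + L_rear + 2 * L_edge
    nf <- max(16L, round(nVertices * L_front / L_tot))
    nr <- max(16L, round(nVertices * L_rear / L_tot))
    ne <- if (t > 0) max(2L, round(nVertices * L_edge / L_tot)) else 0L

    th_f <- seq(-pi / 2, pi / 2, length.out = nf + 1L)
    front <- cbind(t / 2 + cos(th_f), sin(th_f))
    th_r <- seq(pi / 2, 3 * pi / 2, length.out = nr + 1L)
    rear <- cbind(-t / 2 + a * cos(th_r), sin(th_r))
    if (ne > 0L) {
        xe <- seq(t / 2, -t / 2, length.out = ne + 1L)
        top <- cbind(xe, rep(1, ne + 1L))
        bottom <- cbind(-xe, rep(-1, ne + 1L))
    } else {
        top <- front[nrow(front), , drop = FALSE]
        bottom <- rear[nrow(rear), , drop = FALSE]
    }
    ## drop duplicated junction points
    xy <- rbind(front[-nrow(front), ], top[-nrow(top), ],
                rear[-nrow(rear), ], bottom[-nrow(bottom), ])
    ctr <- polygonCentroid(xy)
    sweep(xy, 2, ctr)
}

.polygonDI <- function(xy) deformationIndex(polygonArea(xy), polygonPerimeter(xy))

#' Construct a polygon with prescribed area and deformation index
#'
#' Realises a cell outline of the bullet family whose exact polygon area
#' equals `areaUm2` (to 1e-6 relative) and whose exact polygon DI — computed
#' from the polygon's own shoelace area and arc-length perimeter — equals
#' `targetDi` to within 1e-3, by 1-D root finding on the family's elongation
#' parameter. `targetDi = 0` returns a regular polygon approximating a
#' circle. Used to plant shapes of known DI so the downstream DI estimator
#' can be validated against ground truth.
#'
#' @param areaUm2 target polygon area (um^2), > 0.
#' @param targetDi target deformation index in `[0, 0.5)`; values above the
#'   family's reachable maximum (about 0.34) raise a "shape infeasible" error.
#' @param nVertices vertex count (>= 64, default 256).
#' @return n x 2 vertex matrix (um) centred on its centroid, with attributes
#'   `t` (elongation parameter), `di` and `area_um2` (achieved values).
#' @examples
#' sh <- makeShape(pi * 7.5^2, targetDi = 0.1)
#' attr(sh, "di")
#' @export
makeShape <- function(areaUm2, targetDi, nVertices = 256L) {
    stopifnot(areaUm2 > 0, nVertices >= 64)
    if (targetDi < 0 || targetDi >= 0.5)
        stop("'targetDi' must be in [0, 0.5)")
    if (targetDi == 0) {
        xy <- bulletPolygon(0, nVertices)
        tt <- 0
    } else {
        di_hi <- .polygonDI(bulletPolygon(.bullet_t_max, nVertices))
        if (targetDi > di_hi)
            stop(sprintf(
                "shape infeasible: target DI %.4g exceeds family maximum %.4g",
                targetDi, di_hi))
        tt <- stats::uniroot(
            function(t) .polygonDI(bulletPolygon(t, nVertices)) - targetDi,
            interval = c(0, .bullet_t_max), tol = 1e-12)$root
        xy <- bulletPolygon(tt, nVertices)
    }
    xy <- xy * sqrt(areaUm2 / polygonArea(xy))
    structure(xy, t = tt, di = .polygonDI(xy), area_um2 = polygonArea(xy))
}

## Monotone interpolation table t(DI) for one vertex count, so the renderer
## and event-table writer do not root-find per frame. Cached per nVertices.
.shape_table_env <- new.env(parent = emptyenv())

.bulletTable <- function(nVertices) {
    key <- as.character(nVertices)
    tab <- .shape_table_env[[key]]
    if (is.null(tab)) {
        tg <- c(0, pmin(exp(seq(log(1e-3), log(.bullet_t_max),
                                length.out = 80)), .bullet_t_max))
        dig <- vapply(tg, function(t) .polygonDI(bulletPolygon(t, nVertices)),
                      numeric(1))
        ## enforce strict monotonicity for the inverse spline
        keep <- c(TRUE, diff(dig) > 1e-12)
        tab <- list(
            di_max = max(dig),
            tOfDi = stats::splinefun(dig[keep], tg[keep], method = "hyman"))
        .shape_table_env[[key]] <- tab
    }
    tab
}

## Fast variant of makeShape used inside the renderer: interpolated t, no
## root polishing (|DI error| < 1e-4 over the grid).
.shapeForDI <- function(areaUm2, di, nVertices = 128L) {
    if (di <= 0) {
        xy <- bulletPolygon(0, nVertices)
    } else {
        tab <- .bulletTable(nVertices)
        di <- min(di, tab$di_max)
        tt <- min(max(tab$tOfDi(di), 0), .bullet_t_max)
        xy <- bulletPolygon(tt, nVertices)
    }
    xy * sqrt(areaUm2 / polygonArea(xy))
}
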