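# Closed-form DI oracles, frozen from independent computations:
#  - square of side s: A = s^2, p = 4s  =>  DI = 1 - sqrt(pi)/2
#  - 2:1 ellipse (semi-axes 2, 1): perimeter 4*2*E(e), e^2 = 3/4, by the
#    complete elliptic integral (pracma::ellipke) = 9.6884482, DI 0.0828486
.di_square <- 1 - sqrt(pi) / 2            # 0.11377307454724206
.p_ellipse21 <- 9.688448220547675
.di_ellipse21 <- 0.0828494229

test_that("deformation index matches closed forms and is zero for a circle", {
    expect_identical(deformationIndex(pi, 2 * pi), 0)       # unit circle
    expect_equal(deformationIndex(pi * 7.5^2, 2 * pi * 7.5), 0)
    expect_equal(deformationIndex(1, 4), .di_square, tolerance = 1e-12)
    expect_equal(deformationIndex(3^2, 4 * 3), .di_square, tolerance = 1e-12)
    expect_equal(deformationIndex(2 * pi, .p_ellipse21), .di_ellipse21,
                 tolerance = 1e-6)
    if (requireNamespace("pracma", quietly = TRUE)) {
        # recompute the ellipse perimeter oracle in place
        p <- 8 * pracma::ellipke(3 / 4)$e
        expect_equal(p, .p_ellipse21, tolerance = 1e-12)
    }
})

test_that("deformation index is scale invariant and equals 1 - sqrt(circularity)", {
    set.seed(1)
    for (i in 1:50) {
        a <- runif(1, 0.1, 500); p <- sqrt(4 * pi * a) * runif(1, 1, 3)
        k <- runif(1, 0.01, 100)
        expect_equal(deformationIndex(k^2 * a, k * p),
                     deformationIndex(a, p), tolerance = 1e-12)
        circ <- 4 * pi * a / p^2
        expect_equal(deformationIndex(a, p), 1 - sqrt(circ),
                     tolerance = 1e-12)
    }
})

test_that("tiny isoperimetric violations clamp to zero, larger ones error", {
    a <- pi; p_exact <- 2 * pi
    expect_identical(deformationIndex(a, p_exact * (1 - 1e-12)), 0)
    expect_error(deformationIndex(a, p_exact * 0.99), "non-physical")
    expect_error(deformationIndex(-1, 4), "positive")
    expect_error(deformationIndex(1, 0), "positive")
})

test_that("polygon area/perimeter estimators reproduce regular-polygon closed forms", {
    sq <- cbind(c(0, 2, 2, 0), c(0, 0, 2, 2))
    expect_equal(polygonArea(sq), 4)
    expect_equal(polygonPerimeter(sq), 8)
    expect_equal(polygonCentroid(sq), c(1, 1))
    # inscribed regular n-gon: DI = pi^2 / (6 n^2) + O(n^-4); perimeter -> pi D
    for (n in c(64, 256, 1024)) {
        th <- 2 * pi * seq_len(n) / n
        gon <- cbind(cos(th), sin(th))
        di <- deformationIndex(polygonArea(gon), polygonPerimeter(gon))
        expect_equal(di, pi^2 / (6 * n^2), tolerance = 1e-3)
        expect_equal(polygonPerimeter(gon), 2 * n * sin(pi / n),
                     tolerance = 1e-12)
    }
})

test_that("makeShape hits prescribed area exactly and DI within 1e-3", {
    # circle limit
    sh0 <- makeShape(pi * 7.5^2, targetDi = 0)
    expect_lt(attr(sh0, "di"), 1e-4)
    expect_equal(polygonArea(sh0), pi * 7.5^2, tolerance = 1e-6)
    # the 2:1-ellipse DI value realised in the bullet family
    sh <- makeShape(2 * pi, targetDi = 0.083)
    expect_equal(attr(sh, "di"), 0.083, tolerance = 1e-3)
    expect_equal(polygonArea(sh), 2 * pi, tolerance = 1e-6 * 2 * pi)
    for (target in c(0.02, 0.1, 0.25)) {
        sh <- makeShape(100, targetDi = target)
        expect_equal(
            deformationIndex(polygonArea(sh), polygonPerimeter(sh)),
            target, tolerance = 1e-3)
        expect_equal(polygonArea(sh), 100, tolerance = 1e-4)
    }
    expect_error(makeShape(10, targetDi = 0.45), "shape infeasible")
    expect_error(makeShape(10, targetDi = 0.6), "must be in")
    expect_error(makeShape(10, targetDi = 0.1, nVertices = 16), ">= 64")
})

test_that("bullet-family DI is strictly increasing in the elongation parameter", {
    tgrid <- seq(0, 10, length.out = 60)
    di <- vapply(tgrid, function(t) {
        p <- bulletPolygon(t, 256)
        deformationIndex(polygonArea(p), polygonPerimeter(p))
    }, numeric(1))
    expect_true(all(diff(di) > 0))
    expect_equal(di[1], pi^2 / (6 * 256^2), tolerance = 1e-2)
})

test_that("diProfile orders by x and drops coincident/border frames", {
    obs <- syntheticTrackObs(c(50, -30, 120, 250), diameter_um = 16)
    obs$perimeter_um[3] <- obs$perimeter_um[3] * 1.1   # deformed frame
    obs$coincident[4] <- TRUE
    obs$touches_border[2] <- TRUE
    pr <- diProfile(obs)
    expect_equal(pr$x_um, c(50, 120))      # sorted, filtered
    expect_equal(pr$di[1], 0)
    expect_equal(pr$di[2], 1 - 1 / 1.1, tolerance = 1e-9)
    # single usable observation -> one-point profile
    expect_equal(nrow(diProfile(syntheticTrackObs(42))), 1L)
    # nothing usable -> empty
    expect_equal(nrow(diProfile(syntheticTrackObs(42, coincident = TRUE))), 0L)
})

test_that("moving-average profile reproduces direct-convolution oracle", {
    # constant DI: smoothing is a no-op
    const <- data.frame(x_um = runif(500, 0, 300), di = 0.07)
    sm <- movingAverageProfile(const, window = 3)
    expect_true(all(abs(sm$mean_di - 0.07) < 1e-12))
    # window 1 returns raw bin means
    set.seed(3)
    pts <- data.frame(x_um = runif(2000, 0, 200), di = runif(2000, 0, 0.2))
    raw <- movingAverageProfile(pts, window = 1)
    bin <- floor(pts$x_um / 10)
    expect_equal(raw$mean_di,
                 as.numeric(tapply(pts$di, bin, mean)))
    # planted ramp: smoothed curve equals the bin means convolved with the
    # centred window (computed independently here)
    ramp <- data.frame(x_um = seq(0.05, 299.95, by = 0.05))
    ramp$di <- 0.001 * ramp$x_um
    sm3 <- movingAverageProfile(ramp, window = 3)
    bm <- as.numeric(tapply(ramp$di, floor(ramp$x_um / 10), mean))
    k <- length(bm)
    oracle <- vapply(seq_len(k), function(i) {
        h <- min(1, i - 1, k - i)
        mean(bm[(i - h):(i + h)])
    }, numeric(1))
    expect_equal(sm3$mean_di, oracle, tolerance = 1e-12)
    expect_true(all(abs(sm3$mean_di - 0.001 * sm3$x_um) < 0.005))
    # empty input
    expect_equal(nrow(movingAverageProfile(list())), 0L)
})
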