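test_that("confinement gate is a strict open interval with correct arithmetic", {
    geom <- channelGeometry(18, 19.8)
    dh <- hydraulicDiameter(geom)                 # 18.857 um
    lo <- 0.85 * dh; hi <- 0.95 * dh              # (16.03, 17.91) um
    expect_equal(lo, 16.03, tolerance = 1e-3)
    expect_equal(hi, 17.91, tolerance = 1e-3)
    dc <- c(15.9, lo, lo + 1e-9, 16.5, 17.2, hi - 1e-9, hi, 18.2)
    rec <- data.frame(sample_id = "s", cell_id = seq_along(dc), dc_um = dc,
                      confinement = dc / dh, di_max = 0.1,
                      velocity_mps = 0.3, n_frames_used = 5L,
                      reject_reason = NA_character_)
    gated <- confinementGate(assemblePopulation(rec))
    # records exactly at the bounds are excluded
    expect_setequal(cellRecords(gated)$cell_id, c(3L, 4L, 5L, 6L))
    # idempotent
    expect_identical(cellRecords(confinementGate(gated)),
                     cellRecords(gated))
    expect_equal(sampleMetadata(gated)$gate, c(0.85, 0.95))
    # all records far below the gate: empty gated population
    low <- rec; low$confinement <- 0.5
    expect_equal(nrow(cellRecords(confinementGate(assemblePopulation(low)))),
                 0L)
})

test_that("Mann-Whitney exact p matches a brute-force enumeration oracle", {
    # full enumeration over all C(6,3) = 20 labelings: complete separation
    res <- mannWhitneyOneTailed(c(1, 2, 3), c(4, 5, 6), "greater")
    expect_equal(res$u_statistic, 0)
    expect_equal(res$p_value, 1 / 20)
    expect_true(res$exact)
    # independent oracle: enumerate every split of the pooled sample
    set.seed(8)
    for (rep in 1:5) {
        a <- round(runif(4), 3); b <- round(runif(4) + 0.2, 3)
        pooled <- c(a, b)
        u_obs <- sum(outer(a, b, ">"))
        splits <- utils::combn(8, 4)
        u_all <- apply(splits, 2, function(ix)
            sum(outer(pooled[ix], pooled[-ix], ">")))
        p_oracle <- mean(u_all <= u_obs)
        expect_equal(mannWhitneyOneTailed(a, b, "greater")$p_value,
                     p_oracle, tolerance = 1e-12)
    }
})

test_that("normal approximation with continuity correction tracks the exact p", {
    set.seed(12)
    for (rep in 1:20) {
        a <- runif(10); b <- runif(10) + runif(1, 0, 0.3)
        exact <- mannWhitneyOneTailed(a, b, "greater")
        expect_true(exact$exact)
        # manual normal approximation (the large-sample route)
        u <- exact$u_statistic
        mu <- 100 / 2; sg <- sqrt(10 * 10 * 21 / 12)
        p_norm <- stats::pnorm((u + 0.5 - mu) / sg)
        expect_lt(abs(p_norm - exact$p_value), 0.01)
    }
})

test_that("identical samples are ns; tier ladder is total and ordered", {
    set.seed(2)
    x <- rlnormDi(60)
    res <- mannWhitneyOneTailed(x, x, "greater")
    expect_equal(res$tier, "ns")
    expect_gt(res$p_value, 0.4)
    # planted 1.5x median shift at n = 150: detected in >= 95% of replicates
    set.seed(77)
    hits <- vapply(1:100, function(i) {
        a <- rlnormDi(150, median = 0.1)
        b <- rlnormDi(150, median = 0.15)
        mannWhitneyOneTailed(a, b, "greater")$tier != "ns"
    }, logical(1))
    expect_gte(mean(hits), 0.95)
    expect_error(mannWhitneyOneTailed(numeric(0), 1:3), "empty")
})

test_that("dose-response Cmin finds the lowest effective dose and its direction", {
    doses_um <- c(0.1, 1, 10, 50)
    set.seed(101)
    mk <- function(median) diPopulation(rlnormDi(150, median = median))
    # softening planted at doses >= 1 uM
    ctrl <- diPopulation(rlnormDi(150, 0.1))
    arms <- Map(function(d, m) diPopulation(rlnormDi(150, m), dose_um = d),
                doses_um, c(0.1, 0.15, 0.15, 0.15))
    res <- doseResponseCmin(ctrl, unname(arms))
    expect_equal(res$cmin, 1)
    expect_equal(res$direction, "DI increases (softening)")
    expect_equal(res$pattern, "No change")   # flat above Cmin
    # stiffening at the lowest dose only, flat above
    arms2 <- Map(function(d, m) diPopulation(rlnormDi(150, m), dose_um = d),
                 doses_um, c(0.06, 0.06, 0.06, 0.06))
    res2 <- doseResponseCmin(ctrl, unname(arms2))
    expect_equal(res2$cmin, 0.1)
    expect_equal(res2$direction, "DI decreases (stiffening)")
    expect_equal(res2$pattern, "No change")
    # monotone escalation above Cmin
    arms3 <- Map(function(d, m) diPopulation(rlnormDi(400, m), dose_um = d),
                 doses_um, c(0.1, 0.14, 0.2, 0.28))
    res3 <- doseResponseCmin(ctrl, unname(arms3))
    expect_equal(res3$cmin, 1)
    expect_equal(res3$pattern, "Monotonic increase")
    # all arms null: Cmin = none
    arms0 <- Map(function(d) diPopulation(rlnormDi(150, 0.1), dose_um = d),
                 doses_um)
    res0 <- doseResponseCmin(ctrl, unname(arms0))
    expect_true(is.na(res0$cmin))
    expect_equal(res0$direction, "No change")
    expect_error(doseResponseCmin(ctrl, list()), "at least one dose")
})

test_that("pressure response fit recovers slope, intercept and R^2", {
    pk <- c(3, 5, 7, 10, 15, 25, 30)
    exact <- data.frame(pressure_kpa = pk, mean_di = 0.004 * pk + 0.01)
    fit <- pressureResponseFit(exact)
    expect_equal(fit$slope, 0.004, tolerance = 1e-12)
    expect_equal(fit$intercept, 0.01, tolerance = 1e-12)
    expect_equal(fit$r_squared, 1)
    # constant DI: slope 0
    flat <- data.frame(pressure_kpa = pk, mean_di = 0.07)
    expect_equal(pressureResponseFit(flat)$slope, 0)
    # noisy linear map: slope within 2 standard errors
    set.seed(9)
    noisy <- data.frame(pressure_kpa = pk,
                        mean_di = 0.004 * pk + 0.01 + rnorm(7, 0, 0.005))
    fitn <- pressureResponseFit(noisy)
    se <- summary(stats::lm(mean_di ~ pressure_kpa,
                            noisy))$coefficients[2, 2]
    expect_lt(abs(fitn$slope - 0.004), 2 * se)
    expect_error(pressureResponseFit(exact[1:2, ]), ">= 3 distinct")
})

test_that("density contour matches the analytic Gaussian half-peak ellipse", {
    set.seed(15)
    n <- 4000
    sx <- 0.03; sy <- 0.02
    pts <- cbind(0.9 + rnorm(n, 0, sx), 0.1 + rnorm(n, 0, sy))
    polys <- densityContour(pts, levelFraction = 0.5)
    expect_equal(length(polys), 1L)
    # contour contains the sample mean
    ctr <- polys[[1]]
    expect_true(min(ctr$x) < 0.9 && max(ctr$x) > 0.9)
    expect_true(min(ctr$y) < 0.1 && max(ctr$y) > 0.1)
    # enclosed area vs analytic 50%-of-peak iso-density ellipse,
    # pi * 2ln2 * sqrt(det Sigma), allowing KDE bandwidth inflation
    a_meas <- polygonArea(cbind(ctr$x, ctr$y))
    a_true <- pi * 2 * log(2) * sx * sy
    expect_lt(abs(a_meas - a_true) / a_true, 0.10)
    # two far-separated clusters: two disjoint contours
    pts2 <- rbind(pts, cbind(1.4 + rnorm(n, 0, sx), 0.5 + rnorm(n, 0, sy)))
    expect_equal(length(densityContour(pts2, 0.5)), 2L)
    # enclosed area shrinks as the level rises
    areas <- vapply(c(0.3, 0.5, 0.7), function(lv) {
        g <- densityContour(pts, lv)[[1]]
        polygonArea(cbind(g$x, g$y))
    }, numeric(1))
    expect_true(all(diff(areas) < 0))
    expect_error(densityContour(pts[1:10, ]), ">= 50")
    expect_error(densityContour(cbind(rep(1, 60), rep(2, 60))), "degenerate")
})

test_that("manifold QC passes uniform channels and fails a 5% outlier", {
    v <- lapply(1:10, function(i) rep(0.30, 25))
    names(v) <- paste0("ch", 1:10)
    qc <- manifoldQC(v)
    expect_true(qc$pass)
    expect_equal(qc$max_deviation, 0)
    v$ch3 <- rep(0.30 * 1.05, 25)
    expect_false(manifoldQC(v)$pass)
    # 1% measurement noise, equal planted velocity: pass in >= 95% of runs
    set.seed(33)
    ok <- vapply(1:40, function(i) {
        vv <- lapply(1:10, function(ch) rnorm(30, 0.30, 0.003))
        manifoldQC(vv)$pass
    }, logical(1))
    expect_gte(mean(ok), 0.95)
    # zero-bead channel: failed coverage, not a crash
    v0 <- list(a = rep(0.3, 25), b = numeric(0))
    qc0 <- manifoldQC(v0)
    expect_false(qc0$pass)
    expect_false(qc0$per_channel$coverage_ok[2])
    expect_warning(manifoldQC(list(a = rep(0.3, 25), b = rep(0.3, 5))),
                   "fewer than 20")
})

test_that("boxplot summary uses interpolated quantiles and warns below n=100", {
    s <- boxplotSummary(as.numeric(1:9))
    expect_equal(s$median, 5)
    expect_equal(s$q25, 3)
    expect_equal(s$q75, 7)
    expect_equal(s$p10, 1.8)
    expect_equal(s$p90, 8.2)
    expect_equal(s$n, 9L)
    one <- boxplotSummary(7)
    expect_true(all(unlist(one[c("median", "q25", "q75", "p10", "p90")]) == 7))
    pop <- diPopulation(rlnormDi(50))
    expect_warning(boxplotSummary(pop), "below the population floor")
    big <- diPopulation(rlnormDi(150))
    expect_silent(s2 <- boxplotSummary(big))
    expect_equal(s2$n, 150L)
})
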