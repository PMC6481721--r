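test_that("undeformed diameter uses pre-entry frames only", {
    geom <- testGeom(); acq <- testAcq()
    x <- seq(-85, 315, by = 20)
    obs <- syntheticTrackObs(x, diameter_um = 16)
    base <- summarizeCell(obs, TRUE, geom, acq)
    expect_true(is.na(base$reject_reason))
    expect_equal(base$dc_um, 16, tolerance = 1e-12)
    expect_equal(base$confinement, 16 / hydraulicDiameter(geom))
    # artificially deform every in-section frame: dc must not move at all
    deformed <- obs
    sec <- deformed$x_um >= 0
    deformed$area_um2[sec] <- deformed$area_um2[sec] * 1.4
    deformed$perimeter_um[sec] <- deformed$perimeter_um[sec] * 1.6
    d2 <- summarizeCell(deformed, TRUE, geom, acq)
    expect_identical(d2$dc_um, base$dc_um)
    expect_gt(d2$di_max, base$di_max)
    # conversely, pre-entry manipulation cannot move di_max
    pre <- obs$x_um < 0
    obs2 <- obs; obs2$perimeter_um[pre] <- obs2$perimeter_um[pre] * 2
    expect_identical(summarizeCell(obs2, TRUE, geom, acq)$di_max,
                     base$di_max)
})

test_that("di_max is the maximum DI before exit, coincident frames excluded", {
    geom <- testGeom(); acq <- testAcq()
    x <- seq(-85, 315, by = 20)
    obs <- syntheticTrackObs(x, diameter_um = 16)
    # plant the largest DI on a coincident frame: it must be ignored
    insec <- which(obs$x_um >= 0 & obs$x_um <= geom@testLengthUm)
    obs$perimeter_um[insec] <- obs$perimeter_um[insec] * 1.05
    peak <- insec[length(insec) - 1L]
    obs$perimeter_um[peak] <- obs$perimeter_um[peak] * 1.2
    obs$coincident[peak] <- TRUE
    # and an even larger DI after the exit: also ignored
    post <- which(obs$x_um > geom@testLengthUm)
    obs$perimeter_um[post] <- obs$perimeter_um[post] * 1.5
    rec <- summarizeCell(obs, TRUE, geom, acq)
    expect_equal(rec$di_max, 1 - 1 / 1.05, tolerance = 1e-9)
})

test_that("rejection reasons are first-class outputs", {
    geom <- testGeom(); acq <- testAcq()
    x <- seq(-85, 315, by = 20)
    expect_equal(summarizeCell(syntheticTrackObs(x), FALSE, geom,
                               acq)$reject_reason, "invalid_track")
    # no pre-entry observation
    xin <- x[x >= 0]
    expect_equal(summarizeCell(syntheticTrackObs(xin, frames = seq_along(xin)),
                               TRUE, geom, acq)$reject_reason, "no_preentry")
    # all in-section frames coincident
    obs <- syntheticTrackObs(x)
    obs$coincident[obs$x_um >= 0 & obs$x_um <= geom@testLengthUm] <- TRUE
    expect_equal(summarizeCell(obs, TRUE, geom, acq)$reject_reason,
                 "coincidence")
})

test_that("rendered beads recover planted diameter and stay under the DI error bound", {
    run <- beadRun()
    sm <- run$cells$records
    gt <- groundTruthRecords(run$truth)
    expect_equal(nrow(sm), nrow(gt))
    expect_true(all(abs(sort(sm$dc_um) - sort(gt$diameter_um)) < 0.97))
    expect_true(all(sm$di_max < 0.024))
    expect_true(all(sm$di_max >= 0))
})

test_that("rendered cells recover the planted DI profile and maximum", {
    run <- cellRun()
    sm <- run$cells$records
    gt <- groundTruthRecords(run$truth)
    expect_gte(nrow(sm), nrow(gt) - 1L)    # at most one coincidence casualty
    # per-cell di_max within segmentation tolerance of the planted value
    gt_sorted <- gt[order(gt$diameter_um), ]
    sm_sorted <- sm[order(sm$dc_um), ]
    keep <- seq_len(min(nrow(sm_sorted), nrow(gt_sorted)))
    expect_lt(stats::median(abs(sm_sorted$di_max[keep] -
                                gt_sorted$di_max[keep])), 0.015)
    # raw per-cell profile tracks the planted DI(x) curve
    obs <- run$tracks@observations
    id <- sm$cell_id[1]
    pr <- diProfile(obs[obs$cell_id == id, ])
    gi <- which.min(abs(gt$diameter_um - sm$dc_um[1]))
    planted <- trueDiAt(pr$x_um, gt$di_max[gi], run$geom@testLengthUm)
    expect_lt(stats::median(abs(pr$di - planted)), 0.015)
})

test_that("populations assemble, merge channels, and refuse mixed samples", {
    rec <- data.frame(sample_id = "s1", cell_id = 1:120, dc_um = 17,
                      confinement = 0.9, di_max = 0.1, velocity_mps = 0.3,
                      n_frames_used = 10L, reject_reason = NA_character_)
    pop <- assemblePopulation(rec, metadata = list(cell_line = "MCF7",
                                                   channel_index = 1:2))
    expect_s4_class(pop, "SamplePopulation")
    expect_equal(nrow(cellRecords(pop)), 120L)
    expect_equal(sampleId(pop), "s1")
    # two channels of one sample merge under one id
    two <- rbind(rec[1:60, ], rec[61:120, ])
    expect_equal(nrow(cellRecords(assemblePopulation(two))), 120L)
    # empty population allowed
    expect_equal(nrow(cellRecords(assemblePopulation(rec[0, ]))), 0L)
    rec2 <- rec; rec2$sample_id[1] <- "s2"
    expect_error(assemblePopulation(rec2), "multiple sample_ids")
})

test_that("event-table records reproduce planted diameters and DI exactly", {
    geom <- testGeom(); acq <- testAcq()
    truth <- sampleTransits(populationSpec(), geom, acq, 0.1, seed = 31,
                            nCells = 25)
    ev <- emitEventTable(truth)
    recs <- eventTableRecords(ev, geom, "syn")
    gt <- groundTruthRecords(truth)
    ok <- merge(recs$records, gt, by = "cell_id")
    expect_gt(nrow(ok), 20)
    expect_true(all(abs(ok$dc_um - ok$diameter_um) < 0.01))
    expect_true(all(ok$di_max.x <= ok$di_max.y + 1e-3))
    # for cells with no coincident in-section frame, a frame always lands on
    # the DI plateau (34.5 um long vs ~20 um frame spacing), so the sampled
    # maximum is the planted maximum
    L <- geom@testLengthUm
    insec <- ev[ev$x_um >= 0 & ev$x_um <= L, ]
    multi <- as.integer(names(which(table(insec$frame) >= 2)))
    clean <- setdiff(ok$cell_id,
                     unique(insec$cell_id[insec$frame %in% multi]))
    expect_gt(length(clean), 5)
    ok2 <- ok[ok$cell_id %in% clean, ]
    expect_lt(max(abs(ok2$di_max.x - ok2$di_max.y)), 0.005)
})
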