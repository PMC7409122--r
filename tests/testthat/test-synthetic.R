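test_that("the generator is deterministic for a given seed", {
    lay <- buildBatchLayout("carryover")
    lay <- rbind(lay, qcRecord())
    inst <- fastInstrument()
    sig <- signalModel()
    a1 <- simulateBatch(lay, inst, sig, seed = 5)
    a2 <- simulateBatch(lay, inst, sig, seed = 5)
    expect_identical(lapply(a1, acqScans), lapply(a2, acqScans))
    a3 <- simulateBatch(lay, inst, sig, seed = 6)
    expect_false(identical(acqScans(a1[[3]]), acqScans(a3[[3]])))
    # per-spot seeds derive from the id, not the row position
    expect_identical(acqScans(simulateBatch(lay[c(2, 1, 3), ], inst, sig,
                                            seed = 5)[["T_QC_1"]]),
                     acqScans(a1[["T_QC_1"]]))
})

test_that("degenerate layouts are rejected", {
    lay <- buildBatchLayout("carryover")
    expect_error(simulateBatch(lay[0, ], fastInstrument(), signalModel()),
                 "non-empty")
    dup <- rbind(lay, lay)
    expect_error(simulateBatch(dup, fastInstrument(), signalModel()),
                 "duplicate")
    clin <- qcRecord(role = "CLINICAL", level = "CLINICAL", conc = NA)
    expect_error(simulateSpot(clin, fastInstrument(), signalModel(),
                              seed = 1), "true_conc")
    expect_error(simulateSpot(qcRecord(), fastInstrument(), signalModel()),
                 "seed")
})

test_that("blanks carry no analyte or IS peaks", {
    inst <- fastInstrument()
    sig <- noiselessSignal()
    bv <- simulateSpot(qcRecord("BV", 0, "BV", "T_BV"), inst, sig, seed = 2)
    lloq <- simulateSpot(qcRecord(), inst, sig, seed = 2)
    # residual analyte-window signal in a blank is only interferent leakage:
    # far below the LLOQ signal (and the IS window is empty)
    expect_lt(mobA(bv, analyteWindow()), 0.02 * mobA(lloq, analyteWindow()))
    expect_equal(mobA(bv, isWindow()), 0)
    cal0 <- simulateSpot(qcRecord("CAL0", 0, "CAL0", "T_CAL0"), inst, sig,
                         seed = 2)
    expect_gt(mobA(cal0, isWindow()), 0)  # IS only
    expect_lt(mobA(cal0, analyteWindow()),
              0.02 * mobA(lloq, analyteWindow()))
})

test_that("the shared spot factor cancels under IS normalization", {
    inst <- fastInstrument()
    sig <- signalModel(replicateCv = 0, spotHeterogeneity = 0.4,
                       baselineNoise = 0)
    r1 <- qcRecord("MQC", 400, "QC_MID", "T_M1")
    r2 <- qcRecord("MQC", 400, "QC_MID", "T_M2")
    a1 <- simulateSpot(r1, inst, sig, seed = 11)
    a2 <- simulateSpot(r2, inst, sig, seed = 12)
    raw1 <- mobA(a1, analyteWindow()); raw2 <- mobA(a2, analyteWindow())
    expect_gt(abs(raw1 - raw2) / raw1, 0.02)  # raw areas differ
    y1 <- raw1 / mobA(a1, isWindow())
    y2 <- raw2 / mobA(a2, isWindow())
    expect_equal(y1, y2, tolerance = 1e-6)    # responses do not
})

test_that("expected response is linear in concentration", {
    inst <- fastInstrument()
    sig <- noiselessSignal(interferentIntensity = 0)
    resp <- vapply(c(5, 1000), function(conc) {
        acq <- simulateSpot(qcRecord("X", conc, "CAL", "T_X"), inst, sig,
                            seed = 4)
        mobA(acq, analyteWindow()) / mobA(acq, isWindow())
    }, numeric(1))
    expect_equal(resp[2] / resp[1], 200, tolerance = 1e-6)
})

test_that("expectedVolumes encodes the role semantics", {
    sig <- signalModel()
    v <- expectedVolumes(qcRecord("MQC", 400, "QC_MID"), sig)
    expect_equal(v$analyte, sig@responseSlope * 400 *
                     sig@extractionRecovery * sig@matrixFactorAnalyte)
    # post-extraction spike: no recovery loss
    vr <- expectedVolumes(qcRecord("MQC", 400, "QC_REC"), sig)
    expect_equal(vr$analyte, sig@responseSlope * 400)
    # neat eluent: no matrix, no interferent
    sigMf <- signalModel(matrixFactorAnalyte = 0.8, matrixFactorIs = 0.9)
    vel <- expectedVolumes(qcRecord("MQC", 400, "QC_EL"), sigMf)
    expect_equal(vel$analyte, sigMf@responseSlope * 400)
    expect_equal(vel$interferent, 0)
    # carry-over blank: residual fraction of the source standard
    co <- qcRecord("post_CAL1000", 0, "CARRYOVER_BLANK")
    vco <- expectedVolumes(co, sig)
    expect_equal(vco$analyte, sig@responseSlope * sig@carryoverFraction *
                     1000 * sig@extractionRecovery)
    expect_equal(vco$is, 0)
})

test_that("TIC profiles reflect matrix deposition order", {
    inst <- instrumentModel(scansPerSpot = 60L)
    pre <- simulateTicProfile(TRUE, inst, seed = 9)
    post <- simulateTicProfile(FALSE, inst, seed = 9)
    cv <- function(x) sd(x) / mean(x)
    expect_length(pre, 60L)
    expect_true(all(pre >= 0) && all(post >= 0))
    expect_lt(cv(pre), 0.2)       # stable crystallization
    expect_gt(cv(post), cv(pre))  # sparse bursts at the same seed
})
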