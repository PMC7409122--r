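test_that("mobilogram extraction selects windows exactly", {
    inst <- fastInstrument()
    acq <- manualAcquisition(data.frame(scan = 1L, driftBin = 37L,
                                        mz = 185.10, intensity = 500),
                             inst)
    mob <- extractMobilogram(acq, analyteWindow())
    expect_equal(sum(intensityValues(mob)), 500)
    expect_equal(intensityValues(mob)[37L], 500)
    expect_equal(sum(intensityValues(mob) != 0), 1L)
    # disjoint window: all-zero mobilogram, not an error
    expect_equal(sum(intensityValues(extractMobilogram(acq, isWindow()))), 0)
    # empty acquisition: all-zero
    empty <- manualAcquisition(data.frame(scan = integer(),
                                          driftBin = integer(),
                                          mz = numeric(),
                                          intensity = numeric()), inst)
    expect_equal(sum(intensityValues(extractMobilogram(empty,
                                                       analyteWindow()))), 0)
})

test_that("mobilogram totals match a brute-force sum over raw centroids", {
    inst <- fastInstrument()
    acq <- simulateSpot(qcRecord("MQC", 400, "QC_MID"), inst, signalModel(),
                        seed = 21)
    sc <- acqScans(acq)
    win <- analyteWindow()
    brute <- sum(sc$intensity[sc$mz >= win@mzLow & sc$mz <= win@mzHigh])
    expect_equal(sum(intensityValues(extractMobilogram(acq, win))), brute)
})

test_that("combined spectra are additive and conserve total intensity", {
    inst <- fastInstrument()
    one <- manualAcquisition(data.frame(scan = 1L, driftBin = 10L,
                                        mz = 185.107, intensity = 42), inst)
    prof <- combineSpectrum(one)
    expect_equal(nrow(prof), 1L)
    expect_equal(prof$intensity, 42)
    two <- manualAcquisition(data.frame(scan = c(1L, 2L),
                                        driftBin = c(10L, 55L),
                                        mz = c(185.107, 185.107),
                                        intensity = c(42, 8)), inst)
    expect_equal(combineSpectrum(two)$intensity, 50)
    # conservation on a synthetic spot
    acq <- simulateSpot(qcRecord(), inst, signalModel(), seed = 3)
    expect_equal(sum(combineSpectrum(acq)$intensity),
                 sum(acqScans(acq)$intensity))
})

test_that("MassI is the maximum binned intensity inside the window", {
    inst <- fastInstrument()
    empty <- manualAcquisition(data.frame(scan = integer(),
                                          driftBin = integer(),
                                          mz = numeric(),
                                          intensity = numeric()), inst)
    expect_equal(massI(empty, analyteWindow()), 0)
    one <- manualAcquisition(data.frame(scan = 1L, driftBin = 10L,
                                        mz = 185.107, intensity = 42), inst)
    expect_equal(massI(one, analyteWindow()), 42)
    # brute-force oracle on a synthetic spot
    acq <- simulateSpot(qcRecord("HQC", 800, "QC_HIGH"), inst,
                        signalModel(), seed = 8)
    win <- analyteWindow()
    prof <- combineSpectrum(acq)
    brute <- max(prof$intensity[prof$mz >= win@mzLow &
                                prof$mz <= win@mzHigh])
    expect_equal(massI(acq, win), brute)
})

test_that("peak detection integrates a triangular peak in closed form", {
    # symmetric triangle, height 100, base 0.5 ms, on a zero baseline:
    # area = 0.5 * base * height = 25
    grid <- seq(0.0125, 4, by = 0.025)
    y <- pmax(0, 100 * (1 - abs(grid - 1.85) / 0.25))
    mob <- new("Mobilogram", dtGrid = grid, intensity = y)
    pk <- detectMobilityPeak(mob, extractionWindow(0, 1, 1.85, 0.2))
    expect_equal(peakArea(pk), 25, tolerance = 1e-3)
    expect_equal(apexDt(pk), 1.85, tolerance = 0.025)
})

test_that("degenerate mobilograms give a zero-area peak at the expected DT", {
    grid <- seq(0.02, 4, by = 0.04)
    mob <- new("Mobilogram", dtGrid = grid,
               intensity = numeric(length(grid)))
    pk <- detectMobilityPeak(mob, extractionWindow(0, 1, 1.85, 0.2))
    expect_equal(peakArea(pk), 0)
    expect_equal(apexDt(pk), 1.85)
    expect_error(detectMobilityPeak(mob, extractionWindow(0, 1, 1.85, 10)),
                 "span")
})

test_that("the apex is assigned to the expected peak, not the interferent", {
    # two narrow Gaussians 0.04 ms apart; tolerance 0.02 ms keeps the apex
    # on the expected peak even though the neighbor is taller
    grid <- seq(0.0005, 4, by = 0.001)
    y <- 100 * exp(-(grid - 1.85)^2 / (2 * 0.008^2)) +
        180 * exp(-(grid - 1.89)^2 / (2 * 0.008^2))
    mob <- new("Mobilogram", dtGrid = grid, intensity = y)
    pk <- detectMobilityPeak(mob, extractionWindow(0, 1, 1.85, 0.02))
    expect_lte(abs(apexDt(pk) - 1.85), 0.02)
})

test_that("MobA equals the brute-force trapezoid over the detected bounds", {
    inst <- fastInstrument()
    acq <- simulateSpot(qcRecord("CAL100", 100, "CAL"), inst, signalModel(),
                        seed = 13)
    win <- analyteWindow()
    mob <- extractMobilogram(acq, win)
    pk <- detectMobilityPeak(mob, win)
    idx <- which(dtGrid(mob) >= pk@leftDt & dtGrid(mob) <= pk@rightDt)
    x <- dtGrid(mob)[idx]; y <- intensityValues(mob)[idx]
    brute <- sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
    expect_equal(peakArea(pk), brute, tolerance = 1e-12)
    expect_equal(mobA(acq, win), peakArea(pk))
})

test_that("noiseless MobA is strictly increasing and linear in conc", {
    inst <- fastInstrument()
    sig <- noiselessSignal(interferentIntensity = 0)
    areas <- vapply(c(5, 10, 20, 40), function(conc)
        mobA(simulateSpot(qcRecord("X", conc, "CAL"), inst, sig, seed = 4),
             analyteWindow()), numeric(1))
    expect_true(all(diff(areas) > 0))
    expect_equal(areas[4] / areas[1], 8, tolerance = 0.01)
})

test_that("2D maps are consistent with their marginals", {
    inst <- fastInstrument()
    one <- manualAcquisition(data.frame(scan = 1L, driftBin = 10L,
                                        mz = 185.107, intensity = 42), inst)
    m <- dtMzMap(one, c(185.0, 185.3), c(0, 4))
    expect_equal(sum(m != 0), 1L)
    expect_equal(sum(m), 42)
    acq <- simulateSpot(qcRecord("HQC", 800, "QC_HIGH"), inst,
                        signalModel(), seed = 17)
    mzR <- c(185.05, 185.25); dtR <- c(1.2, 2.6)
    m <- dtMzMap(acq, mzR, dtR)
    # conservation against the raw centroids in the selected ranges
    sc <- acqScans(acq)
    centers <- (sc$driftBin - 0.5) * (4 / 100)  # fastInstrument axis
    sel <- sc$mz >= mzR[1] & sc$mz <= mzR[2] &
        centers >= dtR[1] & centers <= dtR[2]
    expect_equal(sum(m), sum(sc$intensity[sel]))
    # m/z marginal equals the binned totals restricted to the range
    dtAll <- rowsum(sc$intensity[sel],
                    floor(sc$mz[sel] / 0.005))  # per-m/z-bin totals
    expect_equal(sort(rowSums(m)[rowSums(m) > 0]),
                 sort(as.numeric(dtAll)))
    expect_error(dtMzMap(acq, rev(mzR), dtR), "inverted")
})

test_that("W mode resolves the interferent column that V mode merges", {
    # at the LLOQ the interferent is commensurate with the analyte, so the
    # resolved/merged column structure is visible in the m/z marginal
    sig <- noiselessSignal()
    countMax <- function(mode) {
        inst <- fastInstrument(mode)
        acq <- simulateSpot(qcRecord(), inst, sig, seed = 6)
        prof <- combineSpectrum(acq)
        sel <- prof$mz >= 185.05 & prof$mz <= 185.2
        y <- prof$intensity[sel]
        sum(diff(sign(diff(y))) == -2)  # interior local maxima
    }
    expect_equal(countMax("W"), 2L)
    expect_equal(countMax("V"), 1L)
})

test_that("V-mode extraction is biased more than W-mode at the LLOQ", {
    rec <- qcRecord()
    inflation <- vapply(c("V", "W"), function(mode) {
        inst <- fastInstrument(mode)
        with_int <- mobA(simulateSpot(rec, inst, noiselessSignal(),
                                      seed = 3), analyteWindow())
        without <- mobA(simulateSpot(rec, inst,
                                     noiselessSignal(interferentIntensity = 0),
                                     seed = 3), analyteWindow())
        (with_int - without) / without
    }, numeric(1))
    expect_gt(inflation[["V"]], inflation[["W"]])
    expect_lt(inflation[["W"]], 0.01)
})
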