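test_that("precision and accuracy follow their definitions", {
    pa <- precisionAccuracy(c(10, 10, 10), 10)
    expect_equal(pa$bias_pct, 0); expect_equal(pa$cv_pct, 0)
    pa <- precisionAccuracy(c(8, 12), 10)
    expect_equal(pa$bias_pct, 0)
    expect_equal(pa$cv_pct, 100 * sd(c(8, 12)) / 10)  # ~28.28
    expect_equal(pa$cv_pct, 28.2843, tolerance = 1e-4)
    pa <- precisionAccuracy(c(11, 11, 11), 10)
    expect_equal(pa$bias_pct, 10); expect_equal(pa$cv_pct, 0)
    expect_error(precisionAccuracy(c(1, 2), 0), "> 0")
    expect_error(precisionAccuracy(5, 10), "replicates")
})

test_that("precision/accuracy match a brute-force recomputation", {
    set.seed(7)
    for (i in 1:5) {
        m <- stats::rlnorm(8, log(100), 0.2)
        pa <- precisionAccuracy(m, 100)
        mu <- sum(m) / length(m)
        s2 <- sum((m - mu)^2) / (length(m) - 1)
        expect_equal(pa$mean_measured, mu)
        expect_equal(pa$cv_pct, 100 * sqrt(s2) / mu)
        expect_equal(pa$bias_pct, 100 * (mu - 100) / 100)
    }
})

test_that("guideline acceptance limits are 15/15 (20/20 at LLOQ), strict", {
    pa <- function(cv, bias) list(cv_pct = cv, bias_pct = bias)
    expect_true(checkAcceptance(pa(12.6, -3.4), isLloq = TRUE))
    expect_false(checkAcceptance(pa(15.0, 0)))           # strict boundary
    expect_true(checkAcceptance(pa(14.99, 0)))
    expect_true(checkAcceptance(pa(15.0, 0), inclusive = TRUE))
    expect_false(checkAcceptance(pa(5, -20.1), isLloq = TRUE))
    expect_true(checkAcceptance(pa(19.9, 19.9), isLloq = TRUE))
    expect_false(checkAcceptance(pa(19.9, 19.9)))
})

test_that("specificity ratios obey the 20%/5% blank limits", {
    s <- specificityCheck(rep(0, 6), rep(0, 6), 100, 1000)
    expect_true(s$pass)
    expect_equal(s$max_analyte_ratio_pct, 0)
    s <- specificityCheck(c(rep(1, 5), 25), rep(0, 6), 100, 1000)
    expect_false(s$pass)  # one source at 25% of the LLOQ signal
    s <- specificityCheck(rep(0, 6), rep(49, 6), 100, 1000)
    expect_true(s$pass)   # IS contamination 4.9% < 5%
    expect_warning(specificityCheck(rep(0, 3), rep(0, 3), 100, 1000),
                   "fewer than 6")
})

test_that("carry-over blanks pass below 20% of the LLOQ signal", {
    expect_true(carryoverCheck(c(0, 0), c(0, 0), 100, 1000)$pass)
    expect_true(carryoverCheck(c(17, 15), c(1, 2), 100, 1000)$pass)
    expect_false(carryoverCheck(c(21, 3), c(1, 2), 100, 1000)$pass)
})

test_that("recovery compares DIL against the 100%-recovery reference", {
    r <- estimateRecovery(c(1, 1, 1, 1), c(1, 1, 1, 1), 15)
    expect_equal(r$recovery_pct, 100)
    expect_equal(r$cv_pct, 0)
    expect_error(estimateRecovery(numeric(), c(1)), "non-empty")
    expect_error(estimateRecovery(c(1), c(0, 0)), "zero")
})

test_that("the generator's extraction fraction is recoverable", {
    inst <- fastInstrument()
    mk <- function(role, sig) {
        lay <- do.call(rbind, lapply(1:2, function(r)
            qcRecord("MQC", 400, role, sprintf("T_%s_%d", role, r))))
        acqs <- simulateBatch(lay, inst, sig, seed = 31)
        extractResponses(acqs, lay, "MobA")
    }
    # co-extraction, noiseless (no interferent leakage): IS-normalized
    # recovery is exactly 100%
    sig <- noiselessSignal(interferentIntensity = 0)
    dil <- mk("QC_DIL", sig); rec <- mk("QC_REC", sig)
    r <- estimateRecovery(dil$y, rec$y, 400, "response")
    expect_equal(r$recovery_pct, 100, tolerance = 1e-6)
    # ... while raw analyte areas estimate the extraction fraction itself
    rRaw <- estimateRecovery(dil$analyte_signal, rec$analyte_signal, 400,
                             "raw")
    expect_equal(rRaw$recovery_pct, 100 * sig@extractionRecovery,
                 tolerance = 1e-6)
    # analyte-only diagnostic mode: the normalized estimator sees it too
    sigA <- noiselessSignal(recoveryMode = "analyte_only",
                            extractionRecovery = 0.536,
                            interferentIntensity = 0)
    dil <- mk("QC_DIL", sigA); rec <- mk("QC_REC", sigA)
    r <- estimateRecovery(dil$y, rec$y, 400, "response")
    expect_equal(r$recovery_pct, 53.6, tolerance = 1e-6)
})

test_that("matrix factors normalize per compound and cancel co-suppression", {
    m <- matrixFactor(c(1, 1), c(1, 1), c(1, 1), c(1, 1), 15)
    expect_equal(m$mf_analyte_pct, 100)
    expect_equal(m$mf_normalized_pct, 100)
    # analyte and IS suppressed equally: normalized MF stays 100%
    m <- matrixFactor(c(0.8, 0.8), c(0.8, 0.8), c(1, 1), c(1, 1), 15)
    expect_equal(m$mf_analyte_pct, 80)
    expect_equal(m$mf_is_pct, 80)
    expect_equal(m$mf_normalized_pct, 100)
    expect_error(matrixFactor(c(1), c(1), c(0), c(1)), "zero")
})

test_that("generator matrix multipliers are recovered by the MF design", {
    inst <- fastInstrument()
    sig <- noiselessSignal(matrixFactorAnalyte = 0.85,
                           matrixFactorIs = 0.95)
    lay <- buildBatchLayout("matrix_effect",
                            levels = c(MQC = 400), nReplicates = 2L)
    acqs <- simulateBatch(lay, inst, sig, seed = 19)
    resp <- extractResponses(acqs, lay, "MobA")
    mat <- resp[resp$role == "QC_MAT", ]; el <- resp[resp$role == "QC_EL", ]
    m <- matrixFactor(mat$analyte_signal, mat$is_signal,
                      el$analyte_signal, el$is_signal, 400)
    expect_equal(m$mf_normalized_pct, 100 * 0.85 / 0.95, tolerance = 0.01)
})

test_that("validation reports aggregate criteria and round-trip JSON", {
    ok <- list(pass = TRUE, summary = "fine")
    all_sections <- list(sensitivity = ok, calibration = ok,
                         precision_accuracy = ok, specificity = ok,
                         carryover = ok, recovery = ok, matrix_effect = ok,
                         freeze_thaw = ok)
    rep1 <- buildValidationReport(all_sections)
    expect_equal(reportVerdict(rep1), "validated")
    # missing carry-over: not assessed, overall incomplete
    rep2 <- buildValidationReport(all_sections[
        setdiff(names(all_sections), "carryover")])
    expect_equal(reportVerdict(rep2), "incomplete")
    expect_false(isTRUE(reportSections(rep2)$carryover$assessed))
    # one failing criterion: failed
    bad <- all_sections; bad$specificity$pass <- FALSE
    expect_equal(reportVerdict(buildValidationReport(bad)), "failed")
    # lossless serialization round trip
    js <- reportToJson(rep1)
    back <- reportFromJson(js)
    expect_equal(reportVerdict(back), reportVerdict(rep1))
    expect_equal(as.character(reportToJson(back)), as.character(js))
    md <- renderReport(rep2)
    expect_true(any(grepl("not assessed", md)))
})
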