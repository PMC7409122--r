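#' @include io.R
NULL

#' Default pipeline configuration
#'
#' Single source of truth for every tunable of the pipeline: instrument and
#' signal-model parameters, extraction windows, calibration acceptance
#' limits, validation thresholds, and campaign structure. Thresholds
#' default to the guideline values the assay was validated against.
#'
#' @return nested named list.
#' @export
defaultConfig <- function() {
    list(
        instrument = list(resolutionMode = "W", mzFwhm = NULL,
                          dtFwhm = 0.25, dtRange = c(0, 4), dtBins = 200L,
                          scansPerSpot = 60L, acquisitionSeconds = 60),
        signal = as.list(formals(signalModel))[
            setdiff(names(formals(signalModel)), "recoveryMode")],
        windows = list(analyteMz = c(185.094, 185.121),
                       isMz = c(189.125, 189.140), expectedDt = 1.85,
                       dtTolerance = 0.2),
        calibration = list(biasLimitPct = 15, lloqBiasLimitPct = 20,
                           minFraction = 0.75, minLevels = 6L,
                           r2Threshold = 0.988),
        validation = list(cvLimitPct = 15, biasLimitPct = 15,
                          lloqCvLimitPct = 20, lloqBiasLimitPct = 20,
                          specAnalyteLimitPct = 20, specIsLimitPct = 5,
                          recoveryCvLimitPct = 15, matrixCvLimitPct = 15),
        campaign = list(nBatches = 4L, nPaBatches = 3L,
                        freezeThawBatch = 3L, nBlankSources = 6L,
                        carryover = TRUE)
    )
}

.checkKeys <- function(config, template, prefix = "") {
    bad <- setdiff(names(config), names(template))
    if (length(bad))
        stop("unknown config key(s): ",
             paste0(prefix, bad, collapse = ", "))
    for (nm in names(config))
        if (is.list(template[[nm]]) && !is.null(names(template[[nm]])) &&
            is.list(config[[nm]]))
            .checkKeys(config[[nm]], template[[nm]],
                       prefix = paste0(prefix, nm, "$"))
    invisible(TRUE)
}

#' Validate and complete a pipeline configuration
#'
#' Merges a partial configuration over [defaultConfig()]; unknown keys are
#' rejected with a named-key error.
#'
#' @param config partial configuration list.
#' @return completed configuration.
#' @export
validateConfig <- function(config = list()) {
    template <- defaultConfig()
    .checkKeys(config, template)
    merge2 <- function(def, usr) {
        for (nm in names(usr)) {
            def[[nm]] <- if (is.list(def[[nm]]) &&
                             !is.null(names(def[[nm]])) &&
                             is.list(usr[[nm]]))
                merge2(def[[nm]], usr[[nm]]) else usr[[nm]]
        }
        def
    }
    merge2(template, config)
}

#' Read a configuration file (JSON or YAML)
#'
#' @param path file ending in .json, .yaml or .yml.
#' @return validated configuration list.
#' @export
readConfig <- function(path) {
    cfg <- if (grepl("\\.(yaml|yml)$", path, ignore.case = TRUE)) {
        if (!requireNamespace("yaml", quietly = TRUE))
            stop("YAML configs require the yaml package")
        yaml::read_yaml(path)
    } else jsonlite::read_json(path, simplifyVector = TRUE)
    validateConfig(cfg)
}

.configModels <- function(config) {
    ic <- config$instrument
    instrument <- instrumentModel(resolutionMode = ic$resolutionMode,
                                  mzFwhm = ic$mzFwhm, dtFwhm = ic$dtFwhm,
                                  dtRange = ic$dtRange, dtBins = ic$dtBins,
                                  scansPerSpot = ic$scansPerSpot,
                                  acquisitionSeconds = ic$acquisitionSeconds)
    signal <- do.call(signalModel, config$signal)
    wc <- config$windows
    list(instrument = instrument, signal = signal,
         analyteWin = extractionWindow(wc$analyteMz[1], wc$analyteMz[2],
                                       wc$expectedDt, wc$dtTolerance),
         isWin = extractionWindow(wc$isMz[1], wc$isMz[2], wc$expectedDt,
                                  wc$dtTolerance))
}

.paOf <- function(responses, fit, levelName, scope, ftAlso = TRUE) {
    sel <- responses$level == levelName & responses$valid
    if (!ftAlso) sel <- sel & responses$freeze_thaw_cycles == 0
    measured <- backCalculate(fit, responses$y[sel])
    nominal <- responses$nominal_conc_ng_per_mL[sel][1L]
    pa <- precisionAccuracy(measured, nominal, scope)
    pa$level_name <- levelName
    pa
}

#' Run a full synthetic validation campaign
#'
#' Orchestrates the end-to-end pipeline on generated data: validation
#' batches (the configured freeze/thaw batch carries additional
#' freeze/thaw QC replicates), MobA extraction, per-batch 1/x^2-weighted
#' calibration, QC back-calculation, six-source specificity blanks,
#' carry-over blanks in the final batch, and the paired recovery and
#' matrix-effect series — then assembles the validation report. Fully
#' reproducible from `(config, seed)`.
#'
#' @param config configuration list (see [defaultConfig()]); partial
#'   configs are completed via [validateConfig()].
#' @param seed integer campaign seed.
#' @param outDir optional directory for artifacts (per-batch response CSVs,
#'   fit JSON, report JSON and Markdown).
#' @return list with `report` ([ValidationReport-class]), `fits`,
#'   `responses`, `sections`, and the derived statistics.
#' @export
runCampaign <- function(config = list(), seed = 1L, outDir = NULL) {
    config <- validateConfig(config)
    mod <- .configModels(config)
    cc <- config$campaign
    vc <- config$validation
    cal <- config$calibration
    qcNames <- c("LQC", "MQC", "HQC")

    batches <- list()
    fits <- list()
    for (b in seq_len(cc$nBatches)) {
        layout <- buildBatchLayout("validation", batchId = paste0("B", b),
                                   freezeThaw = b == cc$freezeThawBatch)
        acqs <- simulateBatch(layout, mod$instrument, mod$signal,
                              seed = seed * 1000 + b)
        resp <- extractResponses(acqs, layout, "MobA", mod$analyteWin,
                                 mod$isWin)
        calPts <- resp[resp$role == "CAL" & resp$valid, ]
        fit <- fitWeightedLinear(calPts$nominal_conc_ng_per_mL, calPts$y,
                                 level = calPts$level,
                                 sampleId = calPts$sample_id)
        fit <- evaluateCalibration(fit, cal$biasLimitPct,
                                   cal$lloqBiasLimitPct, cal$minFraction,
                                   cal$minLevels, cal$r2Threshold)
        batches[[b]] <- resp
        fits[[b]] <- fit
    }
    names(batches) <- names(fits) <- paste0("B", seq_len(cc$nBatches))

    paB <- seq_len(cc$nPaBatches)

    ## sensitivity: LLOQ precision/accuracy, within each P&A batch + pooled
    lloqWithin <- lapply(paB, function(b)
        .paOf(batches[[b]], fits[[b]], "LLOQ", "within_batch"))
    lloqPooledMeas <- unlist(lapply(paB, function(b) {
        sel <- batches[[b]]$level == "LLOQ" & batches[[b]]$valid
        backCalculate(fits[[b]], batches[[b]]$y[sel])
    }))
    lloqPooled <- precisionAccuracy(lloqPooledMeas, qcLevels()[["LLOQ"]],
                                    "batch_to_batch")
    sensPass <- all(vapply(lloqWithin, checkAcceptance, logical(1),
                           isLloq = TRUE, cvLimitPct = vc$cvLimitPct,
                           biasLimitPct = vc$biasLimitPct,
                           lloqCvLimitPct = vc$lloqCvLimitPct,
                           lloqBiasLimitPct = vc$lloqBiasLimitPct)) &&
        checkAcceptance(lloqPooled, isLloq = TRUE,
                        lloqCvLimitPct = vc$lloqCvLimitPct,
                        lloqBiasLimitPct = vc$lloqBiasLimitPct)

    ## QC precision/accuracy, within-batch and pooled batch-to-batch
    qcWithin <- list(); qcPass <- TRUE
    for (b in paB) for (lv in qcNames) {
        pa <- .paOf(batches[[b]], fits[[b]], lv, "within_batch")
        pa$batch <- paste0("B", b)
        qcWithin[[paste0("B", b, "_", lv)]] <- pa
        qcPass <- qcPass && checkAcceptance(pa, cvLimitPct = vc$cvLimitPct,
                                            biasLimitPct = vc$biasLimitPct)
    }
    qcBetween <- list()
    for (lv in qcNames) {
        meas <- unlist(lapply(paB, function(b) {
            sel <- batches[[b]]$level == lv & batches[[b]]$valid
            backCalculate(fits[[b]], batches[[b]]$y[sel])
        }))
        pa <- precisionAccuracy(meas, qcLevels()[[lv]], "batch_to_batch")
        pa$level_name <- lv
        qcBetween[[lv]] <- pa
        qcPass <- qcPass && checkAcceptance(pa, cvLimitPct = vc$cvLimitPct,
                                            biasLimitPct = vc$biasLimitPct)
    }

    ## freeze/thaw QC replicates (flagged records of the freeze/thaw batch)
    fb <- cc$freezeThawBatch
    ftPas <- list(); ftPass <- TRUE
    for (lv in qcNames) {
        sel <- batches[[fb]]$level == lv & batches[[fb]]$valid &
            batches[[fb]]$freeze_thaw_cycles == 3L
        meas <- backCalculate(fits[[fb]], batches[[fb]]$y[sel])
        pa <- precisionAccuracy(meas, qcLevels()[[lv]], "within_batch")
        pa$level_name <- lv
        ftPas[[lv]] <- pa
        ftPass <- ftPass && checkAcceptance(pa, cvLimitPct = vc$cvLimitPct,
                                            biasLimitPct = vc$biasLimitPct)
    }

    ## reference signals for specificity / carry-over ratios
    allResp <- do.call(rbind, batches)
    lloqSel <- allResp$level == "LLOQ" & allResp$batch_id %in%
        paste0("B", paB)
    lloqAnalyteSignal <- min(allResp$analyte_signal[lloqSel])
    meanIsSignal <- mean(allResp$is_signal[allResp$role != "BV"])

    ## specificity: blanks from independent sources
    srcLayout <- do.call(rbind, lapply(seq_len(cc$nBlankSources),
        function(s) .record(sprintf("SRC%d_BV", s), "BV", "BV", 0,
                            "SPEC", s)))
    srcAcqs <- simulateBatch(srcLayout, mod$instrument, mod$signal,
                             seed = seed * 1000 + 101)
    srcResp <- extractResponses(srcAcqs, srcLayout, "MobA", mod$analyteWin,
                                mod$isWin)
    spec <- specificityCheck(srcResp$analyte_signal, srcResp$is_signal,
                             lloqAnalyteSignal, meanIsSignal,
                             vc$specAnalyteLimitPct, vc$specIsLimitPct,
                             minSources = cc$nBlankSources)

    ## carry-over: blanks on the former high-standard positions (the
    ## section is "not assessed" when the campaign runs no carry-over
    ## blanks)
    co <- NULL
    if (isTRUE(cc$carryover)) {
        coLayout <- buildBatchLayout("carryover",
                                     batchId = paste0("B", cc$nBatches))
        coAcqs <- simulateBatch(coLayout, mod$instrument, mod$signal,
                                seed = seed * 1000 + 102)
        coResp <- extractResponses(coAcqs, coLayout, "MobA",
                                   mod$analyteWin, mod$isWin)
        co <- carryoverCheck(coResp$analyte_signal, coResp$is_signal,
                             lloqAnalyteSignal, meanIsSignal,
                             vc$specAnalyteLimitPct, vc$specIsLimitPct)
    }

    ## recovery: paired QC DIL / QC REC series
    recLayout <- buildBatchLayout("recovery", batchId = "REC")
    recAcqs <- simulateBatch(recLayout, mod$instrument, mod$signal,
                             seed = seed * 1000 + 103)
    recResp <- extractResponses(recAcqs, recLayout, "MobA", mod$analyteWin,
                                mod$isWin)
    recov <- lapply(qcNames, function(lv) {
        dil <- recResp[recResp$role == "QC_DIL" & recResp$level == lv, ]
        rec <- recResp[recResp$role == "QC_REC" & recResp$level == lv, ]
        list(response = estimateRecovery(dil$y, rec$y,
                                         qcLevels()[[lv]], "response"),
             raw = estimateRecovery(dil$analyte_signal, rec$analyte_signal,
                                    qcLevels()[[lv]], "raw"))
    })
    names(recov) <- qcNames
    recCvs <- vapply(recov, function(r) r$response$cv_pct, numeric(1))
    recPass <- all(recCvs < vc$recoveryCvLimitPct)

    ## matrix effect: paired QC MAT / QC EL series
    mfLayout <- buildBatchLayout("matrix_effect", batchId = "MAT")
    mfAcqs <- simulateBatch(mfLayout, mod$instrument, mod$signal,
                            seed = seed * 1000 + 104)
    mfResp <- extractResponses(mfAcqs, mfLayout, "MobA", mod$analyteWin,
                               mod$isWin)
    mfs <- lapply(qcNames, function(lv) {
        mat <- mfResp[mfResp$role == "QC_MAT" & mfResp$level == lv, ]
        el <- mfResp[mfResp$role == "QC_EL" & mfResp$level == lv, ]
        matrixFactor(mat$analyte_signal, mat$is_signal, el$analyte_signal,
                     el$is_signal, qcLevels()[[lv]])
    })
    names(mfs) <- qcNames
    mfPass <- all(vapply(mfs, function(m) m$cv_pct, numeric(1)) <
                      vc$matrixCvLimitPct)

    calPass <- all(vapply(fits, function(f) isTRUE(f@verdict), logical(1)))
    sections <- list(
        sensitivity = list(pass = sensPass, within = lloqWithin,
                           pooled = lloqPooled,
                           summary = sprintf(
                               "LLOQ 5 ng/mL: pooled CV %.1f%%, bias %.1f%%",
                               lloqPooled$cv_pct, lloqPooled$bias_pct)),
        calibration = list(pass = calPass,
                           r2 = vapply(fits, calR2, numeric(1)),
                           verdicts = vapply(fits, function(f) f@verdict,
                                             logical(1)),
                           summary = sprintf("r2 %.4f-%.4f over %d batches",
                               min(vapply(fits, calR2, numeric(1))),
                               max(vapply(fits, calR2, numeric(1))),
                               cc$nBatches)),
        precision_accuracy = list(pass = qcPass, within = qcWithin,
                                  between = qcBetween),
        specificity = list(pass = spec$pass, detail = spec,
                           summary = sprintf(
                               "max analyte %.2f%%, max IS %.2f%%",
                               spec$max_analyte_ratio_pct,
                               spec$max_is_ratio_pct)),
        carryover = if (is.null(co)) NULL else
            list(pass = co$pass, detail = co,
                 summary = sprintf("max analyte %.2f%%, max IS %.2f%%",
                                   co$max_analyte_ratio_pct,
                                   co$max_is_ratio_pct)),
        recovery = list(pass = recPass, byLevel = recov,
                        mean_raw_recovery_pct = mean(vapply(
                            recov, function(r) r$raw$recovery_pct,
                            numeric(1)))),
        matrix_effect = list(pass = mfPass, byLevel = mfs,
                             mean_normalized_mf_pct = mean(vapply(
                                 mfs, function(m) m$mf_normalized_pct,
                                 numeric(1)))),
        freeze_thaw = list(pass = ftPass, byLevel = ftPas)
    )
    report <- buildValidationReport(sections)

    if (!is.null(outDir)) {
        if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
        for (b in names(batches))
            utils::write.csv(batches[[b]],
                             file.path(outDir,
                                       paste0("responses_", b, ".csv")),
                             row.names = FALSE)
        jsonlite::write_json(
            lapply(fits, function(f) list(intercept = f@intercept,
                                          slope = f@slope, r2 = f@r2,
                                          verdict = f@verdict)),
            file.path(outDir, "calibration_fits.json"),
            auto_unbox = TRUE, digits = NA)
        reportToJson(report, file.path(outDir, "validation_report.json"))
        writeLines(renderReport(report),
                   file.path(outDir, "validation_report.md"))
    }
    list(report = report, fits = fits, responses = batches,
         sections = sections, seed = seed, config = config)
}
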