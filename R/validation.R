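#' @include calibration.R
NULL

#' Precision and accuracy of replicate measurements
#'
#' Accuracy (% bias) is the difference between the mean measured and the
#' nominal concentration, as a percentage of nominal; precision (% CV) is
#' the sample (n-1) standard deviation of the measured concentrations as a
#' percentage of their mean.
#'
#' @param measured measured concentrations (ng/mL), length >= 2.
#' @param nominal nominal concentration (ng/mL), > 0.
#' @param scope "within_batch" or "batch_to_batch" (bookkeeping label; for
#'   batch-to-batch statistics pool all replicates of all batches at the
#'   level before calling).
#' @return list with `level`, `n`, `mean_measured`, `cv_pct`, `bias_pct`,
#'   `scope`.
#' @examples
#' precisionAccuracy(c(8, 12), 10)  # bias 0%, CV ~28.28%
#' @export
precisionAccuracy <- function(measured, nominal,
                              scope = c("within_batch", "batch_to_batch")) {
    scope <- match.arg(scope)
    if (!is.finite(nominal) || nominal <= 0)
        stop("nominal concentration must be > 0")
    if (length(measured) < 2L) stop("need at least 2 replicates")
    m <- mean(measured)
    list(level = nominal, n = length(measured), mean_measured = m,
         cv_pct = 100 * stats::sd(measured) / m,
         bias_pct = 100 * (m - nominal) / nominal, scope = scope)
}

#' Guideline acceptance of a precision/accuracy result
#'
#' Limits are 20% CV and +/-20% bias at the LLOQ, 15% and +/-15% elsewhere.
#' The default boundary convention is strict (a CV of exactly 15.0% at a QC
#' level fails), matching the guidelines' "<" phrasing; set
#' `inclusive = TRUE` for inclusive-pass boundaries.
#'
#' @param pa result of [precisionAccuracy()].
#' @param isLloq is this the LLOQ level?
#' @param cvLimitPct,biasLimitPct non-LLOQ limits (percent).
#' @param lloqCvLimitPct,lloqBiasLimitPct LLOQ limits (percent).
#' @param inclusive pass at exactly the limit value?
#' @return TRUE/FALSE.
#' @export
checkAcceptance <- function(pa, isLloq = FALSE, cvLimitPct = 15,
                            biasLimitPct = 15, lloqCvLimitPct = 20,
                            lloqBiasLimitPct = 20, inclusive = FALSE) {
    cvLim <- if (isLloq) lloqCvLimitPct else cvLimitPct
    biasLim <- if (isLloq) lloqBiasLimitPct else biasLimitPct
    cmp <- if (inclusive) `<=` else `<`
    isTRUE(cmp(pa$cv_pct, cvLim)) && isTRUE(cmp(abs(pa$bias_pct), biasLim))
}

.ratioCheck <- function(analyteSignals, isSignals, lloqAnalyteSignal,
                        meanIsSignal, analyteLimitPct, isLimitPct) {
    if (!is.finite(lloqAnalyteSignal) || lloqAnalyteSignal <= 0)
        stop("lloqAnalyteSignal must be > 0")
    if (!is.finite(meanIsSignal) || meanIsSignal <= 0)
        stop("meanIsSignal must be > 0")
    aR <- 100 * analyteSignals / lloqAnalyteSignal
    iR <- 100 * isSignals / meanIsSignal
    list(analyte_ratios_pct = aR, is_ratios_pct = iR,
         max_analyte_ratio_pct = max(aR), max_is_ratio_pct = max(iR),
         pass = max(aR) < analyteLimitPct && max(iR) < isLimitPct)
}

#' Specificity check on blank-matrix sources
#'
#' In blanks from independent matrix sources, the signal in the analyte
#' window must stay below `analyteLimitPct` of the analyte signal at the
#' LLOQ, and the signal in the IS window below `isLimitPct` of the mean IS
#' signal (guideline limits 20% and 5%). Signals are MobA areas in the
#' compound windows.
#'
#' @param blankAnalyteSignals,blankIsSignals per-source blank signals.
#' @param lloqAnalyteSignal lowest analyte signal at the LLOQ level.
#' @param meanIsSignal mean IS signal of calibrators and QCs.
#' @param analyteLimitPct,isLimitPct limits (percent).
#' @param minSources warn below this number of blank sources (default 6).
#' @return list with per-source ratios, max ratios and `pass`.
#' @export
specificityCheck <- function(blankAnalyteSignals, blankIsSignals,
                             lloqAnalyteSignal, meanIsSignal,
                             analyteLimitPct = 20, isLimitPct = 5,
                             minSources = 6L) {
    if (length(blankAnalyteSignals) < minSources)
        warning("fewer than ", minSources, " blank sources; ",
                "verdict computed on ", length(blankAnalyteSignals))
    out <- .ratioCheck(blankAnalyteSignals, blankIsSignals,
                       lloqAnalyteSignal, meanIsSignal, analyteLimitPct,
                       isLimitPct)
    out$n_sources <- length(blankAnalyteSignals)
    out
}

#' Carry-over check on blanks measured after the highest standards
#'
#' Same thresholds as [specificityCheck()] (20% of the lowest LLOQ analyte
#' signal, 5% of the mean IS signal), applied to blanks measured on the
#' positions of the two highest calibration standards.
#'
#' @inheritParams specificityCheck
#' @param blankAnalyteSignals,blankIsSignals signals of the post-high-
#'   standard blanks.
#' @return list with ratios and `pass`.
#' @export
carryoverCheck <- function(blankAnalyteSignals, blankIsSignals,
                           lloqAnalyteSignal, meanIsSignal,
                           analyteLimitPct = 20, isLimitPct = 5) {
    .ratioCheck(blankAnalyteSignals, blankIsSignals, lloqAnalyteSignal,
                meanIsSignal, analyteLimitPct, isLimitPct)
}

#' Extraction recovery from the paired diluted/post-extraction QC design
#'
#' Compares QC DIL samples (spiked before extraction, then diluted to the
#' final composition of the reference series) against QC REC samples
#' (post-extraction spiked, representing 100% recovery), prepared at
#' matched final dilution so the two series are directly comparable:
#' `recovery% = 100 * mean(DIL) / mean(REC)`. With `signal = "response"`
#' (IS-normalized) a co-extracted IS cancels the extraction loss and the
#' estimator returns ~100%, demonstrating the normalization; the
#' `signal = "raw"` diagnostic mode on raw analyte areas estimates the
#' extraction fraction itself.
#'
#' @param qcDil,qcRec numeric vectors (responses or raw areas) at one
#'   level.
#' @param level nominal concentration label (ng/mL).
#' @param signal "response" or "raw" (bookkeeping label).
#' @return list with `level`, `recovery_pct`, `cv_pct`, `n`, `signal`. The
#'   CV is over the per-replicate DIL/mean(REC) ratios.
#' @export
estimateRecovery <- function(qcDil, qcRec, level = NA_real_,
                             signal = c("response", "raw")) {
    signal <- match.arg(signal)
    if (!length(qcDil) || !length(qcRec))
        stop("both QC DIL and QC REC series must be non-empty")
    mRec <- mean(qcRec)
    if (!is.finite(mRec) || mRec == 0) stop("zero QC REC mean")
    ratios <- 100 * qcDil / mRec
    list(level = level, recovery_pct = mean(ratios),
         cv_pct = 100 * stats::sd(ratios) / mean(ratios),
         n = length(qcDil), signal = signal)
}

#' IS-normalized matrix factor from the paired matrix/eluent QC design
#'
#' Compares post-extraction-spiked matrix samples (QC MAT, prepared from a
#' double plasma volume so the spike dilution is compensated) against
#' neat-eluent samples (QC EL): per compound,
#' `MF% = 100 * mean(area in MAT) / mean(area in EL)`, and the normalized
#' matrix factor is `100 * MF_analyte / MF_IS`. The CV is over the
#' per-replicate MAT responses normalized by the mean EL response.
#'
#' @param matAnalyte,matIs raw signal vectors of the QC MAT series.
#' @param elAnalyte,elIs raw signal vectors of the QC EL series.
#' @param level nominal concentration label (ng/mL).
#' @return list with `level`, `mf_analyte_pct`, `mf_is_pct`,
#'   `mf_normalized_pct`, `cv_pct`, `n`.
#' @export
matrixFactor <- function(matAnalyte, matIs, elAnalyte, elIs,
                         level = NA_real_) {
    if (!length(matAnalyte) || !length(elAnalyte))
        stop("both QC MAT and QC EL series must be non-empty")
    if (mean(elAnalyte) == 0 || mean(elIs) == 0)
        stop("zero QC EL mean")
    mfA <- 100 * mean(matAnalyte) / mean(elAnalyte)
    mfI <- 100 * mean(matIs) / mean(elIs)
    respMat <- matAnalyte / matIs
    respEl <- elAnalyte / elIs
    norm <- 100 * respMat / mean(respEl)
    list(level = level, mf_analyte_pct = mfA, mf_is_pct = mfI,
         mf_normalized_pct = 100 * mfA / mfI,
         cv_pct = 100 * stats::sd(norm) / mean(norm),
         n = length(matAnalyte))
}

.sectionNames <- c("sensitivity", "calibration", "precision_accuracy",
                   "specificity", "carryover", "recovery", "matrix_effect",
                   "freeze_thaw")

#' Assemble a validation report
#'
#' Collects per-criterion results into a [ValidationReport-class] mirroring
#' a guideline validation summary. Criteria not supplied are marked "not
#' assessed" and make the overall verdict "incomplete"; any failing
#' assessed criterion makes it "failed"; otherwise "validated".
#'
#' @param sections named list; each element a list carrying at least a
#'   logical `pass`. Recognized names: sensitivity, calibration,
#'   precision_accuracy, specificity, carryover, recovery, matrix_effect,
#'   freeze_thaw.
#' @return a [ValidationReport-class].
#' @export
buildValidationReport <- function(sections) {
    out <- stats::setNames(vector("list", length(.sectionNames)),
                           .sectionNames)
    for (nm in .sectionNames) {
        if (!is.null(sections[[nm]])) {
            s <- sections[[nm]]
            s$assessed <- TRUE
            out[[nm]] <- s
        } else {
            out[[nm]] <- list(assessed = FALSE, pass = NA)
        }
    }
    assessed <- vapply(out, function(s) isTRUE(s$assessed), logical(1))
    passes <- vapply(out, function(s) isTRUE(s$pass), logical(1))
    verdict <- if (any(assessed & !passes)) "failed"
        else if (all(assessed)) "validated" else "incomplete"
    new("ValidationReport", sections = out, verdict = verdict)
}

#' Serialize / parse a validation report as JSON
#'
#' @param report a [ValidationReport-class].
#' @param path optional file; when `NULL` the JSON string is returned.
#' @return `reportToJson`: JSON string (invisibly, if written to file);
#'   `reportFromJson`: a [ValidationReport-class].
#' @export
reportToJson <- function(report, path = NULL) {
    x <- list(verdict = report@verdict, sections = report@sections)
    js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null")
    if (!is.null(path)) {
        writeLines(js, path)
        invisible(js)
    } else js
}

#' @rdname reportToJson
#' @param json JSON string or file path.
#' @export
reportFromJson <- function(json) {
    x <- jsonlite::fromJSON(json, simplifyVector = TRUE,
                            simplifyDataFrame = FALSE,
                            simplifyMatrix = FALSE)
    new("ValidationReport", sections = x$sections, verdict = x$verdict)
}

#' Render a validation report as Markdown
#'
#' @param report a [ValidationReport-class].
#' @return character vector of Markdown lines.
#' @export
renderReport <- function(report) {
    lines <- c("# Validation summary", "",
               paste0("Overall verdict: **", report@verdict, "**"), "",
               "| Criterion | Status | Detail |", "|---|---|---|")
    for (nm in names(report@sections)) {
        s <- report@sections[[nm]]
        status <- if (!isTRUE(s$assessed)) "not assessed"
            else if (isTRUE(s$pass)) "pass" else "fail"
        detail <- if (!is.null(s$summary)) s$summary else ""
        lines <- c(lines, sprintf("| %s | %s | %s |", nm, status, detail))
    }
    lines
}
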