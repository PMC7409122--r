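#' @include mobilogram.R
NULL

#' Internal-standard-normalized response
#'
#' `y = analyteArea / isArea`. A zero IS area flags the response invalid
#' (`valid = FALSE`, `y = NA`) rather than erroring, so a failed spot does
#' not abort a batch. Negative areas are an error.
#'
#' @param analyteArea,isArea non-negative signal values (areas or
#'   intensities); vectorized.
#' @return data.frame with columns `y` and `valid`.
#' @export
computeResponse <- function(analyteArea, isArea) {
    if (any(analyteArea < 0) || any(isArea < 0))
        stop("areas must be >= 0")
    valid <- isArea > 0
    y <- ifelse(valid, analyteArea / isArea, NA_real_)
    data.frame(y = y, valid = valid)
}

#' Extract per-sample responses from a set of acquisitions
#'
#' Applies the chosen data-extraction method (MobA mobility-peak areas or
#' MassI combined-spectrum intensities) with the analyte and IS windows to
#' every acquisition and joins the results onto the batch layout.
#'
#' @param acqs named list of [Acquisition-class] objects (names = sample
#'   ids).
#' @param layout the matching layout data.frame.
#' @param method "MobA" or "MassI".
#' @param analyteWin,isWin [ExtractionWindow-class] objects.
#' @return data.frame: layout columns plus `analyte_signal`, `is_signal`,
#'   `y`, `valid`.
#' @export
extractResponses <- function(acqs, layout, method = c("MobA", "MassI"),
                             analyteWin = analyteWindow(),
                             isWin = isWindow()) {
    method <- match.arg(method)
    f <- if (method == "MobA") mobA else massI
    sig <- t(vapply(layout$sample_id, function(id) {
        acq <- acqs[[id]]
        if (is.null(acq)) stop("no acquisition for sample ", id)
        c(f(acq, analyteWin), f(acq, isWin))
    }, numeric(2)))
    resp <- computeResponse(sig[, 1], sig[, 2])
    out <- cbind(layout,
                 data.frame(analyte_signal = sig[, 1], is_signal = sig[, 2],
                            y = resp$y, valid = resp$valid))
    rownames(out) <- NULL
    out
}

#' Fit a 1/x^2-weighted linear calibration model
#'
#' Weighted least squares of response on nominal concentration with weights
#' `1/x^2` (nominal x, never fitted x), minimizing
#' `sum(w_i * (y_i - a - b x_i)^2)`. Zero-concentration points are excluded
#' (their weight is undefined; the curve is fitted on the non-zero levels
#' only). The coefficient of determination is computed on the weighted
#' model. By default all individual replicate responses enter the fit; set
#' `useLevelMeans = TRUE` to fit level means instead.
#'
#' @param x nominal concentrations (ng/mL).
#' @param y responses.
#' @param level optional level labels, carried into diagnostics.
#' @param sampleId optional sample ids.
#' @param extractionMethod label stored on the fit ("MobA" or "MassI").
#' @param useLevelMeans fit per-level mean responses instead of replicates.
#' @return a [CalibrationFit-class] (not yet evaluated for acceptance; see
#'   [evaluateCalibration()]).
#' @export
fitWeightedLinear <- function(x, y, level = NULL, sampleId = NULL,
                              extractionMethod = "MobA",
                              useLevelMeans = FALSE) {
    keep <- is.finite(x) & is.finite(y) & x > 0
    x <- x[keep]; y <- y[keep]
    level <- if (is.null(level)) as.character(x[seq_along(x)]) else
        as.character(level[keep])
    sampleId <- if (is.null(sampleId)) paste0("pt", seq_along(x)) else
        as.character(sampleId[keep])
    if (useLevelMeans) {
        ag <- stats::aggregate(data.frame(x = x, y = y),
                               by = list(level = level), mean)
        x <- ag$x; y <- ag$y; level <- ag$level
        sampleId <- level
    }
    if (length(unique(x)) < 2L)
        stop("singular fit: need at least two distinct positive x")
    w <- 1 / x^2
    fit <- stats::lm(y ~ x, weights = w)
    cf <- stats::coef(fit)
    ## weighted R^2: residual and total weighted sums of squares, the total
    ## about the weighted mean of y (same convention as summary.lm)
    res <- y - (cf[1] + cf[2] * x)
    yw <- sum(w * y) / sum(w)
    sst <- sum(w * (y - yw)^2)
    r2 <- if (sst > 0) max(0, min(1, 1 - sum(w * res^2) / sst)) else 1
    new("CalibrationFit",
        intercept = unname(cf[1]), slope = unname(cf[2]),
        r2 = r2, extractionMethod = extractionMethod,
        points = data.frame(sampleId = sampleId, level = level, x = x,
                            y = y, weight = w, stringsAsFactors = FALSE))
}

#' Back-calculate concentration from a response
#'
#' Inverse prediction `x = (y - a) / b`. Negative results are reported
#' as-is (needed for honest blank and carry-over statistics); callers may
#' flag them. Errors when the slope is not positive.
#'
#' @param fit a [CalibrationFit-class].
#' @param y response(s).
#' @return concentration(s) in ng/mL.
#' @export
backCalculate <- function(fit, y) {
    if (!is.finite(fit@slope) || fit@slope <= 0)
        stop("back-calculation requires slope > 0")
    (y - fit@intercept) / fit@slope
}

#' Evaluate calibration-curve acceptance
#'
#' Back-calculates every fitted standard, computes per-standard and
#' per-level bias against nominal, and applies the guideline curve rules:
#' a standard (and a level, on its mean) is accepted when its absolute bias
#' is within `biasLimitPct` (`lloqBiasLimitPct` at the lowest level); the
#' curve is accepted when at least `minFraction` of the individual
#' standards and at least `minLevels` levels are accepted. The weighted r2
#' is reported against `r2Threshold` but does not gate the verdict
#' (guidelines impose bias rules, not r2).
#'
#' @param fit a [CalibrationFit-class] from [fitWeightedLinear()].
#' @param biasLimitPct bias limit for non-LLOQ levels (percent).
#' @param lloqBiasLimitPct bias limit at the lowest level (percent).
#' @param minFraction minimum accepted fraction of standards.
#' @param minLevels minimum number of accepted levels.
#' @param r2Threshold reported r2 floor.
#' @return the fit with `backCalc`, `acceptedLevels`, `standardsFraction`,
#'   `r2Ok` and `verdict` filled in.
#' @export
evaluateCalibration <- function(fit, biasLimitPct = 15,
                                lloqBiasLimitPct = 20, minFraction = 0.75,
                                minLevels = 6L, r2Threshold = 0.988) {
    pts <- fit@points
    est <- backCalculate(fit, pts$y)
    lloqX <- min(pts$x)
    limit <- ifelse(pts$x == lloqX, lloqBiasLimitPct, biasLimitPct)
    bias <- 100 * (est - pts$x) / pts$x
    ok <- abs(bias) <= limit
    bc <- data.frame(sampleId = pts$sampleId, level = pts$level,
                     nominal = pts$x, estimated = est, bias_pct = bias,
                     accepted = ok, stringsAsFactors = FALSE)
    lv <- stats::aggregate(
        data.frame(nominal = pts$x, estimated = est),
        by = list(level = pts$level), mean)
    lv$bias_pct <- 100 * (lv$estimated - lv$nominal) / lv$nominal
    lv$limit <- ifelse(lv$nominal == lloqX, lloqBiasLimitPct, biasLimitPct)
    lv$accepted <- abs(lv$bias_pct) <= lv$limit
    fit@backCalc <- bc
    fit@acceptedLevels <- sum(lv$accepted)
    fit@standardsFraction <- mean(ok)
    fit@r2Ok <- fit@r2 >= r2Threshold
    fit@verdict <- fit@standardsFraction >= minFraction &&
        fit@acceptedLevels >= minLevels
    attr(fit@backCalc, "levels") <- lv
    fit
}
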