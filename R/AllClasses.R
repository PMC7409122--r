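#' @import methods
NULL

#' Instrument model for synthetic ion-mobility MS/MS acquisitions
#'
#' Describes the acquisition geometry of the simulated MALDI-Q-IMS-TOF
#' instrument: the TOF resolution mode ("V" = sensitivity, single reflection;
#' "W" = resolution, double reflection), the mass-peak width it implies at the
#' analyte fragment mass, the ion-mobility peak width, the drift-time axis,
#' and how many laser-shot frames make up one spot analysis.
#'
#' @slot resolutionMode character, "V" or "W".
#' @slot mzFwhm numeric, full width at half maximum of mass peaks (m/z units)
#'   at m/z ~185 in the selected mode.
#' @slot dtFwhm numeric, FWHM of mobility peaks in ms.
#' @slot dtMin,dtMax numeric, drift-time axis limits in ms.
#' @slot dtBins integer, number of drift-time bins.
#' @slot scansPerSpot integer, frames acquired over one spot.
#' @slot acquisitionSeconds numeric, nominal duration of one spot analysis.
#'
#' @exportClass InstrumentModel
setClass("InstrumentModel",
    representation(
        resolutionMode     = "character",
        mzFwhm             = "numeric",
        dtFwhm             = "numeric",
        dtMin              = "numeric",
        dtMax              = "numeric",
        dtBins             = "integer",
        scansPerSpot       = "integer",
        acquisitionSeconds = "numeric"
    )
)

setValidity("InstrumentModel", function(object) {
    msg <- character()
    if (!object@resolutionMode %in% c("V", "W"))
        msg <- c(msg, "resolutionMode must be 'V' or 'W'")
    if (object@mzFwhm <= 0) msg <- c(msg, "mzFwhm must be > 0")
    if (object@dtFwhm <= 0) msg <- c(msg, "dtFwhm must be > 0")
    if (object@dtMax <= object@dtMin)
        msg <- c(msg, "drift-time axis must be strictly increasing")
    if (object@dtBins < 2L) msg <- c(msg, "dtBins must be >= 2")
    if (object@scansPerSpot < 1L) msg <- c(msg, "scansPerSpot must be >= 1")
    if (length(msg)) msg else TRUE
})

#' Signal model for the synthetic acquisition generator
#'
#' Parameterizes the signal content of a simulated spot: the analyte and
#' internal-standard (IS) fragment positions in (m/z, drift time), the
#' near-isobaric endogenous interferent offset from the analyte fragment,
#' the linear concentration-response, extraction recovery and matrix-effect
#' multipliers, and the noise structure (multiplicative replicate noise on
#' the analyte channel, shared spot-amplitude heterogeneity that IS
#' normalization cancels, and additive baseline noise).
#'
#' @slot analyteMz,isMz numeric, fragment m/z centers.
#' @slot interferentDeltaMz numeric, interferent offset from the analyte
#'   fragment in m/z.
#' @slot interferentDeltaDt numeric, interferent offset in drift time (ms).
#' @slot analyteDt,isDt numeric, expected drift times (ms).
#' @slot responseSlope numeric, signal volume (a.u.) per ng/mL.
#' @slot isVirtualConc numeric, fixed virtual plasma concentration of the IS
#'   spike in ng/mL.
#' @slot extractionRecovery numeric in (0, 1], fraction of analyte (and IS,
#'   co-extraction) surviving the liquid-liquid extraction.
#' @slot matrixFactorAnalyte,matrixFactorIs numeric, ionization
#'   suppression/enhancement multipliers from co-extracted matrix.
#' @slot replicateCv numeric >= 0, lognormal CV of the IS-normalized
#'   response between technical replicates.
#' @slot spotHeterogeneity numeric >= 0, lognormal CV of the shared
#'   per-spot amplitude factor.
#' @slot baselineNoise numeric >= 0, sd of the additive baseline term.
#' @slot interferentIntensity numeric >= 0, interferent signal volume in
#'   a.u.; concentration-independent.
#' @slot carryoverFraction numeric >= 0, residual fraction of a preceding
#'   high standard's analyte signal seen on a reused target position.
#' @slot recoveryMode character, "co_extraction" (default; loss applies to
#'   analyte and IS identically) or "analyte_only" (diagnostic mode in which
#'   only the analyte channel is attenuated).
#'
#' @exportClass SignalModel
setClass("SignalModel",
    representation(
        analyteMz           = "numeric",
        isMz                = "numeric",
        interferentDeltaMz  = "numeric",
        interferentDeltaDt  = "numeric",
        analyteDt           = "numeric",
        isDt                = "numeric",
        responseSlope       = "numeric",
        isVirtualConc       = "numeric",
        extractionRecovery  = "numeric",
        matrixFactorAnalyte = "numeric",
        matrixFactorIs      = "numeric",
        replicateCv         = "numeric",
        spotHeterogeneity   = "numeric",
        baselineNoise       = "numeric",
        interferentIntensity = "numeric",
        carryoverFraction   = "numeric",
        recoveryMode        = "character"
    )
)

setValidity("SignalModel", function(object) {
    msg <- character()
    if (object@extractionRecovery <= 0 || object@extractionRecovery > 1)
        msg <- c(msg, "extractionRecovery must be in (0, 1]")
    if (object@replicateCv < 0) msg <- c(msg, "replicateCv must be >= 0")
    if (object@spotHeterogeneity < 0)
        msg <- c(msg, "spotHeterogeneity must be >= 0")
    if (object@matrixFactorAnalyte <= 0 || object@matrixFactorIs <= 0)
        msg <- c(msg, "matrix factors must be > 0")
    if (object@baselineNoise < 0) msg <- c(msg, "baselineNoise must be >= 0")
    if (object@interferentIntensity < 0)
        msg <- c(msg, "interferentIntensity must be >= 0")
    if (object@carryoverFraction < 0)
        msg <- c(msg, "carryoverFraction must be >= 0")
    if (!object@recoveryMode %in% c("co_extraction", "analyte_only"))
        msg <- c(msg, "recoveryMode must be 'co_extraction' or 'analyte_only'")
    if (length(msg)) msg else TRUE
})

#' Scan-level ion-mobility MS/MS acquisition
#'
#' The unit of one spot analysis: an ordered table of centroided peaks, one
#' row per (scan, drift bin, m/z centroid). `scans` has columns `scan`
#' (frame index), `driftBin` (1-based drift-time bin), `mz`, `intensity`.
#' `metadata` carries the originating sample record, an instrument snapshot,
#' and the seed used for generation (for simulated data).
#'
#' @slot scans data.frame of centroided peaks.
#' @slot metadata list.
#'
#' @exportClass Acquisition
setClass("Acquisition",
    representation(scans = "data.frame", metadata = "list")
)

setValidity("Acquisition", function(object) {
    sc <- object@scans
    need <- c("scan", "driftBin", "mz", "intensity")
    if (!all(need %in% names(sc)))
        return(paste("scans must have columns", paste(need, collapse = ", ")))
    if (nrow(sc)) {
        if (any(sc$intensity < 0)) return("intensities must be >= 0")
        nb <- object@metadata$instrument$dtBins
        if (!is.null(nb) && (any(sc$driftBin < 1L) || any(sc$driftBin > nb)))
            return("driftBin outside the drift-time axis")
        if (is.unsorted(sc$scan)) return("scans must be ordered by scan index")
    }
    TRUE
})

#' m/z extraction window
#'
#' A rectangular extraction target: an m/z range plus the expected drift time
#' of the compound and a tolerance inside which the mobility apex must fall.
#'
#' @slot mzLow,mzHigh numeric m/z bounds.
#' @slot expectedDt numeric, expected mobility apex (ms).
#' @slot dtTolerance numeric, allowed apex deviation (ms).
#'
#' @exportClass ExtractionWindow
setClass("ExtractionWindow",
    representation(mzLow = "numeric", mzHigh = "numeric",
                   expectedDt = "numeric", dtTolerance = "numeric")
)

setValidity("ExtractionWindow", function(object) {
    msg <- character()
    if (object@mzLow >= object@mzHigh) msg <- c(msg, "mzLow must be < mzHigh")
    if (object@dtTolerance <= 0) msg <- c(msg, "dtTolerance must be > 0")
    if (length(msg)) msg else TRUE
})

#' Extracted ion mobilogram
#'
#' Intensity versus drift time for one m/z extraction window.
#'
#' @slot dtGrid numeric, strictly increasing drift times (ms).
#' @slot intensity numeric, same length, all >= 0.
#'
#' @exportClass Mobilogram
setClass("Mobilogram",
    representation(dtGrid = "numeric", intensity = "numeric")
)

setValidity("Mobilogram", function(object) {
    if (length(object@dtGrid) != length(object@intensity))
        return("dtGrid and intensity must have equal length")
    if (length(object@dtGrid) > 1 && any(diff(object@dtGrid) <= 0))
        return("dtGrid must be strictly increasing")
    if (any(object@intensity < 0)) return("intensities must be >= 0")
    TRUE
})

#' Integrated mobility peak
#'
#' @slot apexDt numeric, apex drift time (ms).
#' @slot leftDt,rightDt numeric, integration bounds (ms).
#' @slot area numeric, trapezoidal area of the raw signal (a.u. * ms).
#' @slot apexIntensity numeric, raw intensity at the apex bin.
#'
#' @exportClass MobilityPeak
setClass("MobilityPeak",
    representation(apexDt = "numeric", leftDt = "numeric",
                   rightDt = "numeric", area = "numeric",
                   apexIntensity = "numeric")
)

setValidity("MobilityPeak", function(object) {
    if (object@leftDt > object@apexDt || object@apexDt > object@rightDt)
        return("must satisfy leftDt <= apexDt <= rightDt")
    if (object@area < 0) return("area must be >= 0")
    TRUE
})

#' 1/x^2-weighted linear calibration fit
#'
#' Holds the weighted-least-squares parameters of the response-versus-nominal
#' concentration line, its weighted coefficient of determination, the fitted
#' points with their weights, per-point and per-level back-calculation
#' diagnostics (filled by [evaluateCalibration()]), and the curve-acceptance
#' verdict.
#'
#' @slot intercept,slope numeric model parameters (response units;
#'   response per ng/mL).
#' @slot r2 numeric, weighted coefficient of determination.
#' @slot extractionMethod character, "MobA" or "MassI".
#' @slot points data.frame with columns `x`, `y`, `weight` and optionally
#'   `level`, `sampleId`.
#' @slot backCalc data.frame of back-calculated concentrations and biases.
#' @slot acceptedLevels integer, number of accepted calibration levels.
#' @slot standardsFraction numeric, fraction of individual standards within
#'   the bias limits.
#' @slot r2Ok logical, r2 at or above the configured threshold.
#' @slot verdict logical curve-acceptance verdict.
#'
#' @exportClass CalibrationFit
setClass("CalibrationFit",
    representation(
        intercept         = "numeric",
        slope             = "numeric",
        r2                = "numeric",
        extractionMethod  = "character",
        points            = "data.frame",
        backCalc          = "data.frame",
        acceptedLevels    = "integer",
        standardsFraction = "numeric",
        r2Ok              = "logical",
        verdict           = "logical"
    ),
    prototype(backCalc = data.frame(), acceptedLevels = NA_integer_,
              standardsFraction = NA_real_, r2Ok = NA, verdict = NA)
)

setValidity("CalibrationFit", function(object) {
    if (!is.na(object@r2) && (object@r2 < 0 || object@r2 > 1))
        return("r2 must be in [0, 1]")
    if (isTRUE(object@verdict) && object@slope <= 0)
        return("accepted fits must have slope > 0")
    TRUE
})

#' Bioanalytical validation report
#'
#' A structured report mirroring a guideline validation summary table:
#' one section per criterion (sensitivity, calibration, QC precision and
#' accuracy, specificity, carry-over, recovery, matrix effect, freeze/thaw),
#' each holding its statistics and a pass/fail flag, plus an overall verdict
#' ("validated", "failed" or "incomplete").
#'
#' @slot sections named list of per-criterion results.
#' @slot verdict character overall verdict.
#'
#' @exportClass ValidationReport
setClass("ValidationReport",
    representation(sections = "list", verdict = "character")
)

setValidity("ValidationReport", function(object) {
    if (!object@verdict %in% c("validated", "failed", "incomplete"))
        return("verdict must be 'validated', 'failed' or 'incomplete'")
    TRUE
})
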