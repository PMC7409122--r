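#' @include AllClasses.R
NULL

#' @describeIn Acquisition-class the centroid table (scan, driftBin, mz,
#'   intensity).
#' @param object an object.
#' @export
setGeneric("acqScans", function(object) standardGeneric("acqScans"))

#' @describeIn Acquisition-class acquisition metadata list.
#' @export
setGeneric("acqMetadata", function(object) standardGeneric("acqMetadata"))

#' @describeIn Mobilogram-class drift-time grid (ms).
#' @export
setGeneric("dtGrid", function(object) standardGeneric("dtGrid"))

#' @describeIn Mobilogram-class intensity vector (a.u.).
#' @export
setGeneric("intensityValues", function(object)
    standardGeneric("intensityValues"))

#' @describeIn MobilityPeak-class integrated peak area (a.u. * ms).
#' @export
setGeneric("peakArea", function(object) standardGeneric("peakArea"))

#' @describeIn MobilityPeak-class apex drift time (ms).
#' @export
setGeneric("apexDt", function(object) standardGeneric("apexDt"))

#' @describeIn CalibrationFit-class model slope (response per ng/mL).
#' @export
setGeneric("calSlope", function(object) standardGeneric("calSlope"))

#' @describeIn CalibrationFit-class model intercept (response units).
#' @export
setGeneric("calIntercept", function(object) standardGeneric("calIntercept"))

#' @describeIn CalibrationFit-class weighted coefficient of determination.
#' @export
setGeneric("calR2", function(object) standardGeneric("calR2"))

#' @describeIn ValidationReport-class overall verdict.
#' @export
setGeneric("reportVerdict", function(object) standardGeneric("reportVerdict"))

#' @describeIn ValidationReport-class named list of per-criterion sections.
#' @export
setGeneric("reportSections", function(object)
    standardGeneric("reportSections"))

setMethod("acqScans", "Acquisition", function(object) object@scans)
setMethod("acqMetadata", "Acquisition", function(object) object@metadata)
setMethod("dtGrid", "Mobilogram", function(object) object@dtGrid)
setMethod("intensityValues", "Mobilogram", function(object) object@intensity)
setMethod("peakArea", "MobilityPeak", function(object) object@area)
setMethod("apexDt", "MobilityPeak", function(object) object@apexDt)
setMethod("calSlope", "CalibrationFit", function(object) object@slope)
setMethod("calIntercept", "CalibrationFit", function(object) object@intercept)
setMethod("calR2", "CalibrationFit", function(object) object@r2)
setMethod("reportVerdict", "ValidationReport", function(object) object@verdict)
setMethod("reportSections", "ValidationReport", function(object)
    object@sections)

setMethod("show", "InstrumentModel", function(object) {
    cat("InstrumentModel:", object@resolutionMode, "mode\n")
    cat("  m/z FWHM @185:", object@mzFwhm, " DT FWHM:", object@dtFwhm, "ms\n")
    cat(sprintf("  DT axis: %.2f-%.2f ms, %d bins; %d scans/spot (%gs)\n",
        object@dtMin, object@dtMax, object@dtBins, object@scansPerSpot,
        object@acquisitionSeconds))
    invisible(NULL)
})

setMethod("show", "SignalModel", function(object) {
    cat("SignalModel\n")
    cat(sprintf("  analyte m/z %.4f @ %.2f ms; IS m/z %.4f @ %.2f ms\n",
        object@analyteMz, object@analyteDt, object@isMz, object@isDt))
    cat(sprintf("  interferent: +%.3f m/z, +%.3f ms (intensity %g a.u.)\n",
        object@interferentDeltaMz, object@interferentDeltaDt,
        object@interferentIntensity))
    cat(sprintf(
        "  slope %g a.u./(ng/mL); recovery %.3f (%s); MF %0.2f/%0.2f\n",
        object@responseSlope, object@extractionRecovery, object@recoveryMode,
        object@matrixFactorAnalyte, object@matrixFactorIs))
    cat(sprintf("  replicate CV %.3f, spot CV %.3f, baseline sd %g\n",
        object@replicateCv, object@spotHeterogeneity, object@baselineNoise))
    invisible(NULL)
})

setMethod("show", "Acquisition", function(object) {
    sc <- object@scans
    id <- object@metadata$sample$sample_id
    cat("Acquisition", if (!is.null(id)) paste0("[", id, "]") else "",
        ":", length(unique(sc$scan)), "scans,", nrow(sc), "centroids\n")
    invisible(NULL)
})

setMethod("show", "Mobilogram", function(object) {
    cat(sprintf("Mobilogram: %d bins, DT %.2f-%.2f ms, total %.4g a.u.\n",
        length(object@dtGrid), min(object@dtGrid), max(object@dtGrid),
        sum(object@intensity)))
    invisible(NULL)
})

setMethod("show", "MobilityPeak", function(object) {
    cat(sprintf(
        "MobilityPeak: apex %.3f ms [%.3f, %.3f], area %.4g a.u.*ms\n",
        object@apexDt, object@leftDt, object@rightDt, object@area))
    invisible(NULL)
})

setMethod("show", "CalibrationFit", function(object) {
    cat(sprintf("CalibrationFit (%s): y = %.5g + %.5g x, weighted r2 = %.4f\n",
        object@extractionMethod, object@intercept, object@slope, object@r2))
    if (!is.na(object@verdict))
        cat(sprintf("  %d levels accepted, %.0f%% standards in limits -> %s\n",
            object@acceptedLevels, 100 * object@standardsFraction,
            if (isTRUE(object@verdict)) "accepted" else "rejected"))
    invisible(NULL)
})

setMethod("show", "ValidationReport", function(object) {
    cat("ValidationReport:", object@verdict, "\n")
    for (nm in names(object@sections)) {
        s <- object@sections[[nm]]
        status <- if (is.null(s$assessed) || isTRUE(s$assessed)) {
            if (isTRUE(s$pass)) "pass" else "FAIL"
        } else "not assessed"
        cat(sprintf("  %-22s %s\n", nm, status))
    }
    invisible(NULL)
})
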