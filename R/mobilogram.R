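#' @include synthetic.R
NULL

#' Construct an m/z extraction window
#'
#' @param mzLow,mzHigh m/z bounds.
#' @param expectedDt expected mobility apex (ms).
#' @param dtTolerance allowed apex deviation (ms).
#' @return an [ExtractionWindow-class] object.
#' @export
extractionWindow <- function(mzLow, mzHigh, expectedDt, dtTolerance = 0.2) {
    new("ExtractionWindow", mzLow = mzLow, mzHigh = mzHigh,
        expectedDt = expectedDt, dtTolerance = dtTolerance)
}

#' Default extraction windows of the assay
#'
#' The analyte (osimertinib fragment) window m/z 185.094-185.121 and the
#' internal-standard window m/z 189.125-189.140, both expecting the mobility
#' apex at 1.85 ms.
#'
#' @param expectedDt expected apex drift time (ms).
#' @param dtTolerance apex tolerance (ms).
#' @return an [ExtractionWindow-class].
#' @export
analyteWindow <- function(expectedDt = 1.85, dtTolerance = 0.2) {
    extractionWindow(185.094, 185.121, expectedDt, dtTolerance)
}

#' @rdname analyteWindow
#' @export
isWindow <- function(expectedDt = 1.85, dtTolerance = 0.2) {
    extractionWindow(189.125, 189.140, expectedDt, dtTolerance)
}

.dtCenters <- function(acq) {
    inst <- acq@metadata$instrument
    if (is.null(inst))
        stop("acquisition metadata lacks the instrument axis description")
    binW <- (inst$dtMax - inst$dtMin) / inst$dtBins
    inst$dtMin + (seq_len(inst$dtBins) - 0.5) * binW
}

#' Extract an ion mobilogram
#'
#' Sums, for each drift-time bin, the intensities of all centroids whose m/z
#' falls inside the window (inclusive bounds), across all scans. Bins with
#' no centroids are zero; an empty acquisition yields an all-zero
#' mobilogram.
#'
#' @param acq an [Acquisition-class].
#' @param window an [ExtractionWindow-class].
#' @return a [Mobilogram-class] on the acquisition's full drift-time grid.
#' @export
extractMobilogram <- function(acq, window) {
    grid <- .dtCenters(acq)
    intensity <- numeric(length(grid))
    sc <- acq@scans
    sel <- sc$mz >= window@mzLow & sc$mz <= window@mzHigh
    if (any(sel)) {
        agg <- tapply(sc$intensity[sel], sc$driftBin[sel], sum)
        intensity[as.integer(names(agg))] <- as.numeric(agg)
    }
    new("Mobilogram", dtGrid = grid, intensity = intensity)
}

#' TIC-combined mass spectrum
#'
#' Bins all centroids of all scans onto a fixed m/z grid and sums them,
#' emulating a spectrum combined over the full TIC.
#'
#' @param acq an [Acquisition-class].
#' @param gridStep m/z grid spacing (default 0.005, at least five bins
#'   across the narrowest extraction window of the assay).
#' @return data.frame with columns `mz` (bin centers) and `intensity`,
#'   sorted by m/z; only non-empty bins are returned.
#' @export
combineSpectrum <- function(acq, gridStep = 0.005) {
    sc <- acq@scans
    if (!nrow(sc))
        return(data.frame(mz = numeric(), intensity = numeric()))
    idx <- floor(sc$mz / gridStep)
    agg <- tapply(sc$intensity, idx, sum)
    data.frame(mz = (as.numeric(names(agg)) + 0.5) * gridStep,
               intensity = as.numeric(agg), row.names = NULL)
}

#' Maximum combined-spectrum intensity in a window (MassI)
#'
#' The assay's intensity-based data-extraction method: the maximum of the
#' TIC-combined spectrum within the extraction window.
#'
#' @inheritParams combineSpectrum
#' @param window an [ExtractionWindow-class].
#' @return intensity (a.u.); 0 when the window is empty.
#' @export
massI <- function(acq, window, gridStep = 0.005) {
    prof <- combineSpectrum(acq, gridStep)
    sel <- prof$mz >= window@mzLow & prof$mz <= window@mzHigh
    if (!any(sel)) 0 else max(prof$intensity[sel])
}

#' Detect and integrate the mobility peak of a mobilogram
#'
#' A deterministic reimplementation of apex-tracking peak integration:
#' the mobilogram is smoothed with a local quadratic (Savitzky-Golay)
#' filter; the apex is the highest smoothed local maximum within
#' `dtTolerance` of the expected drift time (ties broken towards the
#' expected drift time, then towards earlier DT); integration bounds extend
#' from the apex until the smoothed signal falls to the baseline estimate
#' plus `k` times the noise estimate, or to a valley; the area is the
#' trapezoidal integral of the raw signal between the bounds. The baseline
#' is the median — and the noise the median absolute deviation — of the
#' mobilogram outside `expectedDt +/- 3 * dtTolerance`. If no qualifying
#' maximum exists, a zero-area peak at the expected drift time is returned.
#'
#' @param mob a [Mobilogram-class].
#' @param window an [ExtractionWindow-class] providing `expectedDt` and
#'   `dtTolerance`.
#' @param smoothWidth odd Savitzky-Golay window length in bins (default 5).
#' @param k noise multiplier for the boundary/baseline threshold.
#' @return a [MobilityPeak-class].
#' @export
detectMobilityPeak <- function(mob, window, smoothWidth = 5L, k = 2) {
    x <- mob@dtGrid
    y <- mob@intensity
    n <- length(x)
    if (!n) stop("empty mobilogram")
    if (window@dtTolerance > (max(x) - min(x)))
        stop("dtTolerance exceeds the drift-time grid span")
    s <- if (n >= smoothWidth && smoothWidth >= 3L) {
        as.numeric(signal::sgolayfilt(y, p = 2, n = as.integer(smoothWidth)))
    } else y
    outside <- abs(x - window@expectedDt) > 3 * window@dtTolerance
    base <- if (any(outside)) stats::median(y[outside]) else 0
    noise <- if (any(outside)) stats::mad(y[outside]) else 0
    thr <- base + k * noise
    zeroPeak <- new("MobilityPeak", apexDt = window@expectedDt,
                    leftDt = window@expectedDt, rightDt = window@expectedDt,
                    area = 0, apexIntensity = 0)
    isMax <- rep(FALSE, n)
    if (n >= 3L)
        isMax[2:(n - 1L)] <- s[2:(n - 1L)] > s[1:(n - 2L)] &
            s[2:(n - 1L)] >= s[3:n]
    cand <- which(isMax & abs(x - window@expectedDt) <= window@dtTolerance &
                      s > thr)
    if (!length(cand)) return(zeroPeak)
    ## highest apex; ties -> nearest to expected DT, then earliest DT
    ord <- order(-s[cand], abs(x[cand] - window@expectedDt), x[cand])
    apex <- cand[ord[1L]]
    left <- apex
    while (left > 1L) {
        if (s[left - 1L] <= thr) { left <- left - 1L; break }
        if (s[left - 1L] > s[left]) break
        left <- left - 1L
    }
    right <- apex
    while (right < n) {
        if (s[right + 1L] <= thr) { right <- right + 1L; break }
        if (s[right + 1L] > s[right]) break
        right <- right + 1L
    }
    idx <- left:right
    area <- if (length(idx) > 1L)
        sum(diff(x[idx]) * (utils::head(y[idx], -1L) +
                            utils::tail(y[idx], -1L)) / 2) else 0
    new("MobilityPeak", apexDt = x[apex], leftDt = x[left],
        rightDt = x[right], area = max(area, 0), apexIntensity = y[apex])
}

#' Mobility-peak area for an extraction window (MobA)
#'
#' The assay's validated data-extraction method: extract the ion mobilogram
#' of the window, detect the mobility peak nearest the expected drift time,
#' and integrate its raw area.
#'
#' @inheritParams massI
#' @param ... passed to [detectMobilityPeak()].
#' @return peak area in a.u. * ms.
#' @export
mobA <- function(acq, window, ...) {
    peakArea(detectMobilityPeak(extractMobilogram(acq, window), window, ...))
}

#' 2D m/z versus drift-time intensity map
#'
#' Sums centroid intensities on an (m/z bin x drift bin) grid restricted to
#' the requested ranges. The row sums equal the TIC-combined spectrum and
#' the column sums the total mobilogram restricted to the same ranges.
#'
#' @param acq an [Acquisition-class].
#' @param mzRange numeric c(low, high).
#' @param dtRange numeric c(low, high) in ms.
#' @param gridStep m/z grid spacing.
#' @return numeric matrix (m/z bins x drift bins) with `mz` and `dt`
#'   attributes giving the bin centers.
#' @export
dtMzMap <- function(acq, mzRange, dtRange, gridStep = 0.005) {
    if (mzRange[1] >= mzRange[2] || dtRange[1] >= dtRange[2])
        stop("inverted range")
    grid <- .dtCenters(acq)
    dtSel <- which(grid >= dtRange[1] & grid <= dtRange[2])
    mzIdx0 <- floor(mzRange[1] / gridStep)
    mzIdx1 <- floor(mzRange[2] / gridStep)
    mzCenters <- (seq(mzIdx0, mzIdx1) + 0.5) * gridStep
    m <- matrix(0, nrow = length(mzCenters), ncol = length(dtSel))
    sc <- acq@scans
    sel <- sc$mz >= mzRange[1] & sc$mz <= mzRange[2] &
        sc$driftBin %in% dtSel
    if (any(sel)) {
        agg <- data.table(
            ri = floor(sc$mz[sel] / gridStep) - mzIdx0 + 1L,
            ci = match(sc$driftBin[sel], dtSel),
            intensity = sc$intensity[sel]
        )[, list(intensity = sum(intensity)), by = list(ri, ci)]
        m[cbind(agg$ri, agg$ci)] <- agg$intensity
    }
    attr(m, "mz") <- mzCenters
    attr(m, "dt") <- grid[dtSel]
    m
}
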