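#' @include study_design.R
#' @import data.table
NULL

#' Construct an instrument model
#'
#' Defaults reproduce the assay's acquisition geometry: a 0-4 ms drift-time
#' axis over 200 bins, 60 frames over the 60-s spot analysis, mobility peaks
#' of 0.25 ms FWHM, and mode-dependent mass resolution. The V (sensitivity)
#' mode has a mass-peak FWHM of 0.060 at m/z 185 so the interferent 0.03 m/z
#' away merges with the analyte peak; the W (resolution) mode, 0.018, resolves
#' it. Resolving powers are a modeling choice: the modes' qualitative
#' behaviour (merged versus resolved) is the constraint.
#'
#' @param resolutionMode "V" or "W".
#' @param mzFwhm mass-peak FWHM at m/z 185; default 0.060 (V) / 0.018 (W).
#' @param dtFwhm mobility-peak FWHM in ms.
#' @param dtRange drift-time axis limits c(min, max) in ms.
#' @param dtBins number of drift-time bins.
#' @param scansPerSpot frames per spot.
#' @param acquisitionSeconds spot analysis duration.
#' @return an [InstrumentModel-class] object.
#' @export
instrumentModel <- function(resolutionMode = c("W", "V"), mzFwhm = NULL,
                            dtFwhm = 0.25, dtRange = c(0, 4), dtBins = 200L,
                            scansPerSpot = 60L, acquisitionSeconds = 60) {
    resolutionMode <- match.arg(resolutionMode)
    if (is.null(mzFwhm))
        mzFwhm <- if (resolutionMode == "V") 0.060 else 0.018
    new("InstrumentModel", resolutionMode = resolutionMode, mzFwhm = mzFwhm,
        dtFwhm = dtFwhm, dtMin = dtRange[1], dtMax = dtRange[2],
        dtBins = as.integer(dtBins), scansPerSpot = as.integer(scansPerSpot),
        acquisitionSeconds = acquisitionSeconds)
}

#' Construct a signal model
#'
#' Defaults encode the assay's signal structure: the analyte fragment at the
#' midpoint of its extraction window (m/z 185.1075) and the isotope-labeled
#' IS fragment at 189.1325, both at 1.85 ms drift time; an endogenous
#' interfering fragment offset by +0.03 m/z and +0.04 ms with
#' concentration-independent intensity; extraction recovery 0.536; unit
#' matrix factors; 5% replicate CV. The IS is spiked at a fixed virtual
#' plasma concentration of 200 ng/mL (400 ng/mL solution, 50 uL into 100 uL
#' plasma).
#'
#' @param analyteMz,isMz fragment m/z centers.
#' @param interferentDeltaMz,interferentDeltaDt interferent offsets.
#' @param analyteDt,isDt expected drift times (ms).
#' @param responseSlope signal volume (a.u.) per ng/mL of virtual plasma
#'   concentration (before recovery/matrix multipliers).
#' @param isVirtualConc IS virtual plasma concentration (ng/mL).
#' @param extractionRecovery fraction in (0, 1].
#' @param matrixFactorAnalyte,matrixFactorIs matrix multipliers.
#' @param replicateCv lognormal CV of the analyte channel between replicates
#'   (the CV the IS-normalized response inherits).
#' @param spotHeterogeneity lognormal CV of the shared per-spot amplitude.
#' @param baselineNoise sd of additive baseline noise (a.u.).
#' @param interferentIntensity interferent signal volume (a.u.).
#' @param carryoverFraction residual signal fraction on reused positions.
#' @param recoveryMode "co_extraction" or "analyte_only" (diagnostic).
#' @return a [SignalModel-class] object.
#' @export
signalModel <- function(analyteMz = 185.1075, isMz = 189.1325,
                        interferentDeltaMz = 0.03, interferentDeltaDt = 0.04,
                        analyteDt = 1.85, isDt = 1.85, responseSlope = 200,
                        isVirtualConc = 200, extractionRecovery = 0.536,
                        matrixFactorAnalyte = 1, matrixFactorIs = 1,
                        replicateCv = 0.05, spotHeterogeneity = 0.2,
                        baselineNoise = 0.2, interferentIntensity = 200,
                        carryoverFraction = 2e-4,
                        recoveryMode = c("co_extraction", "analyte_only")) {
    new("SignalModel", analyteMz = analyteMz, isMz = isMz,
        interferentDeltaMz = interferentDeltaMz,
        interferentDeltaDt = interferentDeltaDt, analyteDt = analyteDt,
        isDt = isDt, responseSlope = responseSlope,
        isVirtualConc = isVirtualConc,
        extractionRecovery = extractionRecovery,
        matrixFactorAnalyte = matrixFactorAnalyte,
        matrixFactorIs = matrixFactorIs, replicateCv = replicateCv,
        spotHeterogeneity = spotHeterogeneity, baselineNoise = baselineNoise,
        interferentIntensity = interferentIntensity,
        carryoverFraction = carryoverFraction,
        recoveryMode = match.arg(recoveryMode))
}

## lognormal multiplier with unit mean and the requested CV
.lnFactor <- function(cv, n = 1L) {
    if (cv <= 0) return(rep(1, n))
    sdlog <- sqrt(log(1 + cv^2))
    stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

.withSeed <- function(seed, expr) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        old <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old, envir = globalenv()))
    }
    set.seed(as.integer(seed %% 2147483647))
    force(expr)
}

## stable 31-bit hash of a sample id, for per-spot seed derivation
.idHash <- function(id) {
    h <- 0
    for (v in utf8ToInt(id)) h <- (h * 31 + v) %% 2147483629
    h
}

#' Per-scan total-ion-current profile of a spot
#'
#' Emulates the effect of matrix deposition order on crystallization: spots
#' where the extract is deposited on pre-spotted matrix crystallize
#' homogeneously and give a high, stable TIC (low per-scan CV); depositing
#' the matrix after the extract leaves sparse crystals and a low, bursty TIC.
#'
#' @param prespotted logical deposition-order flag.
#' @param instrument an [InstrumentModel-class].
#' @param seed integer seed.
#' @return non-negative numeric vector of per-scan TIC multipliers, length
#'   `scansPerSpot`.
#' @export
simulateTicProfile <- function(prespotted, instrument = instrumentModel(),
                               seed = 1L) {
    n <- instrument@scansPerSpot
    .withSeed(seed, {
        if (isTRUE(prespotted)) {
            stats::rlnorm(n, meanlog = log(1000), sdlog = 0.1)
        } else {
            hit <- stats::rbinom(n, 1L, 0.25)
            tic <- hit * stats::rlnorm(n, meanlog = log(400), sdlog = 1)
            if (all(tic == 0)) tic[1L] <- 400  # degenerate all-miss draw
            tic
        }
    })
}

## deterministic expected signal volumes (a.u.) for a sample record,
## before the random spot/replicate factors
.expectedVolumes <- function(sample, signal) {
    role <- sample$role
    conc <- sample$nominal_conc_ng_per_mL
    if (role == "CLINICAL") {
        conc <- sample$true_conc_ng_per_mL
        if (is.null(conc) || is.na(conc))
            stop("clinical sample needs a true_conc_ng_per_mL for simulation")
    } else if (is.na(conc)) {
        stop("nominal concentration unknown for role ", role)
    }
    recA <- signal@extractionRecovery
    recIS <- if (signal@recoveryMode == "co_extraction") recA else 1
    mfA <- signal@matrixFactorAnalyte
    mfIS <- signal@matrixFactorIs
    hasIS <- TRUE; hasInt <- TRUE
    aConc <- conc
    if (role == "BV") { aConc <- 0; hasIS <- FALSE }
    else if (role == "CAL0") aConc <- 0
    else if (role == "QC_REC") { recA <- 1; recIS <- 1 }
    else if (role == "QC_MAT") { recA <- 1; recIS <- 1 }
    else if (role == "QC_EL") { recA <- 1; recIS <- 1; mfA <- 1; mfIS <- 1
                                hasInt <- FALSE }
    else if (role == "CARRYOVER_BLANK") {
        src <- if (identical(sample$level, "post_CAL1000")) 1000 else 500
        aConc <- signal@carryoverFraction * src
        hasIS <- FALSE; hasInt <- FALSE
        recA <- signal@extractionRecovery
    }
    list(
        analyte = signal@responseSlope * aConc * recA * mfA,
        is = if (hasIS) signal@responseSlope * signal@isVirtualConc *
                 recIS * mfIS else 0,
        interferent = if (hasInt) signal@interferentIntensity else 0
    )
}

#' Expected noiseless signal volumes for a sample record
#'
#' The deterministic part of the generator: analyte, IS and interferent
#' signal volumes (a.u.) before the random per-spot amplitude and replicate
#' factors. Useful as ground truth when measuring extraction bias.
#'
#' @param sample one layout record (one-row data.frame or list).
#' @param signal a [SignalModel-class].
#' @return list with elements `analyte`, `is`, `interferent`.
#' @export
expectedVolumes <- function(sample, signal = signalModel()) {
    if (is.data.frame(sample)) sample <- as.list(sample[1L, ])
    .expectedVolumes(sample, signal)
}

## render one 2D Gaussian peak onto (frame, drift bin, m/z grid) centroids
.renderPeak <- function(volume, mzCenter, dtCenter, instrument, fracs,
                        mzGridStep = 0.005) {
    if (volume <= 0) return(NULL)
    sigMz <- instrument@mzFwhm / (2 * sqrt(2 * log(2)))
    sigDt <- instrument@dtFwhm / (2 * sqrt(2 * log(2)))
    binW <- (instrument@dtMax - instrument@dtMin) / instrument@dtBins
    bins <- seq_len(instrument@dtBins)
    lo <- instrument@dtMin + (bins - 1L) * binW
    keep <- lo + binW > dtCenter - 5 * sigDt & lo < dtCenter + 5 * sigDt
    bins <- bins[keep]; lo <- lo[keep]
    if (!length(bins)) return(NULL)
    wdt <- stats::pnorm(lo + binW, dtCenter, sigDt) -
        stats::pnorm(lo, dtCenter, sigDt)
    g0 <- floor((mzCenter - 4 * sigMz) / mzGridStep)
    g1 <- ceiling((mzCenter + 4 * sigMz) / mzGridStep)
    mzLo <- seq(g0, g1) * mzGridStep
    wmz <- stats::pnorm(mzLo + mzGridStep, mzCenter, sigMz) -
        stats::pnorm(mzLo, mzCenter, sigMz)
    mzPts <- mzLo + mzGridStep / 2
    nf <- length(fracs); nd <- length(bins); nm <- length(mzPts)
    iv <- volume * as.numeric(fracs %o% wdt %o% wmz)
    dt <- data.table(
        scan = rep(seq_len(nf), times = nd * nm),
        driftBin = rep(rep(bins, each = nf), times = nm),
        mz = rep(mzPts, each = nf * nd),
        intensity = iv)
    dt[iv > 1e-12]
}

#' Simulate one spot acquisition
#'
#' Generates the scan-level acquisition of a single sample: the analyte and
#' IS fragments and the near-isobaric interferent are rendered as 2D
#' Gaussians on the (m/z, drift time) grid, split over frames proportionally
#' to the spot's TIC profile, with additive baseline noise. The expected
#' analyte volume is `responseSlope * conc * recovery * matrixFactor *
#' spotFactor * replicateFactor`; the spot factor is shared with the IS (so
#' IS normalization cancels it), the replicate factor is analyte-only.
#' Role semantics: BV renders neither analyte nor IS; CAL0 renders the IS
#' only; QC REC/MAT/EL are post-extraction-spiked (no recovery loss); QC EL
#' carries neither matrix effect nor the endogenous interferent; carry-over
#' blanks render a residual fraction of the source standard's analyte
#' signal.
#'
#' @param sample one layout record (one-row data.frame or list).
#' @param instrument an [InstrumentModel-class].
#' @param signal a [SignalModel-class].
#' @param seed integer seed (required; the generator keeps no hidden state).
#' @return an [Acquisition-class] object.
#' @export
simulateSpot <- function(sample, instrument = instrumentModel(),
                         signal = signalModel(), seed) {
    if (missing(seed)) stop("seed must be supplied")
    if (is.data.frame(sample)) sample <- as.list(sample[1L, ])
    vols <- .expectedVolumes(sample, signal)
    prespotted <- if (is.null(sample$prespotted_matrix)) TRUE
                  else isTRUE(sample$prespotted_matrix)
    acq <- .withSeed(seed, {
        tic <- simulateTicProfile(prespotted, instrument,
                                  seed = (seed + 104729) %% 2147483647)
        fracs <- tic / sum(tic)
        spotF <- .lnFactor(signal@spotHeterogeneity)
        repF <- .lnFactor(signal@replicateCv)
        parts <- list(
            .renderPeak(vols$analyte * spotF * repF, signal@analyteMz,
                        signal@analyteDt, instrument, fracs),
            .renderPeak(vols$is * spotF, signal@isMz, signal@isDt,
                        instrument, fracs),
            .renderPeak(vols$interferent * spotF,
                        signal@analyteMz + signal@interferentDeltaMz,
                        signal@analyteDt + signal@interferentDeltaDt,
                        instrument, fracs))
        parts <- parts[!vapply(parts, is.null, logical(1))]
        if (signal@baselineNoise > 0) {
            nb <- instrument@dtBins
            binW <- (instrument@dtMax - instrument@dtMin) / nb
            for (mzC in c(signal@analyteMz, signal@isMz)) {
                parts[[length(parts) + 1L]] <- data.table(
                    scan = 1L, driftBin = seq_len(nb),
                    mz = round(mzC / 0.005) * 0.005 + 0.0025,
                    intensity = abs(stats::rnorm(nb, 0,
                                                 signal@baselineNoise)))
            }
        }
        sc <- if (length(parts)) rbindlist(parts) else
            data.table(scan = integer(), driftBin = integer(),
                       mz = numeric(), intensity = numeric())
        if (nrow(sc)) {
            sc <- sc[, list(intensity = sum(intensity)),
                     by = list(scan, driftBin, mz)]
            setorder(sc, scan, driftBin, mz)
        }
        sc
    })
    new("Acquisition", scans = as.data.frame(acq),
        metadata = list(sample = sample,
                        instrument = list(
                            resolutionMode = instrument@resolutionMode,
                            mzFwhm = instrument@mzFwhm,
                            dtFwhm = instrument@dtFwhm,
                            dtMin = instrument@dtMin,
                            dtMax = instrument@dtMax,
                            dtBins = instrument@dtBins,
                            scansPerSpot = instrument@scansPerSpot),
                        seed = seed))
}

#' Simulate a whole batch
#'
#' One acquisition per layout record, with per-spot seeds derived
#' deterministically from `(seed, sample_id)` so the output is reproducible
#' bit-for-bit and independent of record order.
#'
#' @param layout a layout data.frame (see [buildBatchLayout()]).
#' @param instrument an [InstrumentModel-class].
#' @param signal a [SignalModel-class].
#' @param seed integer seed.
#' @return named list of [Acquisition-class] objects (names = sample ids).
#' @export
simulateBatch <- function(layout, instrument = instrumentModel(),
                          signal = signalModel(), seed = 1L) {
    if (!nrow(layout)) stop("layout must be non-empty")
    if (anyDuplicated(layout$sample_id))
        stop("duplicate sample_ids in layout")
    out <- vector("list", nrow(layout))
    names(out) <- layout$sample_id
    for (i in seq_len(nrow(layout))) {
        si <- (as.numeric(seed) * 7919 + .idHash(layout$sample_id[i])) %%
            2147483647
        out[[i]] <- simulateSpot(layout[i, ], instrument, signal,
                                 seed = si)
    }
    out
}
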