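#' @include crossval.R
NULL

#' Construct an acquisition from a centroid table
#'
#' Builds an [Acquisition-class] from a table of centroided peaks and an
#' instrument axis description, for data not produced by the generator
#' (file readers, hand-built fixtures).
#'
#' @param scans data.frame with columns `scan`, `driftBin`, `mz`,
#'   `intensity`.
#' @param instrument an [InstrumentModel-class] providing the drift-time
#'   axis.
#' @param sample optional sample-record list.
#' @param seed optional seed to record.
#' @return an [Acquisition-class].
#' @export
acquisition <- function(scans, instrument = instrumentModel(),
                        sample = NULL, seed = NA_integer_) {
    scans <- scans[order(scans$scan, scans$driftBin, scans$mz), ,
                   drop = FALSE]
    rownames(scans) <- NULL
    new("Acquisition", scans = scans,
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

#' Write / read acquisitions in the JSON-lines format
#'
#' One spot is serialized as `<id>.jsonl` — one scan per line, each line a
#' JSON object `{"scan": i, "drift_bin": k, "mz": [...], "intensity":
#' [...]}` — plus a sidecar `<id>.meta.json` with the acquisition metadata.
#' The round trip is lossless.
#'
#' @param acqs named list of [Acquisition-class] objects, or a single
#'   acquisition.
#' @param dir output directory (created if missing).
#' @return `writeAcquisitions` returns the written ids invisibly;
#'   `readAcquisitions` a named list of acquisitions.
#' @export
writeAcquisitions <- function(acqs, dir) {
    if (is(acqs, "Acquisition")) {
        id <- acqs@metadata$sample$sample_id
        acqs <- stats::setNames(list(acqs),
                                if (is.null(id)) "acq1" else id)
    }
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    for (id in names(acqs)) {
        acq <- acqs[[id]]
        sc <- acq@scans
        keys <- paste(sc$scan, sc$driftBin)
        idx <- split(seq_len(nrow(sc)), factor(keys, levels = unique(keys)))
        lines <- vapply(idx, function(rows) as.character(jsonlite::toJSON(
            list(scan = sc$scan[rows[1L]],
                 drift_bin = sc$driftBin[rows[1L]],
                 mz = sc$mz[rows], intensity = sc$intensity[rows]),
            auto_unbox = TRUE, digits = NA)), character(1))
        writeLines(lines, file.path(dir, paste0(id, ".jsonl")))
        jsonlite::write_json(acq@metadata,
                             file.path(dir, paste0(id, ".meta.json")),
                             auto_unbox = TRUE, digits = NA, null = "null")
    }
    invisible(names(acqs))
}

#' @rdname writeAcquisitions
#' @param ids optional subset of ids to read (default: all `.jsonl` in
#'   `dir`).
#' @export
readAcquisitions <- function(dir, ids = NULL) {
    if (is.null(ids)) {
        ids <- sub("\\.jsonl$", "",
                   list.files(dir, pattern = "\\.jsonl$"))
        if (!length(ids)) stop("no .jsonl acquisitions in ", dir)
    }
    out <- stats::setNames(vector("list", length(ids)), ids)
    for (id in ids) {
        lines <- readLines(file.path(dir, paste0(id, ".jsonl")))
        parts <- vector("list", length(lines))
        for (i in seq_along(lines)) {
            rec <- tryCatch(
                jsonlite::fromJSON(lines[i], simplifyVector = TRUE),
                error = function(e) stop("parse error in ", id,
                                         ".jsonl line ", i, ": ",
                                         conditionMessage(e)))
            parts[[i]] <- data.table(scan = rec$scan,
                                     driftBin = rec$drift_bin,
                                     mz = rec$mz,
                                     intensity = rec$intensity)
        }
        sc <- as.data.frame(rbindlist(parts))
        meta <- jsonlite::read_json(file.path(dir,
                                              paste0(id, ".meta.json")),
                                    simplifyVector = TRUE)
        sc <- sc[order(sc$scan, sc$driftBin, sc$mz), , drop = FALSE]
        rownames(sc) <- NULL
        out[[id]] <- new("Acquisition", scans = sc,
                         metadata = as.list(meta))
    }
    out
}

#' Read an acquisition from an mzML file with ion-mobility scans
#'
#' Maps mzML spectra carrying an ion-mobility drift-time attribute onto the
#' acquisition contract: each spectrum becomes one scan, its drift time
#' assigned to the nearest bin of the instrument's drift-time axis. Spectra
#' without a drift-time attribute are skipped with a message; if no
#' spectrum has one, this is a format error. Requires the `mzR` package.
#'
#' @param path mzML file.
#' @param instrument an [InstrumentModel-class] providing the drift-time
#'   axis; when `NULL`, an axis spanning the observed drift times over 200
#'   bins is constructed.
#' @param sampleId id stored in the metadata.
#' @return an [Acquisition-class].
#' @export
readAcquisitionsMzML <- function(path, instrument = NULL,
                                 sampleId = basename(path)) {
    if (!requireNamespace("mzR", quietly = TRUE))
        stop("mzML support requires the mzR package")
    ms <- mzR::openMSfile(path)
    on.exit(mzR::close(ms))
    hd <- mzR::header(ms)
    if (!"ionMobilityDriftTime" %in% names(hd) ||
        all(is.na(hd$ionMobilityDriftTime)))
        stop("no spectra carry an ion-mobility drift-time attribute ",
             "(ionMobilityDriftTime) in ", path)
    keep <- which(!is.na(hd$ionMobilityDriftTime))
    if (length(keep) < nrow(hd))
        message("skipping ", nrow(hd) - length(keep),
                " spectra without drift-time attribute")
    dts <- hd$ionMobilityDriftTime[keep]
    if (is.null(instrument)) {
        rng <- range(dts)
        pad <- max(diff(rng), 1e-3) * 0.05
        instrument <- instrumentModel(dtRange = c(max(0, rng[1] - pad),
                                                  rng[2] + pad),
                                      dtBins = 200L)
    }
    binW <- (instrument@dtMax - instrument@dtMin) / instrument@dtBins
    parts <- vector("list", length(keep))
    for (j in seq_along(keep)) {
        pk <- mzR::peaks(ms, keep[j])
        if (!nrow(pk)) next
        bin <- min(max(1L, ceiling((dts[j] - instrument@dtMin) / binW)),
                   instrument@dtBins)
        parts[[j]] <- data.frame(scan = j, driftBin = bin, mz = pk[, 1],
                                 intensity = pk[, 2])
    }
    sc <- do.call(rbind, parts)
    if (is.null(sc))
        sc <- data.frame(scan = integer(), driftBin = integer(),
                         mz = numeric(), intensity = numeric())
    acquisition(sc, instrument,
                sample = list(sample_id = sampleId, role = "CLINICAL"))
}
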