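#' @include AllGenerics.R
NULL

#' Sample roles used across a quantification campaign
#'
#' The closed set of roles a sample record may carry. Blanks (`BV`, `CAL0`,
#' `QC_EL` at level zero, `CARRYOVER_BLANK`) have nominal concentration 0;
#' clinical samples have unknown nominal concentration (`NA`).
#'
#' @export
SAMPLE_ROLES <- c("BV", "CAL0", "CAL", "QC_LLOQ", "QC_LOW", "QC_MID",
                  "QC_HIGH", "QC_DIL", "QC_REC", "QC_MAT", "QC_EL",
                  "CARRYOVER_BLANK", "CLINICAL")

#' Default calibration and quality-control levels (ng/mL, virtual in plasma)
#'
#' Eight non-zero calibration levels spanning 5-1000 ng/mL and the four QC
#' levels (LLOQ, low, mid, high) of the assay.
#'
#' @return named numeric vector of virtual plasma concentrations.
#' @export
calLevels <- function() {
    c(CAL5 = 5, CAL10 = 10, CAL20 = 20, CAL50 = 50, CAL100 = 100,
      CAL200 = 200, CAL500 = 500, CAL1000 = 1000)
}

#' @rdname calLevels
#' @export
qcLevels <- function() {
    c(LLOQ = 5, LQC = 15, MQC = 400, HQC = 800)
}

#' Sample-preparation spike plan
#'
#' Volume arithmetic of the liquid-liquid extraction protocol: plasma volume,
#' the reference (analyte) and internal-standard spike volumes, the
#' extraction-solvent volume, and any post-extraction dilution. The defaults
#' are the assay's values: 100 uL plasma + 50 uL reference solution + 50 uL
#' IS solution, extracted with 200 uL of tert-butyl methyl ether.
#'
#' @param plasmaVolume plasma volume in uL.
#' @param spikeVolume reference-solution spike volume in uL.
#' @param isVolume internal-standard spike volume in uL.
#' @param solventVolume extraction-solvent volume in uL.
#' @param postDilutionFactor dimensionless post-extraction dilution (>= 1).
#'
#' @return an object of class `spikePlan`.
#' @examples
#' virtualPlasmaConcentration(2000)           # -> 1000 ng/mL
#' virtualPlasmaConcentration(10)             # -> 5 ng/mL
#' @export
spikePlan <- function(plasmaVolume = 100, spikeVolume = 50, isVolume = 50,
                      solventVolume = 200, postDilutionFactor = 1) {
    vols <- c(plasmaVolume, spikeVolume, isVolume, solventVolume)
    if (any(!is.finite(vols)) || any(vols <= 0))
        stop("invalid spike plan: all volumes must be positive")
    if (!is.finite(postDilutionFactor) || postDilutionFactor < 1)
        stop("invalid spike plan: postDilutionFactor must be >= 1")
    structure(list(plasmaVolume = plasmaVolume, spikeVolume = spikeVolume,
                   isVolume = isVolume, solventVolume = solventVolume,
                   postDilutionFactor = postDilutionFactor),
              class = "spikePlan")
}

#' Virtual concentration in plasma after spiking
#'
#' Refers the spiked analyte mass to the plasma volume: spiking
#' `spikeVolume` uL of a solution at `solutionConc` ng/mL into
#' `plasmaVolume` uL of plasma gives a virtual plasma concentration of
#' `solutionConc * spikeVolume / plasmaVolume`. With the default 50 uL spike
#' into 100 uL plasma this is `solutionConc / 2`. The IS spike volume does
#' not enter the denominator: the convention refers concentrations to the
#' plasma volume, the only one consistent with the assay's level table.
#'
#' @param solutionConc concentration of the spiking solution (ng/mL); may be
#'   a vector.
#' @param plan a [spikePlan()].
#' @return virtual plasma concentration(s) in ng/mL.
#' @export
virtualPlasmaConcentration <- function(solutionConc, plan = spikePlan()) {
    if (!inherits(plan, "spikePlan")) plan <- do.call(spikePlan, plan)
    if (any(solutionConc < 0)) stop("solutionConc must be >= 0")
    solutionConc * plan$spikeVolume / plan$plasmaVolume
}

.record <- function(sampleId, role, level, nominal, batchId, repId,
                    ftCycles = 0L, prespotted = TRUE) {
    data.frame(sample_id = sampleId, role = role, level = level,
               nominal_conc_ng_per_mL = nominal, batch_id = batchId,
               replicate_id = repId, freeze_thaw_cycles = ftCycles,
               prespotted_matrix = prespotted, stringsAsFactors = FALSE)
}

.qcRole <- function(levelName) {
    switch(levelName, LLOQ = "QC_LLOQ", LQC = "QC_LOW", MQC = "QC_MID",
           HQC = "QC_HIGH", stop("unknown QC level name: ", levelName))
}

#' Build a deterministic batch layout
#'
#' Expands one of the campaign's batch designs into sample records:
#' \describe{
#'   \item{validation}{4 technical replicates of blind value (BV), CAL0 and
#'     each non-zero calibration level, plus 8 replicates of each QC level
#'     (LLOQ, LQC, MQC, HQC). With `freezeThaw = TRUE`, 4 additional
#'     replicates of LQC/MQC/HQC flagged with three freeze/thaw cycles.}
#'   \item{analytical}{the calibration part of the validation design plus
#'     clinical samples of unknown nominal concentration.}
#'   \item{recovery}{paired QC DIL (spiked before extraction, then diluted
#'     1:1) and QC REC (post-extraction spiked, 100% recovery reference)
#'     series, 4 replicates per level.}
#'   \item{matrix_effect}{paired QC MAT (post-extraction spike into a
#'     double-plasma-volume extract, compensating the spike dilution) and
#'     QC EL (neat-eluent spike) series, 4 replicates per level.}
#'   \item{carryover}{blank spots on the positions of the two highest
#'     calibration standards (post-CAL500 and post-CAL1000).}
#' }
#'
#' @param design one of "validation", "analytical", "recovery",
#'   "matrix_effect", "carryover".
#' @param levels named concentrations (ng/mL). Defaults: [calLevels()] for
#'   calibration designs, the LQC/MQC/HQC subset of [qcLevels()] for
#'   recovery/matrix designs.
#' @param batchId batch identifier.
#' @param freezeThaw add freeze/thaw QC replicates (validation design only).
#' @param clinicalIds character ids of clinical samples (analytical design).
#' @param nReplicates replicates per CAL/paired-series record (default 4).
#' @param nQcReplicates replicates per QC level in the validation design
#'   (default 8).
#' @param prespotted deposition order flag stored on every record.
#'
#' @return data.frame with the layout column contract: `sample_id`, `role`,
#'   `level`, `nominal_conc_ng_per_mL`, `batch_id`, `replicate_id`,
#'   `freeze_thaw_cycles`, `prespotted_matrix`.
#' @examples
#' nrow(buildBatchLayout("validation"))  # 72
#' @export
buildBatchLayout <- function(design = c("validation", "analytical",
                                        "recovery", "matrix_effect",
                                        "carryover"),
                             levels = NULL, batchId = "B1",
                             freezeThaw = FALSE, clinicalIds = character(),
                             nReplicates = 4L, nQcReplicates = 8L,
                             prespotted = TRUE) {
    design <- match.arg(design)
    recs <- list()
    if (design %in% c("validation", "analytical")) {
        if (is.null(levels)) levels <- calLevels()
        if (!length(levels)) stop("levels must be non-empty")
        for (r in seq_len(nReplicates)) {
            recs[[length(recs) + 1L]] <- .record(
                sprintf("%s_BV_%d", batchId, r), "BV", "BV", 0, batchId, r,
                prespotted = prespotted)
            recs[[length(recs) + 1L]] <- .record(
                sprintf("%s_CAL0_%d", batchId, r), "CAL0", "CAL0", 0,
                batchId, r, prespotted = prespotted)
        }
        for (i in seq_along(levels)) {
            nm <- names(levels)[i]
            if (is.null(nm) || !nzchar(nm)) nm <- paste0("CAL", levels[i])
            for (r in seq_len(nReplicates))
                recs[[length(recs) + 1L]] <- .record(
                    sprintf("%s_%s_%d", batchId, nm, r), "CAL", nm,
                    unname(levels[i]), batchId, r, prespotted = prespotted)
        }
        if (design == "validation") {
            qc <- qcLevels()
            for (i in seq_along(qc)) {
                nm <- names(qc)[i]
                for (r in seq_len(nQcReplicates))
                    recs[[length(recs) + 1L]] <- .record(
                        sprintf("%s_%s_%d", batchId, nm, r), .qcRole(nm), nm,
                        unname(qc[i]), batchId, r, prespotted = prespotted)
            }
            if (freezeThaw) {
                for (nm in c("LQC", "MQC", "HQC"))
                    for (r in seq_len(4L))
                        recs[[length(recs) + 1L]] <- .record(
                            sprintf("%s_FT_%s_%d", batchId, nm, r),
                            .qcRole(nm), nm, unname(qc[nm]), batchId, r,
                            ftCycles = 3L, prespotted = prespotted)
            }
        } else {
            for (id in clinicalIds)
                recs[[length(recs) + 1L]] <- .record(
                    sprintf("%s_CLIN_%s", batchId, id), "CLINICAL",
                    "CLINICAL", NA_real_, batchId, 1L,
                    prespotted = prespotted)
        }
    } else if (design %in% c("recovery", "matrix_effect")) {
        if (is.null(levels)) levels <- qcLevels()[c("LQC", "MQC", "HQC")]
        if (!length(levels)) stop("levels must be non-empty")
        roles <- if (design == "recovery") c("QC_DIL", "QC_REC")
                 else c("QC_MAT", "QC_EL")
        for (i in seq_along(levels)) {
            nm <- names(levels)[i]
            if (is.null(nm) || !nzchar(nm)) nm <- paste0("L", levels[i])
            for (role in roles)
                for (r in seq_len(nReplicates))
                    recs[[length(recs) + 1L]] <- .record(
                        sprintf("%s_%s_%s_%d", batchId, role, nm, r), role,
                        nm, unname(levels[i]), batchId, r,
                        prespotted = prespotted)
        }
    } else { # carryover
        for (pos in c("post_CAL500", "post_CAL1000"))
            recs[[length(recs) + 1L]] <- .record(
                sprintf("%s_CO_%s", batchId, pos), "CARRYOVER_BLANK", pos, 0,
                batchId, 1L, prespotted = prespotted)
    }
    out <- do.call(rbind, recs)
    rownames(out) <- NULL
    validateLayout(out)
    out
}

#' Validate a batch-layout table against the column contract
#'
#' Checks column names, role membership, and the nominal-concentration
#' invariants (exactly 0 for blanks, > 0 for non-zero CAL/QC roles, `NA`
#' only for clinical samples).
#'
#' @param layout a layout data.frame.
#' @return the layout, invisibly; errors on violation.
#' @export
validateLayout <- function(layout) {
    need <- c("sample_id", "role", "level", "nominal_conc_ng_per_mL",
              "batch_id", "replicate_id", "freeze_thaw_cycles",
              "prespotted_matrix")
    miss <- setdiff(need, names(layout))
    if (length(miss))
        stop("layout is missing columns: ", paste(miss, collapse = ", "))
    bad <- setdiff(unique(layout$role), SAMPLE_ROLES)
    if (length(bad)) stop("unknown roles: ", paste(bad, collapse = ", "))
    if (anyDuplicated(layout$sample_id))
        stop("duplicate sample_ids in layout")
    nom <- layout$nominal_conc_ng_per_mL
    blanks <- layout$role %in% c("BV", "CAL0", "CARRYOVER_BLANK")
    if (any(blanks & (is.na(nom) | nom != 0)))
        stop("blank roles must have nominal concentration exactly 0")
    spiked <- layout$role %in% c("CAL", "QC_LLOQ", "QC_LOW", "QC_MID",
                                 "QC_HIGH", "QC_DIL", "QC_REC", "QC_MAT",
                                 "QC_EL")
    if (any(spiked & (is.na(nom) | nom <= 0)))
        stop("non-zero CAL/QC roles must have nominal concentration > 0")
    if (any(layout$role == "CLINICAL" & !is.na(nom)))
        stop("clinical samples must have unknown (NA) nominal concentration")
    if (any(layout$freeze_thaw_cycles < 0))
        stop("freeze_thaw_cycles must be >= 0")
    invisible(layout)
}

#' Read/write batch layouts as CSV or JSON
#'
#' Lossless serialization of the layout column contract. The format is
#' chosen from the file extension (".csv" or ".json").
#'
#' @param layout a layout data.frame.
#' @param path file path ending in .csv or .json.
#' @return `readBatchLayout` returns the layout data.frame.
#' @export
writeBatchLayout <- function(layout, path) {
    validateLayout(layout)
    if (grepl("\\.json$", path, ignore.case = TRUE)) {
        jsonlite::write_json(layout, path, digits = NA, na = "null")
    } else {
        utils::write.csv(layout, path, row.names = FALSE)
    }
    invisible(path)
}

#' @rdname writeBatchLayout
#' @export
readBatchLayout <- function(path) {
    layout <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
        as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
    } else {
        utils::read.csv(path, stringsAsFactors = FALSE)
    }
    layout$nominal_conc_ng_per_mL <- as.numeric(layout$nominal_conc_ng_per_mL)
    layout$freeze_thaw_cycles <- as.integer(layout$freeze_thaw_cycles)
    layout$prespotted_matrix <- as.logical(layout$prespotted_matrix)
    validateLayout(layout)
    layout
}
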