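# Shared fixtures: reduced-scale instrument for fast simulation, noiseless
# signal models, and a hand-rolled mzML writer for the reader tests.

fastInstrument <- function(mode = "W", scansPerSpot = 4L, dtBins = 100L) {
    instrumentModel(mode, scansPerSpot = scansPerSpot, dtBins = dtBins)
}

noiselessSignal <- function(...) {
    signalModel(replicateCv = 0, spotHeterogeneity = 0, baselineNoise = 0,
                ...)
}

qcRecord <- function(level = "LLOQ", conc = 5, role = "QC_LLOQ",
                     id = "T_QC_1") {
    data.frame(sample_id = id, role = role, level = level,
               nominal_conc_ng_per_mL = conc, batch_id = "T",
               replicate_id = 1L, freeze_thaw_cycles = 0L,
               prespotted_matrix = TRUE, stringsAsFactors = FALSE)
}

# an acquisition built by hand from explicit centroids
manualAcquisition <- function(centroids, instrument = fastInstrument()) {
    acquisition(centroids, instrument,
                sample = list(sample_id = "manual", role = "CLINICAL"))
}

# minimal uncompressed mzML (64-bit, base64 payloads built in code);
# spectra are (mz vector, intensity vector, drift time ms or NA)
writeTestMzML <- function(path, spectra) {
    enc <- function(x) jsonlite::base64_enc(
        writeBin(as.numeric(x), raw(), size = 8, endian = "little"))
    one <- function(idx, sp) {
        cv <- if (!is.na(sp$dt)) sprintf(paste0(
            '<cvParam cvRef="MS" accession="MS:1002476" ',
            'name="ion mobility drift time" value="%g" unitCvRef="UO" ',
            'unitAccession="UO:0000028" unitName="millisecond"/>'), sp$dt)
            else ""
        sprintf(paste0(
            '<spectrum index="%d" id="scan=%d" defaultArrayLength="%d">',
            '<cvParam cvRef="MS" accession="MS:1000511" name="ms level" ',
            'value="2"/>',
            '<cvParam cvRef="MS" accession="MS:1000127" ',
            'name="centroid spectrum"/>',
            '<scanList count="1"><cvParam cvRef="MS" ',
            'accession="MS:1000795" name="no combination"/><scan>',
            '<cvParam cvRef="MS" accession="MS:1000016" ',
            'name="scan start time" value="%g" unitCvRef="UO" ',
            'unitAccession="UO:0000010" unitName="second"/>%s',
            '</scan></scanList>',
            '<binaryDataArrayList count="2">',
            '<binaryDataArray encodedLength="%d"><cvParam cvRef="MS" ',
            'accession="MS:1000523" name="64-bit float"/><cvParam ',
            'cvRef="MS" accession="MS:1000576" name="no compression"/>',
            '<cvParam cvRef="MS" accession="MS:1000514" name="m/z array" ',
            'unitCvRef="MS" unitAccession="MS:1000040" unitName="m/z"/>',
            '<binary>%s</binary></binaryDataArray>',
            '<binaryDataArray encodedLength="%d"><cvParam cvRef="MS" ',
            'accession="MS:1000523" name="64-bit float"/><cvParam ',
            'cvRef="MS" accession="MS:1000576" name="no compression"/>',
            '<cvParam cvRef="MS" accession="MS:1000515" ',
            'name="intensity array" unitCvRef="MS" ',
            'unitAccession="MS:1000131" unitName="number of detector ',
            'counts"/><binary>%s</binary></binaryDataArray>',
            '</binaryDataArrayList></spectrum>'),
            idx, idx + 1L, length(sp$mz), idx + 0.1, cv,
            nchar(enc(sp$mz)), enc(sp$mz),
            nchar(enc(sp$intensity)), enc(sp$intensity))
    }
    body <- paste0(vapply(seq_along(spectra),
                          function(i) one(i - 1L, spectra[[i]]),
                          character(1)), collapse = "")
    xml <- paste0(
        '<?xml version="1.0" encoding="utf-8"?>',
        '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1.0">',
        '<cvList count="1"><cv id="MS" fullName="PSI-MS" ',
        'URI="https://x"/></cvList>',
        '<fileDescription><fileContent><cvParam cvRef="MS" ',
        'accession="MS:1000580" name="MSn spectrum"/></fileContent>',
        '</fileDescription>',
        '<softwareList count="1"><software id="sw" version="1">',
        '<cvParam cvRef="MS" accession="MS:1000799" ',
        'name="custom unreleased software tool" value=""/></software>',
        '</softwareList>',
        '<instrumentConfigurationList count="1">',
        '<instrumentConfiguration id="ic"/>',
        '</instrumentConfigurationList>',
        '<dataProcessingList count="1"><dataProcessing id="dp">',
        '<processingMethod order="1" softwareRef="sw"><cvParam ',
        'cvRef="MS" accession="MS:1000544" name="Conversion to mzML"/>',
        '</processingMethod></dataProcessing></dataProcessingList>',
        sprintf('<run id="r1" defaultInstrumentConfigurationRef="ic">
<spectrumList count="%d" defaultDataProcessingRef="dp">',
                length(spectra)),
        body, '</spectrumList></run></mzML>')
    writeLines(xml, path)
    path
}
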