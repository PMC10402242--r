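## mzML input (via mzR) and a minimal mzML writer used by the simulator.
## FAIMS compensation voltage (cvParam MS:1001581) is recovered by a light
## text scan because spectrum-level CV is not surfaced by the reader's
## header table.

#' Read centroided spectra from an mzML file
#'
#' Maps MS levels, precursor isolation windows, precursor charge (recorded
#' as unknown when absent, never guessed) and, when present, the FAIMS
#' compensation voltage into [Spectrum-class] objects. Precursor linkage is
#' resolved through precursor scan numbers.
#'
#' @param path mzML file path.
#' @param centroidedOnly If `TRUE` (default), spectra declared profile-mode
#'   are an error (this engine performs no peak picking; centroid upstream).
#' @return List of [Spectrum-class] objects.
#' @export
readMzML <- function(path, centroidedOnly = TRUE) {
  if (!requireNamespace("mzR", quietly = TRUE))
    stop("readMzML requires the mzR package; alternatively convert to the ",
         "peak-list text format (see readPeaklist)", call. = FALSE)
  fh <- mzR::openMSfile(path)
  on.exit(mzR::close(fh))
  hd <- mzR::header(fh)
  if (centroidedOnly && any(!is.na(hd$centroided) & !hd$centroided))
    stop("profile-mode spectra found; centroid the data first or pass ",
         "centroidedOnly = FALSE", call. = FALSE)
  cv <- .scanFaimsCV(path)
  idByAcq <- stats::setNames(hd$spectrumId, hd$acquisitionNum)
  out <- vector("list", nrow(hd))
  for (i in seq_len(nrow(hd))) {
    pk <- mzR::peaks(fh, i)
    lvl <- hd$msLevel[i]
    precAcq <- hd$precursorScanNum[i]
    precId <- if (lvl >= 2 && !is.na(precAcq) && precAcq > 0)
      idByAcq[[as.character(precAcq)]] else NA_character_
    isoC <- hd$isolationWindowTargetMZ[i]
    isoW <- NA_real_
    if (!is.na(hd$isolationWindowLowerOffset[i]))
      isoW <- hd$isolationWindowLowerOffset[i] + hd$isolationWindowUpperOffset[i]
    z <- hd$precursorCharge[i]
    if (!is.na(z) && z == 0) z <- NA_integer_
    myid <- hd$spectrumId[i]
    out[[i]] <- Spectrum(
      id = myid, msLevel = lvl, mz = pk[, 1], intensity = pk[, 2],
      precursorId = precId,
      isoCenter = if (lvl >= 2) isoC else NA_real_, isoWidth = isoW,
      precursorCharge = if (lvl >= 2) as.integer(z) else NA_integer_,
      activation = if (lvl >= 2) "HCD" else NA_character_,
      faimsCV = cv[myid] %||% NA_real_)
  }
  out
}

## map native spectrum id -> FAIMS CV by scanning the XML text
.scanFaimsCV <- function(path) {
  txt <- readLines(path, warn = FALSE)
  out <- numeric(0)
  cur <- NA_character_
  for (line in txt) {
    m <- regmatches(line, regexec("<spectrum[^>]*\\sid=\"([^\"]+)\"", line))[[1]]
    if (length(m)) cur <- m[2]
    m <- regmatches(line, regexec(
      "MS:1001581[^>]*value=\"([-0-9.eE+]+)\"", line))[[1]]
    if (length(m) && !is.na(cur)) out[cur] <- as.numeric(m[2])
  }
  out
}

.b64doubles <- function(x) {
  jsonlite::base64_enc(writeBin(as.numeric(x), raw(), size = 8,
                                endian = "little"))
}

#' Write spectra to a minimal mzML file
#'
#' Emits a small, standard-conformant mzML document (64-bit float arrays, no
#' compression, centroid spectra) carrying MS levels, precursor isolation
#' windows, charges, HCD activation and FAIMS compensation voltages. Spectrum
#' ids are rewritten to `scan=N` native ids in input order.
#'
#' @param spectra List of [Spectrum-class] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeMzML <- function(spectra, path) {
  if (is(spectra, "Spectrum")) spectra <- list(spectra)
  ids <- vapply(spectra, spectrumId, "")
  scan <- stats::setNames(seq_along(spectra), ids)
  sp <- character(0)
  for (i in seq_along(spectra)) {
    s <- spectra[[i]]
    n <- length(s@mz)
    mzb <- .b64doubles(s@mz)
    inb <- .b64doubles(s@intensity)
    prec <- ""
    if (!is.na(s@precursorId)) {
      half <- if (is.na(s@isoWidth)) 1 else s@isoWidth / 2
      zline <- if (!is.na(s@precursorCharge)) sprintf(
        '<cvParam cvRef="MS" accession="MS:1000041" name="charge state" value="%d"/>',
        s@precursorCharge) else ""
      prec <- sprintf(paste0(
        '<precursorList count="1"><precursor spectrumRef="scan=%d">',
        '<isolationWindow>',
        '<cvParam cvRef="MS" accession="MS:1000827" name="isolation window target m/z" value="%.6f" unitCvRef="MS" unitAccession="MS:1000040" unitName="m/z"/>',
        '<cvParam cvRef="MS" accession="MS:1000828" name="isolation window lower offset" value="%.6f" unitCvRef="MS" unitAccession="MS:1000040" unitName="m/z"/>',
        '<cvParam cvRef="MS" accession="MS:1000829" name="isolation window upper offset" value="%.6f" unitCvRef="MS" unitAccession="MS:1000040" unitName="m/z"/>',
        '</isolationWindow>',
        '<selectedIonList count="1"><selectedIon>',
        '<cvParam cvRef="MS" accession="MS:1000744" name="selected ion m/z" value="%.6f" unitCvRef="MS" unitAccession="MS:1000040" unitName="m/z"/>%s',
        '</selectedIon></selectedIonList>',
        '<activation><cvParam cvRef="MS" accession="MS:1000422" name="beam-type collision-induced dissociation"/></activation>',
        '</precursor></precursorList>'),
        scan[[s@precursorId]], s@isoCenter %||% 0, half, half,
        s@isoCenter %||% 0, zline)
    }
    cvline <- if (!is.na(s@faimsCV)) sprintf(
      '<cvParam cvRef="MS" accession="MS:1001581" name="FAIMS compensation voltage" value="%g"/>',
      s@faimsCV) else ""
    sp[i] <- sprintf(paste0(
      '<spectrum index="%d" id="scan=%d" defaultArrayLength="%d">',
      '<cvParam cvRef="MS" accession="MS:1000511" name="ms level" value="%d"/>',
      '<cvParam cvRef="MS" accession="MS:1000127" name="centroid spectrum"/>',
      '<cvParam cvRef="MS" accession="MS:1000294" name="mass spectrum"/>%s%s',
      '<binaryDataArrayList count="2">',
      '<binaryDataArray encodedLength="%d">',
      '<cvParam cvRef="MS" accession="MS:1000523" name="64-bit float"/>',
      '<cvParam cvRef="MS" accession="MS:1000576" name="no compression"/>',
      '<cvParam cvRef="MS" accession="MS:1000514" name="m/z array" unitCvRef="MS" unitAccession="MS:1000040" unitName="m/z"/>',
      '<binary>%s</binary></binaryDataArray>',
      '<binaryDataArray encodedLength="%d">',
      '<cvParam cvRef="MS" accession="MS:1000523" name="64-bit float"/>',
      '<cvParam cvRef="MS" accession="MS:1000576" name="no compression"/>',
      '<cvParam cvRef="MS" accession="MS:1000515" name="intensity array" unitCvRef="MS" unitAccession="MS:1000131" unitName="number of detector counts"/>',
      '<binary>%s</binary></binaryDataArray>',
      '</binaryDataArrayList></spectrum>'),
      i - 1L, i, n, s@msLevel, cvline, prec,
      nchar(mzb), mzb, nchar(inb), inb)
  }
  doc <- paste0(
    '<?xml version="1.0" encoding="utf-8"?>\n',
    '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1.0">\n',
    '<cvList count="2">',
    '<cv id="MS" fullName="Proteomics Standards Initiative Mass Spectrometry Ontology" URI="https://raw.githubusercontent.com/HUPO-PSI/psi-ms-CV/master/psi-ms.obo"/>',
    '<cv id="UO" fullName="Unit Ontology" URI="https://raw.githubusercontent.com/bio-ontology-research-group/unit-ontology/master/unit.obo"/>',
    '</cvList>\n',
    '<fileDescription><fileContent>',
    '<cvParam cvRef="MS" accession="MS:1000579" name="MS1 spectrum"/>',
    '</fileContent></fileDescription>\n',
    '<softwareList count="1"><software id="nativeTDP" version="0.1.0">',
    '<cvParam cvRef="MS" accession="MS:1000799" name="custom unreleased software tool" value="nativeTDP"/>',
    '</software></softwareList>\n',
    '<instrumentConfigurationList count="1">',
    '<instrumentConfiguration id="IC1">',
    '<cvParam cvRef="MS" accession="MS:1000031" name="instrument model"/>',
    '</instrumentConfiguration></instrumentConfigurationList>\n',
    '<dataProcessingList count="1"><dataProcessing id="DP1">',
    '<processingMethod order="1" softwareRef="nativeTDP">',
    '<cvParam cvRef="MS" accession="MS:1000544" name="Conversion to mzML"/>',
    '</processingMethod></dataProcessing></dataProcessingList>\n',
    '<run id="run1" defaultInstrumentConfigurationRef="IC1">\n',
    sprintf('<spectrumList count="%d" defaultDataProcessingRef="DP1">\n',
            length(spectra)),
    paste(sp, collapse = "\n"), "\n",
    '</spectrumList>\n</run>\n</mzML>\n')
  writeLines(doc, path)
  invisible(path)
}
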