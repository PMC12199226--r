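# Minimal mzML writer used to author fixtures for the mzR import path.
# (Full mzML writing is not part of the package; this is test tooling.)

writeMzmlFixture <- function(run, path) {
  enc <- function(x)
    jsonlite::base64_enc(writeBin(as.double(x), raw(), size = 8,
                                  endian = "little"))
  specXml <- function(i, s) {
    b64mz <- enc(s@mz); b64int <- enc(s@intensity)
    prec <- if (s@msLevel == 2L) sprintf(paste0(
      '<precursorList count="1"><precursor><isolationWindow>',
      '<cvParam cvRef="MS" accession="MS:1000827" name="isolation window target m/z" value="%.6f" unitName="m/z"/>',
      '<cvParam cvRef="MS" accession="MS:1000828" name="isolation window lower offset" value="%.3f" unitName="m/z"/>',
      '<cvParam cvRef="MS" accession="MS:1000829" name="isolation window upper offset" value="%.3f" unitName="m/z"/>',
      '</isolationWindow><selectedIonList count="1"><selectedIon>',
      '<cvParam cvRef="MS" accession="MS:1000744" name="selected ion m/z" value="%.6f" unitName="m/z"/>',
      '</selectedIon></selectedIonList><activation>',
      '<cvParam cvRef="MS" accession="MS:1000422" name="beam-type collision-induced dissociation"/>',
      '</activation></precursor></precursorList>'),
      s@precursorMz, s@isolationWidth / 2, s@isolationWidth / 2, s@precursorMz)
    else ""
    sprintf(paste0(
      '<spectrum index="%d" id="scan=%d" defaultArrayLength="%d">',
      '<cvParam cvRef="MS" accession="MS:1000511" name="ms level" value="%d"/>',
      '<cvParam cvRef="MS" accession="MS:1000127" name="centroid spectrum"/>',
      '%s<binaryDataArrayList count="2">',
      '<binaryDataArray encodedLength="%d">',
      '<cvParam cvRef="MS" accession="MS:1000523" name="64-bit float"/>',
      '<cvParam cvRef="MS" accession="MS:1000576" name="no compression"/>',
      '<cvParam cvRef="MS" accession="MS:1000514" name="m/z array" unitName="m/z"/>',
      '<binary>%s</binary></binaryDataArray>',
      '<binaryDataArray encodedLength="%d">',
      '<cvParam cvRef="MS" accession="MS:1000523" name="64-bit float"/>',
      '<cvParam cvRef="MS" accession="MS:1000576" name="no compression"/>',
      '<cvParam cvRef="MS" accession="MS:1000515" name="intensity array" unitName="number of detector counts"/>',
      '<binary>%s</binary></binaryDataArray>',
      '</binaryDataArrayList></spectrum>'),
      i - 1L, s@scanId, length(s@mz), s@msLevel, prec,
      nchar(b64mz), b64mz, nchar(b64int), b64int)
  }
  specs <- vapply(seq_along(spectra(run)),
                  function(i) specXml(i, spectra(run)[[i]]), character(1))
  xml <- sprintf(paste0(
    '<?xml version="1.0" encoding="utf-8"?>\n',
    '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1.0">',
    '<cvList count="1"><cv id="MS" fullName="PSI-MS" URI="http://psidev.info"/></cvList>',
    '<fileDescription><fileContent>',
    '<cvParam cvRef="MS" accession="MS:1000580" name="MSn spectrum"/>',
    '</fileContent></fileDescription>',
    '<softwareList count="1"><software id="s" version="1"/></softwareList>',
    '<instrumentConfigurationList count="1"><instrumentConfiguration id="ic"/></instrumentConfigurationList>',
    '<dataProcessingList count="1"><dataProcessing id="dp">',
    '<processingMethod order="1" softwareRef="s">',
    '<cvParam cvRef="MS" accession="MS:1000544" name="Conversion to mzML"/>',
    '</processingMethod></dataProcessing></dataProcessingList>',
    '<run id="%s" defaultInstrumentConfigurationRef="ic">',
    '<spectrumList count="%d" defaultDataProcessingRef="dp">%s</spectrumList>',
    '</run></mzML>'),
    runId(run), length(spectra(run)), paste(specs, collapse = ""))
  writeLines(xml, path)
  invisible(path)
}
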