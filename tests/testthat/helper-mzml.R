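# Minimal mzML writer used as an independent oracle for read_mzml: spectra
# are encoded exactly as the mzML standard prescribes (64-bit little-endian
# floats, base64, no compression), without going through any mzML library.

b64_doubles <- function(x) {
  jsonlite::base64_enc(writeBin(as.numeric(x), raw(), size = 8,
                                endian = "little"))
}

mzml_spectrum_xml <- function(index, mz, intensity) {
  e_mz <- b64_doubles(mz)
  e_it <- b64_doubles(intensity)
  sprintf('
<spectrum index="%d" id="scan=%d" defaultArrayLength="%d">
  <cvParam cvRef="MS" accession="MS:1000511" name="ms level" value="1"/>
  <cvParam cvRef="MS" accession="MS:1000128" name="profile spectrum" value=""/>
  <binaryDataArrayList count="2">
    <binaryDataArray encodedLength="%d">
      <cvParam cvRef="MS" accession="MS:1000523" name="64-bit float" value=""/>
      <cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/>
      <cvParam cvRef="MS" accession="MS:1000514" name="m/z array" value=""/>
      <binary>%s</binary>
    </binaryDataArray>
    <binaryDataArray encodedLength="%d">
      <cvParam cvRef="MS" accession="MS:1000523" name="64-bit float" value=""/>
      <cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/>
      <cvParam cvRef="MS" accession="MS:1000515" name="intensity array" value=""/>
      <binary>%s</binary>
    </binaryDataArray>
  </binaryDataArrayList>
</spectrum>',
          index - 1L, index, length(mz), nchar(e_mz), e_mz, nchar(e_it), e_it)
}

write_minimal_mzml <- function(path, spectra) {
  body <- paste(vapply(seq_along(spectra), function(k) {
    mzml_spectrum_xml(k, spectra[[k]]$mz, spectra[[k]]$intensity)
  }, character(1)), collapse = "\n")
  doc <- paste0('<?xml version="1.0" encoding="utf-8"?>
<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1.0">
  <cvList count="1"><cv id="MS" fullName="PSI-MS" URI="http://psidev.info"/></cvList>
  <fileDescription><fileContent>
    <cvParam cvRef="MS" accession="MS:1000579" name="MS1 spectrum" value=""/>
  </fileContent></fileDescription>
  <run id="run1">
    <spectrumList count="', length(spectra), '" defaultDataProcessingRef="dp">',
    body, '
    </spectrumList>
  </run>
</mzML>')
  writeLines(doc, path)
  invisible(path)
}
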