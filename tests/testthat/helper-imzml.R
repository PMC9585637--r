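# Byte-level imzML/ibd fixture writer, independent of the package reader:
# XML is assembled from string templates and the binary sidecar with
# writeBin, following the imzML accession conventions (IMS:1000050/51 pixel
# positions, IMS:1000102/103 external offset / array length, MS:1000521/523
# float widths, continuous vs processed dialect flags IMS:1000030/31).
write_imzml_fixture <- function(stack, base_path, mz_centers,
                                dialect = c("continuous", "processed"),
                                intensity_dtype = c("f64", "f32")) {
  dialect <- match.arg(dialect)
  intensity_dtype <- match.arg(intensity_dtype)
  imzml_path <- paste0(base_path, ".imzML")
  ibd_path <- paste0(base_path, ".ibd")
  n <- dim(stack$data)[1]; m <- dim(stack$data)[2]; d <- dim(stack$data)[3]
  stopifnot(length(mz_centers) == d)

  int_acc <- if (intensity_dtype == "f64") "MS:1000523" else "MS:1000521"
  int_size <- if (intensity_dtype == "f64") 8L else 4L

  con <- file(ibd_path, "wb")
  writeBin(as.raw(1:16), con)  # 16-byte UUID placeholder
  offset <- 16L
  put_doubles <- function(x, size) {
    writeBin(as.numeric(x), con, size = size, endian = "little")
    start <- offset
    offset <<- offset + length(x) * size
    start
  }
  mz_shared_offset <- if (dialect == "continuous") put_doubles(mz_centers, 8L) else NA

  spectra_xml <- character(0)
  idx <- 0L
  for (y in seq_len(n)) {
    for (x in seq_len(m)) {
      idx <- idx + 1L
      mz_off <- if (dialect == "continuous") mz_shared_offset else put_doubles(mz_centers, 8L)
      int_off <- put_doubles(stack$data[y, x, ], int_size)
      spectra_xml <- c(spectra_xml, sprintf(
        '      <spectrum index="%d" id="spectrum=%d" defaultArrayLength="%d">
        <scanList count="1"><scan>
          <cvParam cvRef="IMS" accession="IMS:1000050" name="position x" value="%d"/>
          <cvParam cvRef="IMS" accession="IMS:1000051" name="position y" value="%d"/>
        </scan></scanList>
        <binaryDataArrayList count="2">
          <binaryDataArray encodedLength="0">
            <referenceableParamGroupRef ref="mzArray"/>
            <cvParam cvRef="IMS" accession="IMS:1000102" name="external offset" value="%d"/>
            <cvParam cvRef="IMS" accession="IMS:1000103" name="external array length" value="%d"/>
            <binary/>
          </binaryDataArray>
          <binaryDataArray encodedLength="0">
            <referenceableParamGroupRef ref="intensityArray"/>
            <cvParam cvRef="IMS" accession="IMS:1000102" name="external offset" value="%d"/>
            <cvParam cvRef="IMS" accession="IMS:1000103" name="external array length" value="%d"/>
            <binary/>
          </binaryDataArray>
        </binaryDataArrayList>
      </spectrum>',
        idx - 1L, idx, d, x, y, mz_off, d, int_off, d))
    }
  }
  close(con)

  dialect_acc <- if (dialect == "continuous") {
    '<cvParam cvRef="IMS" accession="IMS:1000030" name="continuous"/>'
  } else {
    '<cvParam cvRef="IMS" accession="IMS:1000031" name="processed"/>'
  }
  xml <- sprintf(
'<?xml version="1.0" encoding="UTF-8"?>
<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1">
  <fileDescription><fileContent>%s</fileContent></fileDescription>
  <referenceableParamGroupList count="2">
    <referenceableParamGroup id="mzArray">
      <cvParam cvRef="MS" accession="MS:1000514" name="m/z array"/>
      <cvParam cvRef="MS" accession="MS:1000523" name="64-bit float"/>
      <cvParam cvRef="IMS" accession="IMS:1000101" name="external data" value="true"/>
    </referenceableParamGroup>
    <referenceableParamGroup id="intensityArray">
      <cvParam cvRef="MS" accession="MS:1000515" name="intensity array"/>
      <cvParam cvRef="MS" accession="%s" name="float"/>
      <cvParam cvRef="IMS" accession="IMS:1000101" name="external data" value="true"/>
    </referenceableParamGroup>
  </referenceableParamGroupList>
  <run id="run0">
    <spectrumList count="%d">
%s
    </spectrumList>
  </run>
</mzML>', dialect_acc, int_acc, idx, paste(spectra_xml, collapse = "\n"))
  writeLines(xml, imzml_path)
  list(imzml = imzml_path, ibd = ibd_path)
}
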