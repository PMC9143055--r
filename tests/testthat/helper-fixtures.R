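# Small deterministic fixtures shared across test files.

tiny_run <- function(m = 4, n = 3, seed = 42) {
  set.seed(seed)
  msi_run(matrix(abs(rnorm(m * n)), m, n),
          data.frame(x = (seq_len(m) - 1L) %% 2L,
                     y = (seq_len(m) - 1L) %/% 2L),
          axis = sort(runif(n, 100, 1000)),
          run_id = "tiny", slide_id = "tiny")
}

small_sim_config <- function(seed = 7, ...) {
  sim_config(n_slides = 2, cores_per_slide = 12, tumour_fraction = 0.75,
             n_features = 20, n_markers = 3, marker_log2_effect = 1,
             slide_batch_sd = 0.2, ppm_jitter_sd = 2, noise_sd = 0.2,
             core_radius_px = 2, snr_floor = 1, seed = seed, ...)
}

# Writes a minimal imzML file (plus .ibd companion) that follows the
# imaging-MS conventions the package reader supports. `spectra` is a list of
# list(x, y, mz, intensity); continuous mode stores one shared m/z array.
write_imzml_fixture <- function(path, spectra, continuous = TRUE,
                                mz_size = 8, int_size = 4) {
  ibd_path <- sub("\\.imzml$", ".ibd", path, ignore.case = TRUE)
  con <- file(ibd_path, "wb")
  writeBin(as.raw(1:16), con)           # UUID placeholder
  offset <- 16
  write_array <- function(vals, size) {
    start <- offset
    writeBin(as.numeric(vals), con, size = size, endian = "little")
    offset <<- offset + size * length(vals)
    c(offset = start, length = length(vals), encoded = size * length(vals))
  }
  mz_meta <- NULL
  if (continuous) mz_meta <- write_array(spectra[[1]]$mz, mz_size)
  entries <- lapply(spectra, function(sp) {
    mzm <- if (continuous) mz_meta else write_array(sp$mz, mz_size)
    intm <- write_array(sp$intensity, int_size)
    list(sp = sp, mz = mzm, int = intm)
  })
  close(con)

  dtype_cv <- function(size, is_mz) {
    acc <- if (size == 8) "MS:1000523" else "MS:1000521"
    nm <- if (size == 8) "64-bit float" else "32-bit float"
    sprintf('<cvParam cvRef="MS" accession="%s" name="%s" value=""/>', acc, nm)
  }
  array_xml <- function(meta, group) {
    paste0(
      '<binaryDataArray encodedLength="0">',
      sprintf('<referenceableParamGroupRef ref="%s"/>', group),
      sprintf('<cvParam cvRef="IMS" accession="IMS:1000102" name="external offset" value="%d"/>', meta[["offset"]]),
      sprintf('<cvParam cvRef="IMS" accession="IMS:1000103" name="external array length" value="%d"/>', meta[["length"]]),
      sprintf('<cvParam cvRef="IMS" accession="IMS:1000104" name="external encoded length" value="%d"/>', meta[["encoded"]]),
      '<binary/></binaryDataArray>')
  }
  spectra_xml <- vapply(seq_along(entries), function(i) {
    e <- entries[[i]]
    paste0(
      sprintf('<spectrum index="%d" id="spectrum=%d" defaultArrayLength="%d">',
              i - 1, i, e$mz[["length"]]),
      '<scanList count="1"><scan>',
      sprintf('<cvParam cvRef="IMS" accession="IMS:1000050" name="position x" value="%d"/>', e$sp$x),
      sprintf('<cvParam cvRef="IMS" accession="IMS:1000051" name="position y" value="%d"/>', e$sp$y),
      '</scan></scanList>',
      '<binaryDataArrayList count="2">',
      array_xml(e$mz, "mzArray"), array_xml(e$int, "intensityArray"),
      '</binaryDataArrayList></spectrum>')
  }, character(1))

  mode_cv <- if (continuous) {
    '<cvParam cvRef="IMS" accession="IMS:1000030" name="continuous" value=""/>'
  } else {
    '<cvParam cvRef="IMS" accession="IMS:1000031" name="processed" value=""/>'
  }
  xml <- paste0(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1">',
    '<fileDescription><fileContent>', mode_cv, '</fileContent></fileDescription>',
    '<referenceableParamGroupList count="2">',
    '<referenceableParamGroup id="mzArray">',
    '<cvParam cvRef="MS" accession="MS:1000514" name="m/z array" value=""/>',
    dtype_cv(mz_size, TRUE), '</referenceableParamGroup>',
    '<referenceableParamGroup id="intensityArray">',
    '<cvParam cvRef="MS" accession="MS:1000515" name="intensity array" value=""/>',
    dtype_cv(int_size, FALSE), '</referenceableParamGroup>',
    '</referenceableParamGroupList>',
    '<run id="run1"><spectrumList count="', length(entries), '">',
    paste(spectra_xml, collapse = ""),
    '</spectrumList></run></mzML>')
  writeLines(xml, path)
  invisible(path)
}
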