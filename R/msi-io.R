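#' Construct a per-run MSI spectral matrix
#'
#' The unit of work of the pipeline is one MSI run: a dense `M x N` matrix of
#' non-negative intensities (`M` pixels, `N` mass-axis entries) together with
#' the integer pixel grid coordinates and the run's mass axis. Coordinates are
#' 0-based grid indices; the physical position of a pixel is
#' `index * pixel_size_um`. Non-rectangular acquisitions are represented by
#' absent rows, never by `NA` rows.
#'
#' @param intensities numeric matrix, `M` pixels by `N` mass-axis entries,
#'   all values finite and non-negative.
#' @param coords data frame with integer columns `x`, `y`, one row per pixel;
#'   no duplicated `(x, y)` pair.
#' @param axis strictly increasing positive numeric vector of m/z values
#'   (length `N`).
#' @param run_id,slide_id identifiers for the run and its slide.
#' @param pixel_size_um pixel edge length in micrometres (default 85, the
#'   typical DESI raster pitch).
#' @return An object of class `msi_run`.
#' @examples
#' run <- msi_run(matrix(1:6, 2, 3), data.frame(x = 0:1, y = c(0L, 0L)),
#'                axis = c(100, 200, 300), run_id = "r1", slide_id = "s1")
#' dim(run$intensities)
#' @export
msi_run <- function(intensities, coords, axis, run_id, slide_id,
                    pixel_size_um = 85) {
  intensities <- as.matrix(intensities)
  storage.mode(intensities) <- "double"
  coords <- tibble::as_tibble(coords[, c("x", "y")])
  coords$x <- as.integer(coords$x)
  coords$y <- as.integer(coords$y)
  out <- structure(
    list(run_id = as.character(run_id), slide_id = as.character(slide_id),
         coords = coords, intensities = intensities,
         axis = as.numeric(axis), pixel_size_um = as.numeric(pixel_size_um)),
    class = "msi_run")
  validate_msi_run(out)
}

#' Validate an `msi_run` object
#'
#' Checks the structural invariants: matrix row count equals the number of
#' coordinate rows, axis length equals the number of columns, the axis is
#' strictly increasing and positive, intensities are finite and non-negative,
#' and no pixel coordinate occurs twice.
#'
#' @param run an `msi_run` object.
#' @return `run`, invisibly returned on success; otherwise an error of class
#'   `msitma_validation_error`.
#' @export
validate_msi_run <- function(run) {
  stopifnot(inherits(run, "msi_run"))
  m <- nrow(run$intensities)
  n <- ncol(run$intensities)
  if (nrow(run$coords) != m) {
    abort(sprintf("run '%s': %d coordinate rows for %d pixel rows.",
                  run$run_id, nrow(run$coords), m),
          class = "msitma_validation_error")
  }
  if (length(run$axis) != n) {
    abort(sprintf("run '%s': axis length %d != %d matrix columns.",
                  run$run_id, length(run$axis), n),
          class = "msitma_validation_error")
  }
  if (n > 0) validate_mass_axis(run$axis)
  if (m > 0 && anyDuplicated(run$coords[, c("x", "y")])) {
    abort(sprintf("run '%s': duplicated pixel coordinates.", run$run_id),
          class = "msitma_validation_error")
  }
  if (m > 0 && n > 0 &&
      (any(!is.finite(run$intensities)) || any(run$intensities < 0))) {
    abort(sprintf("run '%s': intensities must be finite and non-negative.",
                  run$run_id),
          class = "msitma_validation_error")
  }
  invisible(run)
}

#' Validate a mass axis
#'
#' A mass axis is a strictly increasing vector of positive m/z values; it is
#' the `N` dimension of every `M x N` run matrix once runs share a common
#' axis.
#'
#' @param axis numeric vector of m/z values.
#' @return `axis`, invisibly, or a validation error.
#' @export
validate_mass_axis <- function(axis) {
  if (length(axis) == 0) return(invisible(axis))
  if (any(!is.finite(axis)) || any(axis <= 0)) {
    abort("mass axis values must be finite and > 0.",
          class = "msitma_validation_error")
  }
  if (is.unsorted(axis, strictly = TRUE)) {
    abort("mass axis must be strictly increasing.",
          class = "msitma_validation_error")
  }
  invisible(axis)
}

#' @export
print.msi_run <- function(x, ...) {
  cat(sprintf("<msi_run '%s' (slide '%s')>  %d pixels x %d m/z, pixel %g um\n",
              x$run_id, x$slide_id, nrow(x$intensities),
              ncol(x$intensities), x$pixel_size_um))
  invisible(x)
}

#' Total ion count per pixel
#'
#' @param run an `msi_run`.
#' @return numeric vector of per-pixel summed intensities (length `M`).
#' @export
tic <- function(run) {
  validate_msi_run(run)
  if (ncol(run$intensities) == 0) return(rep(0, nrow(run$intensities)))
  rowSums(run$intensities)
}

#' Write an MSI run in the internal container format
#'
#' The internal format is a single serialised R container per run holding the
#' dense intensity matrix, pixel coordinates, and mass axis; round-trips are
#' lossless to the bit. The run is validated before writing, so a run with an
#' unsorted axis or duplicate coordinates is refused.
#'
#' @param run an `msi_run`.
#' @param path output file path (conventionally `.msirun`).
#' @return `path`, invisibly.
#' @seealso [read_run()]
#' @export
write_run <- function(run, path) {
  validate_msi_run(run)
  dir <- dirname(path)
  if (!dir.exists(dir)) {
    abort(sprintf("cannot write '%s': directory does not exist.", path),
          class = "msitma_io_error")
  }
  payload <- unclass(run)
  payload$format_version <- 1L
  ok <- tryCatch({ saveRDS(payload, path, compress = FALSE); TRUE },
                 error = function(e) e)
  if (!isTRUE(ok)) {
    abort(sprintf("cannot write '%s': %s", path, conditionMessage(ok)),
          class = "msitma_io_error")
  }
  invisible(path)
}

#' Read one MSI run
#'
#' Reads a run either from the internal container format written by
#' [write_run()] or from an imzML file (continuous or processed mode,
#' read-only). Processed-mode spectra are rasterised onto the union of the
#' file's own m/z arrays. The result is validated before being returned.
#'
#' @param path file path.
#' @param format `"internal"` or `"imzml"`.
#' @param run_id,slide_id identifiers to attach when the file format carries
#'   none (imzML); default to the file name.
#' @return a validated `msi_run`.
#' @export
read_run <- function(path, format = c("internal", "imzml"),
                     run_id = NULL, slide_id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    abort(sprintf("file '%s' does not exist.", path),
          class = "msitma_io_error")
  }
  if (format == "internal") {
    payload <- tryCatch(readRDS(path), error = function(e) {
      abort(sprintf("cannot parse '%s' as an internal run container: %s",
                    path, conditionMessage(e)), class = "msitma_parse_error")
    })
    needed <- c("run_id", "slide_id", "coords", "intensities", "axis",
                "pixel_size_um")
    if (!is.list(payload) || !all(needed %in% names(payload))) {
      abort(sprintf("'%s' is not an internal run container.", path),
            class = "msitma_parse_error")
    }
    msi_run(payload$intensities, payload$coords, payload$axis,
            payload$run_id, payload$slide_id, payload$pixel_size_um)
  } else {
    read_imzml(path, run_id = run_id, slide_id = slide_id)
  }
}

# ---- imzML -----------------------------------------------------------------

imzml_cv <- function(node, accession) {
  p <- xml2::xml_find_first(
    node, sprintf(".//d1:cvParam[@accession='%s']", accession))
  if (inherits(p, "xml_missing")) return(NULL)
  xml2::xml_attr(p, "value")
}

imzml_has_cv <- function(node, accession) {
  !inherits(xml2::xml_find_first(
    node, sprintf(".//d1:cvParam[@accession='%s']", accession)), "xml_missing")
}

# map an array-description node to readBin arguments
imzml_dtype <- function(node) {
  if (imzml_has_cv(node, "MS:1000523")) return(list(what = "double", size = 8))
  if (imzml_has_cv(node, "MS:1000521")) return(list(what = "double", size = 4))
  if (imzml_has_cv(node, "MS:1000522")) return(list(what = "integer", size = 8))
  if (imzml_has_cv(node, "MS:1000519")) return(list(what = "integer", size = 4))
  abort("imzML binary array with unsupported or missing data type.",
        class = "msitma_parse_error")
}

read_imzml <- function(path, run_id = NULL, slide_id = NULL) {
  doc <- tryCatch(xml2::read_xml(path), error = function(e) {
    abort(sprintf("cannot parse imzML '%s': %s", path, conditionMessage(e)),
          class = "msitma_parse_error")
  })
  ibd_path <- sub("\\.imzml$", ".ibd", path, ignore.case = TRUE)
  if (identical(ibd_path, path)) ibd_path <- paste0(path, ".ibd")
  if (!file.exists(ibd_path)) {
    abort(sprintf("imzML binary companion '%s' not found.", ibd_path),
          class = "msitma_io_error")
  }

  file_content <- xml2::xml_find_first(doc, ".//d1:fileContent")
  continuous <- imzml_has_cv(file_content, "IMS:1000030")

  # referenceable param groups tell m/z arrays from intensity arrays
  groups <- xml2::xml_find_all(doc, ".//d1:referenceableParamGroup")
  group_role <- vapply(groups, function(g) {
    if (imzml_has_cv(g, "MS:1000514")) "mz"
    else if (imzml_has_cv(g, "MS:1000515")) "intensity"
    else "other"
  }, character(1))
  names(group_role) <- xml2::xml_attr(groups, "id")
  group_dtype <- lapply(groups, imzml_dtype_or_null)
  names(group_dtype) <- xml2::xml_attr(groups, "id")

  spectra <- xml2::xml_find_all(doc, ".//d1:spectrum")
  if (length(spectra) == 0) {
    abort(sprintf("imzML '%s' contains no spectra.", path),
          class = "msitma_parse_error")
  }

  con <- file(ibd_path, "rb")
  on.exit(close(con), add = TRUE)

  read_array <- function(arr_node) {
    grp <- xml2::xml_find_first(arr_node, ".//d1:referenceableParamGroupRef")
    ref <- if (!inherits(grp, "xml_missing")) xml2::xml_attr(grp, "ref") else NA
    role <- if (!is.na(ref) && ref %in% names(group_role)) group_role[[ref]]
            else if (imzml_has_cv(arr_node, "MS:1000514")) "mz"
            else if (imzml_has_cv(arr_node, "MS:1000515")) "intensity"
            else "other"
    dt <- if (!is.na(ref) && !is.null(group_dtype[[ref]])) group_dtype[[ref]]
          else imzml_dtype(arr_node)
    offset <- as.numeric(imzml_cv(arr_node, "IMS:1000102"))
    n <- as.integer(imzml_cv(arr_node, "IMS:1000103"))
    if (is.na(offset) || is.na(n)) {
      abort(sprintf("imzML '%s': binary array without external offset/length.",
                    path), class = "msitma_parse_error")
    }
    seek(con, where = offset, origin = "start")
    vals <- readBin(con, what = dt$what, n = n, size = dt$size, endian = "little")
    list(role = role, values = as.numeric(vals))
  }

  px <- lapply(spectra, function(sp) {
    x <- as.integer(imzml_cv(sp, "IMS:1000050"))
    y <- as.integer(imzml_cv(sp, "IMS:1000051"))
    if (is.na(x) || is.na(y)) {
      abort(sprintf("imzML '%s': spectrum '%s' lacks pixel coordinates.",
                    path, xml2::xml_attr(sp, "id")),
            class = "msitma_parse_error")
    }
    arrays <- lapply(xml2::xml_find_all(sp, ".//d1:binaryDataArray"), read_array)
    roles <- vapply(arrays, `[[`, character(1), "role")
    mz <- arrays[[match("mz", roles)]]$values
    inten <- arrays[[match("intensity", roles)]]$values
    if (length(mz) != length(inten)) {
      abort(sprintf("imzML '%s': m/z and intensity arrays differ in length.",
                    path), class = "msitma_parse_error")
    }
    list(x = x, y = y, mz = mz, intensity = inten)
  })

  if (is.null(run_id)) run_id <- sub("\\.imzml$", "", basename(path),
                                     ignore.case = TRUE)
  if (is.null(slide_id)) slide_id <- run_id

  if (continuous) {
    axis <- px[[1]]$mz
    mat <- do.call(rbind, lapply(px, function(p) {
      if (length(p$mz) != length(axis)) {
        abort(sprintf("imzML '%s': continuous mode but spectra differ in axis length.",
                      path), class = "msitma_parse_error")
      }
      p$intensity
    }))
  } else {
    axis <- sort(unique(unlist(lapply(px, `[[`, "mz"))))
    mat <- matrix(0, nrow = length(px), ncol = length(axis))
    for (i in seq_along(px)) {
      j <- match(px[[i]]$mz, axis)
      agg <- rowsum(px[[i]]$intensity, j)
      mat[i, as.integer(rownames(agg))] <- agg[, 1]
    }
  }
  coords <- tibble::tibble(x = vapply(px, `[[`, integer(1), "x"),
                           y = vapply(px, `[[`, integer(1), "y"))
  msi_run(mat, coords, axis, run_id, slide_id)
}

imzml_dtype_or_null <- function(node) {
  tryCatch(imzml_dtype(node), error = function(e) NULL)
}

# ---- core tables -----------------------------------------------------------

#' Write a core table to CSV
#'
#' One row per TMA core: identifiers, label, pixel count, and the averaged
#' spectrum spread into one `mz_*` column per mass-axis entry, so the file is
#' self-describing and readable by any CSV tool.
#'
#' @param core_table a core table as returned by [average_core_spectra()]
#'   (tibble with a `spectrum` list-column and an `axis` attribute).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_core_table <- function(core_table, path) {
  axis <- attr(core_table, "axis")
  spec <- do.call(rbind, core_table$spectrum)
  colnames(spec) <- sprintf("mz_%.5f", axis)
  flat <- cbind(as.data.frame(core_table[setdiff(names(core_table), "spectrum")]),
                as.data.frame(spec))
  utils::write.csv(flat, path, row.names = FALSE)
  invisible(path)
}

#' Read a core table written by [write_core_table()]
#'
#' @param path CSV path.
#' @return a core table tibble with `spectrum` list-column and `axis`
#'   attribute.
#' @export
read_core_table <- function(path) {
  flat <- utils::read.csv(path, check.names = FALSE)
  mz_cols <- grep("^mz_", names(flat), value = TRUE)
  axis <- as.numeric(sub("^mz_", "", mz_cols))
  meta <- flat[setdiff(names(flat), mz_cols)]
  spec <- as.matrix(flat[mz_cols])
  out <- tibble::as_tibble(meta)
  out$spectrum <- lapply(seq_len(nrow(spec)), function(i) unname(spec[i, ]))
  attr(out, "axis") <- axis
  out
}
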