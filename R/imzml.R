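# Minimal imzML importer (continuous and processed dialects).
#
# imzML stores the spectral metadata as mzML-flavoured XML and the m/z /
# intensity arrays in a sidecar binary file (.ibd) addressed by external
# offset / length cvParams. No installed R package reads imzML, so the
# subset needed to extract ion images is parsed here directly: per-spectrum
# pixel coordinates (IMS:1000050/51), external array offsets
# (IMS:1000102/103) and the binary data type of each array
# (MS:1000521 32-bit float / MS:1000523 64-bit float, plus 32-bit ints).

imzml_dtype <- function(cv_accessions) {
  if ("MS:1000523" %in% cv_accessions) return(list(what = "double", size = 8))
  if ("MS:1000521" %in% cv_accessions) return(list(what = "double", size = 4))
  if ("MS:1000519" %in% cv_accessions) return(list(what = "integer", size = 4))
  abort("unsupported or missing binary data type in imzML param group")
}

imzml_cv <- function(node) {
  cvs <- xml2::xml_find_all(node, ".//cvParam")
  tibble(
    accession = xml2::xml_attr(cvs, "accession"),
    name = xml2::xml_attr(cvs, "name"),
    value = xml2::xml_attr(cvs, "value")
  )
}

#' Import imzML data as a channel stack
#'
#' Reads an imzML/ibd pair and extracts one ion image per requested m/z
#' channel: the per-pixel intensity of a channel is the summed intensity of
#' all peaks within `mz_center +/- tolerance` (`tolerance = 0` keeps
#' exact-center matches only). Overlapping tolerance windows are extracted
#' independently — a peak inside two windows contributes to both channels.
#' The grid is inferred from the coordinate metadata; pixels without a
#' spectrum are zero-filled.
#'
#' @param path path to the `.imzML` file; the `.ibd` binary is expected next
#'   to it (same base name).
#' @param mz_channels numeric vector of m/z window centers.
#' @param tolerance half-width of each extraction window, in m/z units.
#' @return A [channel_stack()] with labels `"mz<center>"`; rows are y
#'   positions (scan lines), columns x positions.
#' @export
import_imzml <- function(path, mz_channels, tolerance = 0.05) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  mz_channels <- as.numeric(mz_channels)
  if (length(mz_channels) < 1 || any(!is.finite(mz_channels))) {
    abort("need at least one finite m/z channel center")
  }
  if (tolerance < 0) abort("`tolerance` must be >= 0")
  ibd_path <- sub("\\.imzml$", ".ibd", path, ignore.case = TRUE)
  if (identical(ibd_path, path)) ibd_path <- paste0(path, ".ibd")
  if (!file.exists(ibd_path)) abort(sprintf("missing binary sidecar: %s", ibd_path))

  doc <- tryCatch(xml2::read_xml(path), error = function(e) {
    abort(sprintf("cannot parse imzML file %s: %s", path, conditionMessage(e)))
  })
  xml2::xml_ns_strip(doc)

  # binary data types per referenceable param group
  groups <- xml2::xml_find_all(doc, ".//referenceableParamGroup")
  group_info <- list()
  for (g in groups) {
    id <- xml2::xml_attr(g, "id")
    cv <- imzml_cv(g)
    group_info[[id]] <- list(
      dtype = tryCatch(imzml_dtype(cv$accession), error = function(e) NULL),
      is_mz = "MS:1000514" %in% cv$accession,
      is_intensity = "MS:1000515" %in% cv$accession
    )
  }

  spectra <- xml2::xml_find_all(doc, ".//spectrum")
  if (length(spectra) == 0) abort("imzML file contains no spectra")

  parse_spectrum <- function(sp) {
    cv_scan <- imzml_cv(xml2::xml_find_first(sp, ".//scan"))
    x <- as.integer(cv_scan$value[cv_scan$accession == "IMS:1000050"][1])
    y <- as.integer(cv_scan$value[cv_scan$accession == "IMS:1000051"][1])
    arrays <- xml2::xml_find_all(sp, ".//binaryDataArray")
    info <- lapply(arrays, function(a) {
      ref <- xml2::xml_attr(xml2::xml_find_first(a, ".//referenceableParamGroupRef"), "ref")
      cv <- imzml_cv(a)
      gi <- if (!is.na(ref)) group_info[[ref]] else NULL
      dtype <- if (!is.null(gi)) gi$dtype else NULL
      if (is.null(dtype)) dtype <- imzml_dtype(cv$accession)
      list(
        is_mz = (!is.null(gi) && gi$is_mz) || "MS:1000514" %in% cv$accession,
        dtype = dtype,
        offset = as.numeric(cv$value[cv$accession == "IMS:1000102"][1]),
        length = as.numeric(cv$value[cv$accession == "IMS:1000103"][1])
      )
    })
    list(x = x, y = y, arrays = info)
  }
  parsed <- lapply(spectra, parse_spectrum)

  xs <- vapply(parsed, `[[`, integer(1), "x")
  ys <- vapply(parsed, `[[`, integer(1), "y")
  if (any(is.na(xs)) || any(is.na(ys))) abort("spectrum without pixel coordinates")
  n <- max(ys); m <- max(xs)
  d <- length(mz_channels)
  data <- array(0, dim = c(n, m, d))

  con <- file(ibd_path, "rb")
  on.exit(close(con))
  read_array <- function(a) {
    seek(con, where = a$offset, origin = "start")
    readBin(con, what = a$dtype$what, n = a$length, size = a$dtype$size,
            endian = "little")
  }
  for (sp in parsed) {
    mz_arr <- NULL; int_arr <- NULL
    for (a in sp$arrays) {
      if (a$is_mz) mz_arr <- read_array(a) else int_arr <- read_array(a)
    }
    if (is.null(mz_arr) || is.null(int_arr)) abort("spectrum missing m/z or intensity array")
    for (c in seq_len(d)) {
      sel <- abs(mz_arr - mz_channels[c]) <= tolerance
      if (any(sel)) data[sp$y, sp$x, c] <- data[sp$y, sp$x, c] + sum(int_arr[sel])
    }
  }
  stack <- channel_stack(data, paste0("mz", format(mz_channels, trim = TRUE)))
  empty <- vapply(seq_len(d), function(c) all(stack$data[, , c] == 0), logical(1))
  if (any(empty)) {
    abort(sprintf("no signal extracted for channel %s (center %s +/- %s)",
                  stack$channel_labels[which(empty)[1]],
                  format(mz_channels[which(empty)[1]]), format(tolerance)))
  }
  stack
}
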