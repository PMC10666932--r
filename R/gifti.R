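#' GIFTI import/export
#'
#' Minimal GIFTI (Geometry format under the Neuroimaging Informatics
#' Technology Initiative) reader/writer for interoperating with real
#' surface-based datasets: surface meshes (pointset + triangle arrays),
#' per-vertex maps and masks, and multi-timepoint data series. Supports
#' `ASCII`, `Base64Binary` and `GZipBase64Binary` encodings,
#' little-endian, row- or column-major arrays. Only the subset of the
#' format needed for per-vertex cortical data is implemented.
#'
#' @name gifti-io
NULL

.gifti_dtype <- function(label) {
  switch(label,
         NIFTI_TYPE_FLOAT32 = list(what = "double", size = 4L),
         NIFTI_TYPE_FLOAT64 = list(what = "double", size = 8L),
         NIFTI_TYPE_INT32 = list(what = "integer", size = 4L),
         NIFTI_TYPE_UINT8 = list(what = "integer", size = 1L),
         .stop_invalid("unsupported GIFTI DataType: ", label))
}

.gifti_read_metadata <- function(node) {
  mds <- xml2::xml_find_all(node, "./MetaData/MD")
  vals <- vapply(mds, function(md)
    xml2::xml_text(xml2::xml_find_first(md, "./Value")), character(1))
  names(vals) <- vapply(mds, function(md)
    xml2::xml_text(xml2::xml_find_first(md, "./Name")), character(1))
  vals
}

#' Read a GIFTI file into a list of data arrays
#'
#' @param path Path to a `.gii` file.
#' @return A list with `metadata` (named character) and `arrays`, each a
#'   list with `intent`, `data` (vector or matrix) and `metadata`.
#' @rdname gifti-io
#' @export
read_gifti <- function(path) {
  .assert(file.exists(path), "no such file: ", path)
  doc <- xml2::read_xml(path)
  arrays <- lapply(xml2::xml_find_all(doc, "//DataArray"), function(da) {
    att <- function(a) xml2::xml_attr(da, a)
    encoding <- att("Encoding")
    endian <- att("Endian")
    if (!is.na(endian) && !identical(endian, "LittleEndian")) {
      .stop_invalid("only LittleEndian GIFTI data is supported")
    }
    dtype <- .gifti_dtype(att("DataType"))
    dims <- as.integer(c(att("Dim0"), att("Dim1")))
    dims <- dims[!is.na(dims)]
    n <- prod(dims)
    raw_text <- xml2::xml_text(xml2::xml_find_first(da, "./Data"))
    vals <- switch(
      encoding,
      ASCII = as.numeric(strsplit(trimws(raw_text), "\\s+")[[1]]),
      Base64Binary = readBin(jsonlite::base64_dec(gsub("\\s", "", raw_text)),
                             dtype$what, n = n, size = dtype$size,
                             endian = "little",
                             signed = !identical(att("DataType"),
                                                 "NIFTI_TYPE_UINT8")),
      GZipBase64Binary = readBin(
        memDecompress(jsonlite::base64_dec(gsub("\\s", "", raw_text)),
                      type = "gzip"),
        dtype$what, n = n, size = dtype$size, endian = "little",
        signed = !identical(att("DataType"), "NIFTI_TYPE_UINT8")),
      .stop_invalid("unsupported GIFTI encoding: ", encoding)
    )
    .assert(length(vals) == n, "GIFTI data length mismatch in ", path)
    data <- if (length(dims) == 2L) {
      if (identical(att("ArrayIndexingOrder"), "ColumnMajorOrder")) {
        matrix(vals, dims[1], dims[2])
      } else {
        matrix(vals, dims[1], dims[2], byrow = TRUE)
      }
    } else vals
    list(intent = att("Intent"), data = data,
         metadata = .gifti_read_metadata(da))
  })
  list(metadata = .gifti_read_metadata(xml2::xml_root(doc)),
       arrays = arrays)
}

.gifti_md_xml <- function(metadata) {
  if (length(metadata) == 0) return("<MetaData/>")
  paste0("<MetaData>", paste0(
    "<MD><Name><![CDATA[", names(metadata), "]]></Name><Value><![CDATA[",
    unname(metadata), "]]></Value></MD>", collapse = ""), "</MetaData>")
}

.gifti_encode <- function(values, datatype, encoding) {
  if (encoding == "ASCII") {
    return(paste(format(values, digits = 17, trim = TRUE,
                        scientific = FALSE), collapse = " "))
  }
  dtype <- .gifti_dtype(datatype)
  raw_ <- writeBin(
    if (dtype$what == "integer") as.integer(values) else as.numeric(values),
    raw(), size = dtype$size, endian = "little")
  jsonlite::base64_enc(raw_)
}

#' Write a GIFTI file from a list of data arrays
#'
#' @param arrays List of lists with fields `intent`, `data`, `datatype`
#'   (a NIFTI type label) and optionally `metadata`.
#' @param metadata Named character vector of file-level metadata.
#' @param encoding `"Base64Binary"` or `"ASCII"`.
#' @rdname gifti-io
#' @export
write_gifti <- function(arrays, path, metadata = character(),
                        encoding = c("Base64Binary", "ASCII")) {
  encoding <- match.arg(encoding)
  blocks <- vapply(arrays, function(a) {
    d <- a$data
    dim_attrs <- if (is.matrix(d)) {
      sprintf('Dimensionality="2" Dim0="%d" Dim1="%d"', nrow(d), ncol(d))
    } else {
      sprintf('Dimensionality="1" Dim0="%d"', length(d))
    }
    vals <- if (is.matrix(d)) as.vector(t(d)) else as.vector(d)
    paste0(
      sprintf(paste0('<DataArray Intent="%s" DataType="%s" ',
                     'ArrayIndexingOrder="RowMajorOrder" %s ',
                     'Encoding="%s" Endian="LittleEndian" ',
                     'ExternalFileName="" ExternalFileOffset="">'),
              a$intent, a$datatype, dim_attrs, encoding),
      .gifti_md_xml(a$metadata),
      "<Data>", .gifti_encode(vals, a$datatype, encoding), "</Data>",
      "</DataArray>"
    )
  }, character(1))
  xml <- paste0(
    '<?xml version="1.0" encoding="UTF-8"?>\n',
    '<!DOCTYPE GIFTI SYSTEM "http://www.nitrc.org/frs/download.php/115/gifti.dtd">\n',
    sprintf('<GIFTI Version="1.0" NumberOfDataArrays="%d">',
            length(arrays)),
    .gifti_md_xml(metadata), paste(blocks, collapse = ""), "</GIFTI>"
  )
  writeLines(xml, path)
  invisible(path)
}

#' @details `write_gifti_surface()` / `read_gifti_surface()` convert
#'   between [surface_mesh][build_icosphere] objects and GIFTI surface
#'   files (pointset + triangle arrays; triangle indices are 0-based on
#'   disk per the GIFTI convention and 1-based in memory). On read, the
#'   sphere is rescaled to the nominal radius (default 100 mm) so
#'   millimetre searchlight radii behave as on a template cortical sphere.
#' @rdname gifti-io
#' @export
write_gifti_surface <- function(mesh, path) {
  stopifnot(inherits(mesh, "surface_mesh"))
  write_gifti(list(
    list(intent = "NIFTI_INTENT_POINTSET", data = mesh$vertices,
         datatype = "NIFTI_TYPE_FLOAT32",
         metadata = c(AnatomicalStructurePrimary =
                        if (mesh$hemisphere == "left") "CortexLeft"
                        else "CortexRight")),
    list(intent = "NIFTI_INTENT_TRIANGLE", data = mesh$faces - 1L,
         datatype = "NIFTI_TYPE_INT32")
  ), path)
}

#' @rdname gifti-io
#' @export
read_gifti_surface <- function(path, hemisphere = NULL,
                               nominal_radius_mm = 100) {
  g <- read_gifti(path)
  intents <- vapply(g$arrays, `[[`, character(1), "intent")
  pt <- g$arrays[[match("NIFTI_INTENT_POINTSET", intents)]]
  tr <- g$arrays[[match("NIFTI_INTENT_TRIANGLE", intents)]]
  .assert(!is.null(pt$data) && !is.null(tr$data),
          "GIFTI surface needs pointset and triangle arrays")
  faces <- matrix(as.integer(tr$data), nrow(tr$data), 3) + 1L
  n <- nrow(pt$data)
  if (any(faces < 1 | faces > n)) {
    .stop_invalid("triangle indices out of range for ", n, " vertices")
  }
  if (is.null(hemisphere)) {
    anat <- pt$metadata["AnatomicalStructurePrimary"]
    hemisphere <- if (identical(unname(anat), "CortexRight")) "right"
      else "left"
  }
  order_ <- log((n - 2) / 10, base = 4)
  .assert(abs(order_ - round(order_)) < 1e-9,
          "vertex count ", n, " is not an icosphere count (10*4^k + 2)")
  structure(
    list(
      vertices = .project_to_sphere(pt$data, nominal_radius_mm),
      faces = faces, hemisphere = hemisphere,
      cortex_mask = rep(TRUE, n),
      subdivision_order = as.integer(round(order_)),
      nominal_radius_mm = nominal_radius_mm
    ),
    class = "surface_mesh"
  )
}

#' @details `write_gifti_map()` / `read_gifti_map()` handle single
#'   per-vertex maps (contrast maps keep category/provenance metadata; `NA`
#'   at masked vertices is stored as NaN).
#' @rdname gifti-io
#' @export
write_gifti_map <- function(map, path) {
  values <- .map_values(map)
  md <- if (inherits(map, "contrast_map")) {
    c(subject_id = map$subject_id, category = map$category,
      provenance = map$provenance,
      source_description = map$source_description)
  } else character()
  write_gifti(list(list(intent = "NIFTI_INTENT_NONE", data = values,
                        datatype = "NIFTI_TYPE_FLOAT32", metadata = md)),
              path)
}

#' @rdname gifti-io
#' @param expected_n_vertices If given, reading errors when the file's
#'   vertex count differs (guards against mixing meshes).
#' @export
read_gifti_map <- function(path, expected_n_vertices = NULL) {
  g <- read_gifti(path)
  a <- g$arrays[[1]]
  values <- as.numeric(a$data)
  if (!is.null(expected_n_vertices) &&
      length(values) != expected_n_vertices) {
    .stop_invalid("map has ", length(values), " vertices; expected ",
                  expected_n_vertices)
  }
  md <- a$metadata
  if (all(c("subject_id", "category", "provenance") %in% names(md))) {
    mask <- is.finite(values)
    return(.new_contrast_map(values, md[["subject_id"]], md[["category"]],
                             md[["provenance"]],
                             md["source_description"], mask))
  }
  values
}

#' @details `write_gifti_timeseries()` / `read_gifti_timeseries()` store a
#'   multi-run [time_series()] as one time-series data array per timepoint,
#'   with the run table and TR in the file metadata so run boundaries
#'   survive the round trip.
#' @rdname gifti-io
#' @export
write_gifti_timeseries <- function(ts, path) {
  stopifnot(inherits(ts, "time_series"))
  arrays <- lapply(seq_len(nrow(ts$data)), function(t_) {
    list(intent = "NIFTI_INTENT_TIME_SERIES", data = ts$data[t_, ],
         datatype = "NIFTI_TYPE_FLOAT32")
  })
  write_gifti(arrays, path, metadata = c(
    subject_id = ts$subject_id, condition_id = ts$condition_id,
    tr_s = format(ts$tr_s, digits = 17),
    run_table = jsonlite::toJSON(ts$run_table)
  ))
}

#' @rdname gifti-io
#' @export
read_gifti_timeseries <- function(path, expected_n_vertices = NULL) {
  g <- read_gifti(path)
  data <- do.call(rbind, lapply(g$arrays, function(a) as.numeric(a$data)))
  if (!is.null(expected_n_vertices) &&
      ncol(data) != expected_n_vertices) {
    .stop_invalid("time series has ", ncol(data), " vertices; expected ",
                  expected_n_vertices)
  }
  md <- g$metadata
  time_series(data,
              as.data.frame(jsonlite::fromJSON(md[["run_table"]])),
              subject_id = md[["subject_id"]],
              condition_id = md[["condition_id"]],
              tr_s = as.numeric(md[["tr_s"]]))
}

#' Read a cortex mask from GIFTI shape/label data or one-column text
#'
#' @param path `.gii` file (first data array, nonzero = cortical) or a
#'   plain text file with one 0/1 value per vertex.
#' @return Logical vector.
#' @export
read_cortex_mask <- function(path) {
  if (grepl("\\.gii$", path)) {
    as.numeric(read_gifti(path)$arrays[[1]]$data) != 0
  } else {
    scan(path, what = numeric(), quiet = TRUE) != 0
  }
}
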