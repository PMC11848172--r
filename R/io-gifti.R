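# Minimal GIFTI surface/functional XML support. Written arrays use ASCII
# encoding (text-only, diff-friendly); readers additionally accept
# Base64Binary and GZipBase64Binary little/big-endian payloads, which covers
# files produced by the common neuroimaging toolchains.

gifti_decode_data <- function(node) {
  data_node <- xml2::xml_find_first(node, ".//Data")
  txt <- xml2::xml_text(data_node)
  enc <- xml2::xml_attr(node, "Encoding")
  dtype <- xml2::xml_attr(node, "DataType")
  endian <- xml2::xml_attr(node, "Endian")
  endian <- if (is.na(endian) || endian == "LittleEndian") "little" else "big"
  n <- prod(as.integer(vapply(
    seq_len(as.integer(xml2::xml_attr(node, "Dimensionality"))) - 1L,
    function(d) as.integer(xml2::xml_attr(node, paste0("Dim", d))),
    integer(1))))
  if (enc == "ASCII") {
    vals <- scan(text = txt, quiet = TRUE)
    # the declared storage type is part of the format contract: quantize so
    # ASCII and binary encodings of the same array read back identically
    if (dtype == "NIFTI_TYPE_FLOAT32") vals <- as_float32(vals)
  } else if (enc %in% c("Base64Binary", "GZipBase64Binary")) {
    bytes <- jsonlite::base64_dec(gsub("[[:space:]]", "", txt))
    if (enc == "GZipBase64Binary") bytes <- memDecompress(bytes, type = "gzip")
    vals <- switch(dtype,
      NIFTI_TYPE_FLOAT32 = readBin(bytes, "numeric", n = n, size = 4L,
                                   endian = endian),
      NIFTI_TYPE_FLOAT64 = readBin(bytes, "numeric", n = n, size = 8L,
                                   endian = endian),
      NIFTI_TYPE_INT32 = readBin(bytes, "integer", n = n, size = 4L,
                                 endian = endian),
      NIFTI_TYPE_UINT8 = as.integer(readBin(bytes, "integer", n = n, size = 1L,
                                            signed = FALSE)),
      stopf("unsupported GIFTI DataType '%s'", dtype))
  } else {
    stopf("unsupported GIFTI encoding '%s'", enc)
  }
  if (length(vals) != n)
    stopf("GIFTI data array has %d values, header declares %d",
          length(vals), n)
  vals
}

gifti_array_dims <- function(node) {
  dim_n <- as.integer(xml2::xml_attr(node, "Dimensionality"))
  vapply(seq_len(dim_n) - 1L,
         function(d) as.integer(xml2::xml_attr(node, paste0("Dim", d))),
         integer(1))
}

gifti_data_arrays <- function(path) {
  doc <- xml2::read_xml(path)
  if (xml2::xml_name(doc) != "GIFTI") stopf("'%s' is not a GIFTI file", path)
  xml2::xml_find_all(doc, ".//DataArray")
}

gifti_array_xml <- function(intent, dtype, values, dims,
                            ind_ord = "RowMajorOrder") {
  dim_attrs <- paste(sprintf('Dim%d="%d"', seq_along(dims) - 1L, dims),
                     collapse = " ")
  fmt <- if (grepl("FLOAT", dtype)) "%.9g" else "%d"
  txt <- paste(sprintf(fmt, values), collapse = " ")
  sprintf(
    paste0('<DataArray Intent="%s" DataType="%s" ArrayIndexingOrder="%s" ',
           'Dimensionality="%d" %s Encoding="ASCII" Endian="LittleEndian" ',
           'ExternalFileName="" ExternalFileOffset="">\n',
           '<Data>%s</Data>\n</DataArray>'),
    intent, dtype, ind_ord, length(dims), dim_attrs, txt)
}

gifti_write_doc <- function(arrays_xml, path) {
  writeLines(c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf('<GIFTI Version="1.0" NumberOfDataArrays="%d">',
            length(arrays_xml)),
    arrays_xml,
    "</GIFTI>"), path)
  invisible(path)
}

#' Read a GIFTI functional/shape file as a vertex map
#'
#' @param path `.func.gii` / `.shape.gii` path.
#' @param expected_n Optional vertex count to validate against.
#' @return Numeric vertex map (first data array).
#' @export
read_gifti_map <- function(path, expected_n = NULL) {
  arrays <- gifti_data_arrays(path)
  if (!length(arrays)) stopf("no data arrays in '%s'", path)
  vals <- gifti_decode_data(arrays[[1L]])
  if (!is.null(expected_n) && length(vals) != expected_n)
    stopf("GIFTI map '%s' has %d values, expected %d", path, length(vals),
          expected_n)
  vals
}

#' Write a vertex map as a GIFTI functional file
#'
#' Values pass through float32 quantization (the declared data type) so that
#' write/read round trips are bit-exact.
#'
#' @param map Numeric vertex map.
#' @param path Output path (`.func.gii`).
#' @return `path`, invisibly.
#' @export
write_gifti_map <- function(map, path) {
  gifti_write_doc(gifti_array_xml("NIFTI_INTENT_NONE", "NIFTI_TYPE_FLOAT32",
                                  as_float32(map), length(map)), path)
}

#' Read a GIFTI surface geometry file
#'
#' Expects a POINTSET and a TRIANGLE data array.
#'
#' @param path `.surf.gii` path.
#' @param hemisphere Hemisphere tag to attach.
#' @return A [surface_mesh()].
#' @export
read_gifti_surface <- function(path, hemisphere = "left") {
  arrays <- gifti_data_arrays(path)
  intents <- vapply(arrays, function(a) xml2::xml_attr(a, "Intent"),
                    character(1))
  ip <- match("NIFTI_INTENT_POINTSET", intents)
  it <- match("NIFTI_INTENT_TRIANGLE", intents)
  if (is.na(ip) || is.na(it))
    stopf("'%s' lacks POINTSET/TRIANGLE arrays", path)
  vdim <- gifti_array_dims(arrays[[ip]])
  fdim <- gifti_array_dims(arrays[[it]])
  v <- matrix(gifti_decode_data(arrays[[ip]]), nrow = vdim[1L],
              ncol = vdim[2L], byrow = TRUE)
  f <- matrix(as.integer(gifti_decode_data(arrays[[it]])), nrow = fdim[1L],
              ncol = fdim[2L], byrow = TRUE) + 1L
  surface_mesh(v, f, hemisphere = hemisphere)
}

#' Write a surface mesh as a GIFTI geometry file
#'
#' @param mesh A [surface_mesh()].
#' @param path Output path (`.surf.gii`).
#' @return `path`, invisibly.
#' @export
write_gifti_surface <- function(mesh, path) {
  gifti_write_doc(c(
    gifti_array_xml("NIFTI_INTENT_POINTSET", "NIFTI_TYPE_FLOAT32",
                    as_float32(as.numeric(t(mesh$vertices))),
                    c(n_vertices(mesh), 3L)),
    gifti_array_xml("NIFTI_INTENT_TRIANGLE", "NIFTI_TYPE_INT32",
                    as.integer(t(mesh$faces)) - 1L,
                    c(nrow(mesh$faces), 3L))), path)
}

#' Write a binary vertex mask as a GIFTI label-style file
#'
#' @param mask Logical vertex mask.
#' @param path Output path (`.label.gii`).
#' @return `path`, invisibly.
#' @export
write_gifti_mask <- function(mask, path) {
  gifti_write_doc(gifti_array_xml("NIFTI_INTENT_LABEL", "NIFTI_TYPE_INT32",
                                  as.integer(as.logical(mask)), length(mask)),
                  path)
}

#' Read a GIFTI label-style mask file
#'
#' @param path `.label.gii` path.
#' @param expected_n Optional vertex count to validate against.
#' @return Logical vertex mask.
#' @export
read_gifti_mask <- function(path, expected_n = NULL) {
  vals <- read_gifti_map(path, expected_n)
  vals != 0
}
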