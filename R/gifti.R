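# Minimal GIFTI surface I/O (XML via xml2). Reads NIFTI_INTENT_POINTSET +
# NIFTI_INTENT_TRIANGLE arrays in ASCII, Base64Binary or GZipBase64Binary
# encoding (little-endian float32/int32); writes ASCII so files stay text.

#' Read a GIFTI surface file
#'
#' @param path a `.gii` surface file containing a POINTSET and a TRIANGLE
#'   data array.
#' @return a [surface_mesh()]; coordinates are converted from millimeters to
#'   meters (GIFTI surface convention is mm).
#' @export
read_gifti_surface <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("malformed GIFTI: ", conditionMessage(e)))
  arrays <- xml2::xml_find_all(doc, ".//DataArray")
  if (length(arrays) == 0) stop("malformed GIFTI: no DataArray elements")
  verts <- NULL; faces <- NULL
  for (a in arrays) {
    intent <- xml2::xml_attr(a, "Intent")
    vals <- gifti_decode(a)
    dim1 <- as.integer(xml2::xml_attr(a, "Dim0"))
    m <- matrix(vals, ncol = 3, byrow =
                  identical(xml2::xml_attr(a, "ArrayIndexingOrder"),
                            "RowMajorOrder"))
    if (!is.na(dim1) && nrow(m) != dim1)
      stop("malformed GIFTI: data length disagrees with Dim0")
    if (identical(intent, "NIFTI_INTENT_POINTSET")) verts <- m
    if (identical(intent, "NIFTI_INTENT_TRIANGLE")) faces <- m + 1L
  }
  if (is.null(verts) || is.null(faces))
    stop("malformed GIFTI: need POINTSET and TRIANGLE arrays")
  surface_mesh(verts / 1000, faces)
}

gifti_decode <- function(a) {
  enc <- xml2::xml_attr(a, "Encoding")
  dtype <- xml2::xml_attr(a, "DataType")
  node <- xml2::xml_find_first(a, ".//Data")
  txt <- xml2::xml_text(node)
  if (identical(enc, "ASCII")) {
    vals <- as.numeric(strsplit(trimws(txt), "\\s+")[[1]])
  } else {
    raw <- jsonlite::base64_dec(gsub("\\s", "", txt))
    if (identical(enc, "GZipBase64Binary")) raw <- memDecompress(raw, type = "gzip")
    vals <- switch(dtype,
      NIFTI_TYPE_FLOAT32 = readBin(raw, "double", n = length(raw) / 4,
                                   size = 4, endian = "little"),
      NIFTI_TYPE_INT32 = readBin(raw, "integer", n = length(raw) / 4,
                                 size = 4, endian = "little"),
      stop("unsupported GIFTI DataType: ", dtype))
  }
  if (anyNA(vals)) stop("malformed GIFTI: undecodable data")
  vals
}

#' Write a GIFTI surface file (ASCII encoding)
#'
#' @param mesh a [surface_mesh()] (meters; written in mm per GIFTI
#'   convention).
#' @param path output `.gii` path.
#' @export
write_gifti_surface <- function(mesh, path) {
  v <- mesh$vertices * 1000
  f <- mesh$faces - 1L
  vtxt <- paste(apply(v, 1, function(r) paste(sprintf("%.9g", r), collapse = " ")),
                collapse = "\n")
  ftxt <- paste(apply(f, 1, paste, collapse = " "), collapse = "\n")
  xml <- sprintf(
'<?xml version="1.0" encoding="UTF-8"?>
<GIFTI Version="1.0" NumberOfDataArrays="2">
<DataArray Intent="NIFTI_INTENT_POINTSET" DataType="NIFTI_TYPE_FLOAT32"
 ArrayIndexingOrder="RowMajorOrder" Dimensionality="2" Dim0="%d" Dim1="3"
 Encoding="ASCII" Endian="LittleEndian">
<Data>%s</Data>
</DataArray>
<DataArray Intent="NIFTI_INTENT_TRIANGLE" DataType="NIFTI_TYPE_INT32"
 ArrayIndexingOrder="RowMajorOrder" Dimensionality="2" Dim0="%d" Dim1="3"
 Encoding="ASCII" Endian="LittleEndian">
<Data>%s</Data>
</DataArray>
</GIFTI>', nrow(v), vtxt, nrow(f), ftxt)
  writeLines(xml, path)
  invisible(path)
}
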