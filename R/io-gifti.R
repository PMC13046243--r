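# Minimal GIFTI surface/metric/label I/O.
#
# The GIFTI container is XML; arrays are written here with ASCII encoding
# and read back from ASCII, Base64Binary or GZipBase64Binary encodings
# (little- or big-endian FLOAT32/FLOAT64/INT32), which covers files produced
# by the common surface toolchains. Triangle indices are 0-based on disk and
# 1-based in memory.

gifti_type_info <- function(type) {
  switch(type,
    NIFTI_TYPE_FLOAT32 = list(what = "double", size = 4L),
    NIFTI_TYPE_FLOAT64 = list(what = "double", size = 8L),
    NIFTI_TYPE_INT32 = list(what = "integer", size = 4L),
    NIFTI_TYPE_UINT8 = list(what = "integer", size = 1L),
    stop_format(sprintf("unsupported GIFTI DataType \"%s\"", type)))
}

decode_gifti_data <- function(node, n_values) {
  enc <- xml2::xml_attr(node, "Encoding")
  type <- xml2::xml_attr(node, "DataType")
  endian <- xml2::xml_attr(node, "Endian")
  txt <- xml2::xml_text(xml2::xml_find_first(node, "./Data"))
  if (is.na(txt)) stop_format("DataArray has no Data element")
  if (identical(enc, "ASCII")) {
    vals <- as.numeric(strsplit(trimws(txt), "\\s+")[[1]])
  } else if (enc %in% c("Base64Binary", "GZipBase64Binary")) {
    raw <- jsonlite::base64_dec(gsub("\\s", "", txt))
    if (enc == "GZipBase64Binary") raw <- memDecompress(raw, type = "gzip")
    info <- gifti_type_info(type)
    vals <- readBin(raw, what = info$what, n = n_values, size = info$size,
                    endian = if (identical(endian, "BigEndian")) "big" else "little")
  } else {
    stop_format(sprintf("unsupported GIFTI Encoding \"%s\"", enc))
  }
  if (length(vals) != n_values) {
    stop_format(sprintf("DataArray holds %d values, expected %d",
                        length(vals), n_values))
  }
  vals
}

gifti_array_matrix <- function(node) {
  dims <- as.integer(c(xml2::xml_attr(node, "Dim0"), xml2::xml_attr(node, "Dim1")))
  dims[is.na(dims)] <- 1L
  order <- xml2::xml_attr(node, "ArrayIndexingOrder")
  vals <- decode_gifti_data(node, prod(dims))
  if (identical(order, "ColumnMajorOrder")) {
    matrix(vals, nrow = dims[1], ncol = dims[2])
  } else {
    matrix(vals, nrow = dims[1], ncol = dims[2], byrow = TRUE)
  }
}

gifti_find_arrays <- function(path) {
  doc <- xml2::xml_ns_strip(xml2::read_xml(path))
  nodes <- xml2::xml_find_all(doc, ".//DataArray")
  if (length(nodes) == 0L) stop_format("no DataArray elements found")
  intents <- vapply(nodes, function(n) xml2::xml_attr(n, "Intent"), character(1))
  list(nodes = nodes, intents = intents)
}

#' Read a GIFTI surface file
#'
#' @param path Path to a `.surf.gii` file with POINTSET and TRIANGLE arrays.
#' @return A `laminar_mesh`.
#' @export
read_surface <- function(path) {
  arr <- gifti_find_arrays(path)
  ip <- which(arr$intents == "NIFTI_INTENT_POINTSET")
  it <- which(arr$intents == "NIFTI_INTENT_TRIANGLE")
  if (length(ip) == 0L) stop_format("surface file lacks a POINTSET array")
  if (length(it) == 0L) stop_format("surface file lacks a TRIANGLE (topology) array")
  verts <- gifti_array_matrix(arr$nodes[[ip[1]]])
  tris <- gifti_array_matrix(arr$nodes[[it[1]]]) + 1L
  surface_mesh(verts, tris)
}

gifti_skeleton <- function(n_arrays) {
  doc <- xml2::xml_new_root("GIFTI", Version = "1.0",
                            NumberOfDataArrays = as.character(n_arrays))
  doc
}

gifti_add_array <- function(doc, values, intent, type, dims) {
  da <- xml2::xml_add_child(doc, "DataArray",
    Intent = intent, DataType = type, ArrayIndexingOrder = "RowMajorOrder",
    Dimensionality = as.character(length(dims)), Encoding = "ASCII",
    Endian = "LittleEndian", ExternalFileName = "", ExternalFileOffset = "")
  for (i in seq_along(dims)) {
    xml2::xml_attr(da, paste0("Dim", i - 1L)) <- as.character(dims[i])
  }
  m <- matrix(values, nrow = dims[1])
  txt <- paste(apply(m, 1L, paste, collapse = " "), collapse = "\n")
  xml2::xml_add_child(da, "Data", txt)
  invisible(doc)
}

#' Write a GIFTI surface file
#'
#' @param mesh A `laminar_mesh`.
#' @param path Output path (conventionally `.surf.gii`).
#' @return `path`, invisibly.
#' @export
write_surface <- function(mesh, path) {
  doc <- gifti_skeleton(2L)
  gifti_add_array(doc, mesh$vertices, "NIFTI_INTENT_POINTSET",
                  "NIFTI_TYPE_FLOAT32", dim(mesh$vertices))
  gifti_add_array(doc, mesh$triangles - 1L, "NIFTI_INTENT_TRIANGLE",
                  "NIFTI_TYPE_INT32", dim(mesh$triangles))
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Read a GIFTI metric (functional) file
#'
#' @param path Path to a `.func.gii`/`.shape.gii` file.
#' @return Numeric matrix, vertices x maps.
#' @export
read_metric <- function(path) {
  arr <- gifti_find_arrays(path)
  keep <- which(!arr$intents %in% c("NIFTI_INTENT_POINTSET", "NIFTI_INTENT_TRIANGLE"))
  if (length(keep) == 0L) stop_format("no metric arrays found")
  do.call(cbind, lapply(arr$nodes[keep], gifti_array_matrix))
}

#' Write a GIFTI metric (functional) file
#'
#' @param values Numeric vector or matrix (vertices x maps).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_metric <- function(values, path) {
  values <- as.matrix(values)
  doc <- gifti_skeleton(ncol(values))
  for (j in seq_len(ncol(values))) {
    gifti_add_array(doc, values[, j], "NIFTI_INTENT_NONE",
                    "NIFTI_TYPE_FLOAT32", c(nrow(values), 1L))
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Write a GIFTI label file
#'
#' @param labels Integer per-vertex labels.
#' @param path Output path (conventionally `.label.gii`).
#' @return `path`, invisibly.
#' @export
write_labels <- function(labels, path) {
  labels <- as.integer(labels)
  doc <- gifti_skeleton(1L)
  lt <- xml2::xml_add_child(doc, "LabelTable")
  for (l in sort(unique(labels))) {
    xml2::xml_add_child(lt, "Label", Key = as.character(l),
                        paste0("parcel_", l))
  }
  gifti_add_array(doc, labels, "NIFTI_INTENT_LABEL", "NIFTI_TYPE_INT32",
                  c(length(labels), 1L))
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Read a GIFTI label file
#'
#' @param path Path to a `.label.gii` file.
#' @return Integer per-vertex labels.
#' @export
read_labels <- function(path) {
  arr <- gifti_find_arrays(path)
  il <- which(arr$intents == "NIFTI_INTENT_LABEL")
  if (length(il) == 0L) il <- seq_along(arr$intents)
  as.integer(gifti_array_matrix(arr$nodes[[il[1]]]))
}
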