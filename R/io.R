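#' Read a triangulated surface
#'
#' Supports FreeSurfer binary surfaces, GIFTI (`.surf.gii`), ASCII PLY and
#' OFF. With `format = "auto"` the format is detected from the file's magic
#' bytes before any parsing, so a wrong extension cannot be silently
#' misparsed. Coordinates are interpreted as millimetres.
#'
#' @param path file path.
#' @param format one of `"auto"`, `"freesurfer"`, `"gifti"`, `"ply"`, `"off"`.
#' @param name mesh label; defaults to the file name.
#' @return a [triangle_mesh()].
#' @export
read_surface <- function(path, format = c("auto", "freesurfer", "gifti", "ply", "off"),
                         name = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("surface file not found: ", path)
  if (format == "auto") format <- detect_surface_format(path)
  mesh <- switch(format,
    freesurfer = read_fs_surface(path),
    gifti = read_gifti_surface(path),
    ply = read_ply_surface(path),
    off = read_off_surface(path))
  mesh$name <- name %||% basename(path)
  validate_mesh(mesh)
  if (!is_oriented_mesh(mesh)) {
    de <- directed_edges(mesh)
    dup <- de[duplicated(paste(de[, 1L], de[, 2L])), , drop = FALSE]
    stop("non-manifold or inconsistently oriented surface in ", path,
         ": repeated directed edge(s) e.g. ",
         paste(dup[1L, ], collapse = "-"))
  }
  mesh
}

detect_surface_format <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", n = 8L)
  txt <- rawToChar(magic[magic != as.raw(0)][1:min(5, sum(magic != as.raw(0)))])
  if (length(magic) >= 3L && identical(as.integer(magic[1:3]), c(255L, 255L, 254L)))
    return("freesurfer")
  if (startsWith(txt, "ply")) return("ply")
  if (startsWith(txt, "OFF")) return("off")
  if (startsWith(txt, "<?xml") || startsWith(txt, "<GIFT")) return("gifti")
  stop("cannot detect surface format of ", path, " from magic bytes at offset 0: ",
       paste(sprintf("%02x", as.integer(magic)), collapse = " "))
}

#' Write a triangulated surface
#'
#' @param mesh a [triangle_mesh()].
#' @param path output path.
#' @param format one of `"freesurfer"`, `"gifti"`, `"ply"`, `"off"`, or
#'   `"auto"` to infer from the extension (`.ply`, `.off`, `.gii`, otherwise
#'   FreeSurfer binary).
#' @return invisibly, `path`.
#' @export
write_surface <- function(mesh, path, format = c("auto", "freesurfer", "gifti", "ply", "off")) {
  format <- match.arg(format)
  if (!inherits(mesh, "triangle_mesh")) stop("mesh must be a triangle_mesh")
  if (n_vertices(mesh) == 0L || n_faces(mesh) == 0L)
    stop("refusing to write an empty mesh (no vertices or faces)")
  validate_mesh(mesh)
  if (format == "auto") {
    ext <- tolower(sub(".*\\.", "", path))
    format <- switch(ext, ply = "ply", off = "off", gii = "gifti", "freesurfer")
  }
  switch(format,
    freesurfer = write_fs_surface(mesh, path),
    gifti = write_gifti_surface(mesh, path),
    ply = write_ply_surface(mesh, path),
    off = write_off_surface(mesh, path))
  invisible(path)
}

# ---- FreeSurfer binary surface (big-endian) --------------------------------

TRIANGLE_FILE_MAGIC <- c(255L, 255L, 254L)
CURV_FILE_MAGIC <- c(255L, 255L, 255L)

read_fs_surface <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- as.integer(readBin(con, "raw", n = 3L))
  if (!identical(magic, TRIANGLE_FILE_MAGIC))
    stop("not a FreeSurfer triangle surface (bad magic at byte 0): ", path)
  # comment: bytes up to and including "\n\n"
  prev <- as.raw(0)
  repeat {
    b <- readBin(con, "raw", n = 1L)
    if (length(b) == 0L) stop("truncated FreeSurfer surface header in ", path)
    if (b == as.raw(10) && prev == as.raw(10)) break
    prev <- b
  }
  nv <- readBin(con, "integer", n = 1L, size = 4L, endian = "big")
  nf <- readBin(con, "integer", n = 1L, size = 4L, endian = "big")
  v <- readBin(con, "numeric", n = 3L * nv, size = 4L, endian = "big")
  f <- readBin(con, "integer", n = 3L * nf, size = 4L, endian = "big")
  if (length(v) < 3L * nv || length(f) < 3L * nf)
    stop("truncated FreeSurfer surface data in ", path)
  triangle_mesh(matrix(v, nv, 3L, byrow = TRUE),
                matrix(f, nf, 3L, byrow = TRUE) + 1L,
                validate = FALSE)
}

write_fs_surface <- function(mesh, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(TRIANGLE_FILE_MAGIC), con)
  writeBin(charToRaw("created by cortimorph\n\n"), con)
  writeBin(as.integer(n_vertices(mesh)), con, size = 4L, endian = "big")
  writeBin(as.integer(n_faces(mesh)), con, size = 4L, endian = "big")
  writeBin(as.numeric(t(mesh$vertices)), con, size = 4L, endian = "big")
  writeBin(as.integer(t(mesh$faces) - 1L), con, size = 4L, endian = "big")
}

# ---- GIFTI -----------------------------------------------------------------

read_gifti_surface <- function(path) {
  doc <- xml2::read_xml(path)
  arrays <- xml2::xml_find_all(doc, ".//DataArray")
  if (length(arrays) == 0L) stop("no DataArray elements in GIFTI file ", path)
  pts <- NULL; tri <- NULL
  for (arr in arrays) {
    intent <- xml2::xml_attr(arr, "Intent")
    dat <- decode_gifti_array(arr, path)
    if (identical(intent, "NIFTI_INTENT_POINTSET")) pts <- dat
    if (identical(intent, "NIFTI_INTENT_TRIANGLE")) tri <- dat
  }
  if (is.null(pts) || is.null(tri))
    stop("GIFTI file ", path, " lacks a POINTSET and/or TRIANGLE array")
  triangle_mesh(pts, tri + 1L, validate = FALSE)
}

decode_gifti_array <- function(arr, path) {
  enc <- xml2::xml_attr(arr, "Encoding")
  dtype <- xml2::xml_attr(arr, "DataType")
  endian <- if (identical(xml2::xml_attr(arr, "Endian"), "BigEndian")) "big" else "little"
  ord <- xml2::xml_attr(arr, "ArrayIndexingOrder")
  d0 <- as.integer(xml2::xml_attr(arr, "Dim0"))
  d1 <- as.integer(xml2::xml_attr(arr, "Dim1"))
  if (is.na(d1)) d1 <- 1L
  n <- d0 * d1
  dnode <- xml2::xml_find_first(arr, ".//Data")
  txt <- xml2::xml_text(dnode)
  vals <- switch(enc,
    "ASCII" = as.numeric(strsplit(trimws(txt), "\\s+")[[1L]]),
    "Base64Binary" = ,
    "GZipBase64Binary" = {
      raw <- jsonlite::base64_dec(gsub("\\s", "", txt))
      if (enc == "GZipBase64Binary") raw <- memDecompress(raw, type = "gzip")
      if (startsWith(dtype, "NIFTI_TYPE_INT"))
        readBin(raw, "integer", n = n, size = 4L, endian = endian)
      else
        readBin(raw, "numeric", n = n, size = 4L, endian = endian)
    },
    stop("unsupported GIFTI encoding '", enc, "' in ", path))
  if (length(vals) != n)
    stop("GIFTI array in ", path, " has ", length(vals), " values, expected ", n)
  m <- if (identical(ord, "ColumnMajorOrder")) matrix(vals, d0, d1)
       else matrix(vals, d0, d1, byrow = TRUE)
  if (startsWith(dtype, "NIFTI_TYPE_INT")) storage.mode(m) <- "integer"
  m
}

write_gifti_surface <- function(mesh, path) {
  enc64 <- function(x, type) {
    raw <- writeBin(if (type == "int") as.integer(x) else as.numeric(x),
                    raw(), size = 4L, endian = "little")
    jsonlite::base64_enc(memCompress(raw, type = "gzip"))
  }
  v64 <- enc64(as.numeric(t(mesh$vertices)), "num")
  f64 <- enc64(as.integer(t(mesh$faces) - 1L), "int")
  xml <- paste0(
    '<?xml version="1.0" encoding="UTF-8"?>\n',
    '<GIFTI Version="1.0" NumberOfDataArrays="2">\n',
    '<DataArray Intent="NIFTI_INTENT_POINTSET" DataType="NIFTI_TYPE_FLOAT32" ',
    'ArrayIndexingOrder="RowMajorOrder" Dimensionality="2" Dim0="', n_vertices(mesh),
    '" Dim1="3" Encoding="GZipBase64Binary" Endian="LittleEndian">\n<Data>',
    v64, '</Data>\n</DataArray>\n',
    '<DataArray Intent="NIFTI_INTENT_TRIANGLE" DataType="NIFTI_TYPE_INT32" ',
    'ArrayIndexingOrder="RowMajorOrder" Dimensionality="2" Dim0="', n_faces(mesh),
    '" Dim1="3" Encoding="GZipBase64Binary" Endian="LittleEndian">\n<Data>',
    f64, '</Data>\n</DataArray>\n</GIFTI>\n')
  writeLines(xml, path, sep = "")
}

# ---- PLY (ascii) -----------------------------------------------------------

read_ply_surface <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!startsWith(lines[1L], "ply")) stop("not a PLY file (no 'ply' magic): ", path)
  hdr_end <- which(trimws(lines) == "end_header")[1L]
  if (is.na(hdr_end)) stop("PLY header without end_header in ", path)
  hdr <- lines[seq_len(hdr_end)]
  fmt <- grep("^format", hdr, value = TRUE)
  if (!grepl("ascii", fmt)) stop("only ascii PLY is supported; ", path, " is ", fmt)
  nv <- as.integer(sub(".*element vertex +", "", grep("element vertex", hdr, value = TRUE)))
  nf <- as.integer(sub(".*element face +", "", grep("element face", hdr, value = TRUE)))
  body <- lines[(hdr_end + 1L):length(lines)]
  vl <- body[seq_len(nv)]
  v <- matrix(as.numeric(unlist(strsplit(trimws(vl), "\\s+"))), nv, byrow = TRUE)[, 1:3, drop = FALSE]
  fl <- body[nv + seq_len(nf)]
  fparts <- strsplit(trimws(fl), "\\s+")
  f <- t(vapply(fparts, function(p) as.integer(p[2:4]), integer(3))) + 1L
  triangle_mesh(v, f, validate = FALSE)
}

write_ply_surface <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0", "comment created by cortimorph",
               paste("element vertex", n_vertices(mesh)),
               "property double x", "property double y", "property double z",
               paste("element face", n_faces(mesh)),
               "property list uchar int vertex_indices", "end_header"), con)
  writeLines(apply(mesh$vertices, 1L, function(r) paste(sprintf("%.10g", r), collapse = " ")), con)
  writeLines(paste(3L, mesh$faces[, 1L] - 1L, mesh$faces[, 2L] - 1L, mesh$faces[, 3L] - 1L), con)
}

# ---- OFF -------------------------------------------------------------------

read_off_surface <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (!startsWith(trimws(lines[1L]), "OFF")) stop("not an OFF file: ", path)
  counts <- as.integer(strsplit(trimws(lines[2L]), "\\s+")[[1L]])
  nv <- counts[1L]; nf <- counts[2L]
  v <- matrix(as.numeric(unlist(strsplit(trimws(lines[2L + seq_len(nv)]), "\\s+"))),
              nv, 3L, byrow = TRUE)
  fl <- strsplit(trimws(lines[2L + nv + seq_len(nf)]), "\\s+")
  f <- t(vapply(fl, function(p) as.integer(p[2:4]), integer(3))) + 1L
  triangle_mesh(v, f, validate = FALSE)
}

write_off_surface <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("OFF", con)
  writeLines(paste(n_vertices(mesh), n_faces(mesh), nrow(mesh_edges(mesh))), con)
  writeLines(apply(mesh$vertices, 1L, function(r) paste(sprintf("%.10g", r), collapse = " ")), con)
  writeLines(paste(3L, mesh$faces[, 1L] - 1L, mesh$faces[, 2L] - 1L, mesh$faces[, 3L] - 1L), con)
}

# ---- vertex fields ---------------------------------------------------------

#' Read a per-vertex scalar field
#'
#' Reads FreeSurfer "curv" (new binary format) or CSV with header
#' `vertex,value` where `vertex` is the 0-based vertex index in mesh order.
#' The record count must equal the mesh vertex count.
#'
#' @param path file path.
#' @param mesh the owning [triangle_mesh()].
#' @param format `"auto"`, `"curv"` or `"csv"`.
#' @param units unit label stored on the field.
#' @return a [vertex_field()].
#' @export
read_vertex_field <- function(path, mesh, format = c("auto", "curv", "csv"), units = "") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("vertex field file not found: ", path)
  if (format == "auto") {
    con <- file(path, "rb")
    magic <- as.integer(readBin(con, "raw", n = 3L))
    close(con)
    format <- if (identical(magic, CURV_FILE_MAGIC)) "curv" else "csv"
  }
  vals <- if (format == "curv") {
    con <- file(path, "rb")
    on.exit(close(con))
    magic <- as.integer(readBin(con, "raw", n = 3L))
    if (!identical(magic, CURV_FILE_MAGIC))
      stop("not a FreeSurfer curv file (bad magic at byte 0): ", path)
    nv <- readBin(con, "integer", n = 1L, size = 4L, endian = "big")
    readBin(con, "integer", n = 2L, size = 4L, endian = "big")  # nfaces, vals/vertex
    readBin(con, "numeric", n = nv, size = 4L, endian = "big")
  } else {
    d <- read.csv(path)
    if (!all(c("vertex", "value") %in% names(d)))
      stop("CSV vertex field must have columns 'vertex' and 'value': ", path)
    d$value[order(d$vertex)]
  }
  if (length(vals) != n_vertices(mesh))
    stop("vertex field in ", path, " has ", length(vals),
         " values but mesh '", mesh$name, "' has ", n_vertices(mesh), " vertices")
  vertex_field(vals, mesh, units = units)
}

#' Write a per-vertex scalar field
#'
#' @param field a [vertex_field()] (or numeric vector).
#' @param path output path.
#' @param mesh the owning mesh (needed for the curv header's face count).
#' @param format `"curv"` (FreeSurfer binary) or `"csv"` (`vertex,value`,
#'   0-based index).
#' @return invisibly, `path`.
#' @export
write_vertex_field <- function(field, path, mesh, format = c("csv", "curv")) {
  format <- match.arg(format)
  check_alignment(field, mesh)
  if (format == "curv") {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(as.raw(CURV_FILE_MAGIC), con)
    writeBin(as.integer(c(length(field), n_faces(mesh), 1L)), con, size = 4L, endian = "big")
    writeBin(as.numeric(field), con, size = 4L, endian = "big")
  } else {
    write.csv(data.frame(vertex = seq_along(field) - 1L,
                         value = as.numeric(field)),
              path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
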