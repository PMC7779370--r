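#' Read a triangulated surface mesh
#'
#' Supports ASCII OFF and ASCII PLY. Vertex coordinates are taken as mm.
#' Hemisphere labels are not part of either format; all vertices are labelled
#' `"left"` unless labels are supplied afterwards.
#'
#' @param path file path.
#' @param format `"off"`, `"ply"`, or `"auto"` (by extension).
#' @return A [cortical_mesh()].
#' @export
read_mesh <- function(path, format = c("auto", "off", "ply")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, off = "off", ply = "ply",
                     stop_invalid(sprintf("cannot infer mesh format from '%s'", path)))
  }
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  if (format == "off") read_off_lines(lines, path) else read_ply_lines(lines, path)
}

parse_fail <- function(path, line, msg)
  stop_invalid(sprintf("parse error in '%s' at line %d: %s", path, line, msg))

read_off_lines <- function(lines, path) {
  keep <- which(nzchar(lines) & !startsWith(lines, "#"))
  if (length(keep) < 2 || lines[keep[1]] != "OFF")
    parse_fail(path, 1, "missing OFF header")
  hdr <- as.numeric(strsplit(lines[keep[2]], "\\s+")[[1]])
  if (length(hdr) < 2 || anyNA(hdr)) parse_fail(path, keep[2], "bad count line")
  nv <- hdr[1]; nf <- hdr[2]
  body <- keep[-(1:2)]
  if (length(body) < nv + nf) parse_fail(path, length(lines), "truncated file")
  vtx <- t(vapply(lines[body[seq_len(nv)]],
                  function(s) as.numeric(strsplit(s, "\\s+")[[1]][1:3]),
                  numeric(3), USE.NAMES = FALSE))
  if (anyNA(vtx)) parse_fail(path, body[1], "bad vertex line")
  fl <- t(vapply(lines[body[nv + seq_len(nf)]],
                 function(s) as.numeric(strsplit(s, "\\s+")[[1]][1:4]),
                 numeric(4), USE.NAMES = FALSE))
  if (anyNA(fl) || any(fl[, 1] != 3)) parse_fail(path, body[nv + 1], "non-triangular face")
  cortical_mesh(vtx, fl[, 2:4] + 1L)
}

read_ply_lines <- function(lines, path) {
  if (length(lines) == 0 || lines[1] != "ply") parse_fail(path, 1, "missing ply header")
  endh <- match("end_header", lines)
  if (is.na(endh)) parse_fail(path, length(lines), "missing end_header")
  hdr <- lines[seq_len(endh)]
  if (!any(grepl("^format ascii", hdr)))
    parse_fail(path, 2, "only ascii PLY is supported")
  getcount <- function(el) {
    ln <- grep(paste0("^element ", el, " "), hdr, value = TRUE)
    if (length(ln) != 1) parse_fail(path, 1, paste("missing element", el))
    as.integer(strsplit(ln, "\\s+")[[1]][3])
  }
  nv <- getcount("vertex"); nf <- getcount("face")
  body <- lines[(endh + 1):length(lines)]
  body <- body[nzchar(body)]
  if (length(body) < nv + nf) parse_fail(path, length(lines), "truncated file")
  vtx <- t(vapply(body[seq_len(nv)],
                  function(s) as.numeric(strsplit(s, "\\s+")[[1]][1:3]),
                  numeric(3), USE.NAMES = FALSE))
  if (anyNA(vtx)) parse_fail(path, endh + 1, "bad vertex line")
  fl <- t(vapply(body[nv + seq_len(nf)],
                 function(s) as.numeric(strsplit(s, "\\s+")[[1]][1:4]),
                 numeric(4), USE.NAMES = FALSE))
  if (anyNA(fl) || any(fl[, 1] != 3)) parse_fail(path, endh + nv + 1, "non-triangular face")
  cortical_mesh(vtx, fl[, 2:4] + 1L)
}

#' Write a mesh to OFF or PLY (ASCII)
#'
#' @param mesh a [cortical_mesh()].
#' @param path output path.
#' @param format `"off"`, `"ply"`, or `"auto"` (by extension).
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, format = c("auto", "off", "ply")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- switch(tolower(tools::file_ext(path)), off = "off", ply = "ply",
                     stop_invalid("cannot infer mesh format from path"))
  v <- apply(mesh$vertices, 1, function(r) paste(formatC(r, format = "g", digits = 17),
                                                 collapse = " "))
  f <- apply(mesh$triangles - 1L, 1, function(r) paste(c(3L, r), collapse = " "))
  if (format == "off") {
    writeLines(c("OFF", paste(mesh$m, nrow(mesh$triangles), 0), v, f), path)
  } else {
    hdr <- c("ply", "format ascii 1.0",
             paste("element vertex", mesh$m),
             "property double x", "property double y", "property double z",
             paste("element face", nrow(mesh$triangles)),
             "property list uchar int vertex_indices", "end_header")
    writeLines(c(hdr, v, f), path)
  }
  invisible(path)
}

#' Read tractography streamlines
#'
#' Plain text: one `x y z` point per line, tracks separated by blank lines.
#' TCK: the MRtrix binary track format (Float32LE), tracks separated by NaN
#' triplets. TRK is not supported.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"text"`, or `"tck"`.
#' @return A [streamline_set()].
#' @export
read_streamlines <- function(path, format = c("auto", "text", "tck")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, tck = "tck", trk = stop_invalid("TRK is not supported; convert to TCK or plain text"),
                     "text")
  }
  if (format == "text") read_streamlines_text(path) else read_streamlines_tck(path)
}

read_streamlines_text <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  grp <- cumsum(!nzchar(lines))
  keep <- nzchar(lines)
  if (!any(keep)) return(streamline_set(list()))
  tracks <- lapply(split(lines[keep], grp[keep]), function(ls) {
    pts <- t(vapply(ls, function(s) {
      xs <- as.numeric(strsplit(s, "\\s+")[[1]])
      if (length(xs) != 3 || anyNA(xs))
        stop_invalid(sprintf("parse error in '%s': expected 'x y z', got '%s'", path, s))
      xs
    }, numeric(3), USE.NAMES = FALSE))
    pts
  })
  streamline_set(unname(tracks))
}

read_streamlines_tck <- function(path) {
  bytes <- readBin(path, "raw", n = file.size(path))
  # ASCII header terminated by "END\n"
  pat <- charToRaw("END\n")
  limit <- min(length(bytes) - length(pat) + 1L, 8192L)
  hdr_end <- NA_integer_
  for (i in seq_len(limit)) {
    if (bytes[i] == pat[1] && all(bytes[i:(i + 3L)] == pat)) { hdr_end <- i + 3L; break }
  }
  if (is.na(hdr_end)) stop_invalid(sprintf("'%s': no TCK header terminator found", path))
  hdr <- strsplit(rawToChar(bytes[seq_len(hdr_end)]), "\n")[[1]]
  if (length(hdr) == 0 || hdr[1] != "mrtrix tracks")
    stop_invalid(sprintf("'%s' is not a TCK file", path))
  dt <- sub("^datatype: *", "", grep("^datatype:", hdr, value = TRUE))
  if (length(dt) && dt[1] != "Float32LE")
    stop_invalid("only Float32LE TCK files are supported")
  off <- as.integer(sub("^file: *\\. *", "", grep("^file:", hdr, value = TRUE)[1]))
  vals <- readBin(bytes[(off + 1L):length(bytes)], "numeric",
                  n = (length(bytes) - off) / 4, size = 4, endian = "little")
  pts <- matrix(vals, ncol = 3, byrow = TRUE)
  brk <- which(!is.finite(pts[, 1]) & !is.finite(pts[, 2]) & !is.finite(pts[, 3]))
  starts <- c(1, head(brk, -1) + 1)
  ends <- brk - 1
  ok <- ends >= starts
  tracks <- Map(function(s, e) pts[s:e, , drop = FALSE], starts[ok], ends[ok])
  streamline_set(unname(tracks))
}

#' Write streamlines to plain text or TCK
#'
#' @param streamlines a [streamline_set()].
#' @param path output path.
#' @param format `"auto"` (by extension), `"text"`, or `"tck"`.
#' @return `path`, invisibly.
#' @export
write_streamlines <- function(streamlines, path, format = c("auto", "text", "tck")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (tolower(tools::file_ext(path)) == "tck") "tck" else "text"
  if (format == "text") {
    blocks <- vapply(streamlines$tracks, function(p)
      paste(apply(p, 1, function(r) paste(formatC(r, format = "g", digits = 17),
                                          collapse = " ")), collapse = "\n"),
      character(1))
    writeLines(paste(blocks, collapse = "\n\n"), path)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    mk_hdr <- function(off) paste0(paste(c(
      "mrtrix tracks", "datatype: Float32LE",
      sprintf("count: %d", length(streamlines$tracks)),
      sprintf("file: . %d", off), "END"), collapse = "\n"), "\n")
    off <- nchar(mk_hdr(0))
    while (nchar(mk_hdr(off)) != off) off <- nchar(mk_hdr(off))
    writeChar(mk_hdr(off), con, eos = NULL)
    for (p in streamlines$tracks) {
      writeBin(as.numeric(t(p)), con, size = 4, endian = "little")
      writeBin(rep(NaN, 3), con, size = 4, endian = "little")
    }
    writeBin(rep(Inf, 3), con, size = 4, endian = "little")
  }
  invisible(path)
}

#' Sparse matrix round-trip in Matrix Market coordinate format
#'
#' Thin wrappers over `Matrix::writeMM` / `Matrix::readMM`; symmetric-flagged
#' files are expanded to full symmetric matrices on read.
#'
#' @param A sparse matrix.
#' @param path file path (conventionally `.mtx`).
#' @return `write_sparse_matrix` returns `path` invisibly;
#'   `read_sparse_matrix` returns a `CsparseMatrix`.
#' @export
write_sparse_matrix <- function(A, path) {
  Matrix::writeMM(methods::as(methods::as(A, "generalMatrix"), "TsparseMatrix"), path)
  invisible(path)
}

#' @rdname write_sparse_matrix
#' @export
read_sparse_matrix <- function(path) {
  methods::as(methods::as(Matrix::readMM(path), "generalMatrix"), "CsparseMatrix")
}

#' Two-column vertex label table I/O
#'
#' Text interchange for per-vertex integer or string labels (hemisphere,
#' parcellation regions): `vertex_index label` per line, 1-based indices.
#'
#' @param labels vector of per-vertex labels.
#' @param path file path.
#' @return `write_vertex_labels` returns `path` invisibly;
#'   `read_vertex_labels` the label vector ordered by vertex.
#' @export
write_vertex_labels <- function(labels, path) {
  utils::write.table(data.frame(vertex = seq_along(labels), label = labels),
                     path, row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_vertex_labels
#' @export
read_vertex_labels <- function(path) {
  tab <- utils::read.table(path, header = FALSE,
                           col.names = c("vertex", "label"),
                           colClasses = c("integer", "character"))
  out <- character(max(tab$vertex))
  out[tab$vertex] <- tab$label
  num <- suppressWarnings(as.numeric(out))
  if (!anyNA(num)) num else out
}
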