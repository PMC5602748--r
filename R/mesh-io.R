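#' Read a triangle surface mesh
#'
#' Supports the OFF dialect ("OFF" header, counts line, vertex lines, "3 i j k"
#' face lines, 0-based indices) and the FreeSurfer ASCII surface dialect
#' (comment line, "V F" counts line, vertex lines with a trailing 0, face
#' lines with a trailing 0, 0-based indices).
#'
#' @param path file path
#' @param format `"off"` or `"freesurfer_ascii"`
#' @return an [sd_mesh()]
#' @export
read_surface <- function(path, format = c("off", "freesurfer_ascii")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (format == "off") {
    if (!length(lines) || toupper(trimws(lines[1])) != "OFF")
      stop(sprintf("%s: line 1: malformed OFF header", path))
    counts <- suppressWarnings(as.integer(strsplit(trimws(lines[2]), "\\s+")[[1]]))
    if (length(counts) < 2 || anyNA(counts[1:2]))
      stop(sprintf("%s: line 2: malformed counts line", path))
    nv <- counts[1]; nf <- counts[2]
    body <- 3L
  } else {
    start <- 1L
    while (start <= length(lines) && startsWith(trimws(lines[start]), "#")) start <- start + 1L
    counts <- suppressWarnings(as.integer(strsplit(trimws(lines[start]), "\\s+")[[1]]))
    if (length(counts) < 2 || anyNA(counts[1:2]))
      stop(sprintf("%s: line %d: malformed counts line", path, start))
    nv <- counts[1]; nf <- counts[2]
    body <- start + 1L
  }
  if (length(lines) < body + nv + nf - 1L)
    stop(sprintf("%s: truncated file: %d vertices + %d faces declared", path, nv, nf))
  vl <- lines[body:(body + nv - 1L)]
  fl <- if (nf > 0) lines[(body + nv):(body + nv + nf - 1L)] else character(0)
  vv <- matrix(suppressWarnings(as.numeric(unlist(strsplit(trimws(vl), "\\s+")))),
               nrow = nv, byrow = TRUE)
  if (anyNA(vv[, 1:3])) {
    bad <- which(apply(is.na(vv[, 1:3, drop = FALSE]), 1, any))[1]
    stop(sprintf("%s: line %d: non-numeric vertex coordinates", path, body + bad - 1L))
  }
  ff <- if (nf > 0) {
    matrix(suppressWarnings(as.numeric(unlist(strsplit(trimws(fl), "\\s+")))),
           nrow = nf, byrow = TRUE)
  } else matrix(numeric(0), 0, 4)
  if (format == "off") {
    if (nf > 0 && any(ff[, 1] != 3))
      stop(sprintf("%s: line %d: only triangular faces supported",
                   path, body + nv + which(ff[, 1] != 3)[1] - 1L))
    faces <- ff[, 2:4, drop = FALSE]
  } else {
    faces <- ff[, 1:3, drop = FALSE]
  }
  if (nf > 0 && (anyNA(faces) || any(faces < 0) || any(faces >= nv))) {
    bad <- which(apply(faces, 1, function(r) anyNA(r) || any(r < 0) || any(r >= nv)))[1]
    stop(sprintf("%s: line %d: face index out of range 0..%d",
                 path, body + nv + bad - 1L, nv - 1L))
  }
  sd_mesh(vv[, 1:3, drop = FALSE], faces + 1)
}

#' Write a triangle surface mesh
#'
#' Round trip contract: `read_surface(write_surface(m))` reproduces vertex
#' coordinates within 1e-6 mm and identical faces. The PLY writer carries the
#' mesh's per-vertex scalar channel as a `quality` property (used for heatmap
#' export).
#'
#' @param mesh an [sd_mesh()]
#' @param path output file path
#' @param format `"off"`, `"freesurfer_ascii"` or `"ply"`
#' @return the path, invisibly
#' @export
write_surface <- function(mesh, path, format = c("off", "freesurfer_ascii", "ply")) {
  format <- match.arg(format)
  if (nrow(mesh$vertices) == 0L) stop("empty mesh")
  v <- mesh$vertices; f <- mesh$faces - 1L
  fmt_v <- sprintf("%.9g %.9g %.9g", v[, 1], v[, 2], v[, 3])
  con <- file(path, "w")
  on.exit(close(con))
  if (format == "off") {
    writeLines(c("OFF", sprintf("%d %d 0", nrow(v), nrow(f)),
                 fmt_v, sprintf("3 %d %d %d", f[, 1], f[, 2], f[, 3])), con)
  } else if (format == "freesurfer_ascii") {
    writeLines(c("#!ascii surface", sprintf("%d %d", nrow(v), nrow(f)),
                 paste(fmt_v, "0"), sprintf("%d %d %d 0", f[, 1], f[, 2], f[, 3])), con)
  } else {
    has_scalar <- !is.null(mesh$scalar)
    header <- c("ply", "format ascii 1.0",
                sprintf("element vertex %d", nrow(v)),
                "property float x", "property float y", "property float z",
                if (has_scalar) "property float quality",
                sprintf("element face %d", nrow(f)),
                "property list uchar int vertex_indices", "end_header")
    body_v <- if (has_scalar) paste(fmt_v, sprintf("%.9g", mesh$scalar)) else fmt_v
    writeLines(c(header, body_v, sprintf("3 %d %d %d", f[, 1], f[, 2], f[, 3])), con)
  }
  invisible(path)
}
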