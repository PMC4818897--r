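# STL (ASCII and binary) and PLY surface I/O. STL carries no unit metadata;
# coordinates are taken as millimetres as exported by CT segmentation tools.

#' Read an STL surface (binary or ASCII)
#'
#' The dialect is sniffed from the header. Duplicated per-facet corner
#' vertices are welded (tolerance 1e-6 mm), preserving the face count.
#'
#' @param path file path.
#' @param units_scale multiplier applied to all coordinates (STL has no unit
#'   metadata; CT exports are mm by convention, so the default is 1).
#' @return a [trimesh()].
#' @export
read_stl <- function(path, units_scale = 1.0) {
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path), "elbow4d_file_error")
  }
  size <- file.info(path)$size
  if (is.na(size) || size == 0) {
    abort(sprintf("empty STL file: %s", path), "elbow4d_empty_mesh_error")
  }
  head_raw <- readBin(path, "raw", n = min(size, 4096))
  head_txt <- tryCatch(rawToChar(head_raw[head_raw != as.raw(0)]),
                       error = function(e) "")
  is_ascii <- grepl("^\\s*solid", head_txt, useBytes = TRUE) &&
    grepl("facet", head_txt, fixed = TRUE, useBytes = TRUE)
  mesh <- if (is_ascii) read_stl_ascii(path) else read_stl_binary(path)
  if (units_scale != 1.0) mesh$vertices <- mesh$vertices * units_scale
  weld_vertices(mesh)
}

read_stl_ascii <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  vlines <- lines[startsWith(lines, "vertex")]
  if (length(vlines) == 0L || length(vlines) %% 3L != 0L) {
    abort(sprintf("truncated or malformed ASCII STL: %s", path),
          "elbow4d_format_error")
  }
  nums <- suppressWarnings(
    as.numeric(unlist(strsplit(sub("^vertex\\s+", "", vlines), "\\s+")))
  )
  if (anyNA(nums) || length(nums) != 3L * length(vlines)) {
    abort(sprintf("malformed vertex line in ASCII STL: %s", path),
          "elbow4d_format_error")
  }
  vertices <- matrix(nums, ncol = 3L, byrow = TRUE)
  n_tri <- nrow(vertices) / 3L
  faces <- matrix(seq_len(3L * n_tri), ncol = 3L, byrow = TRUE)
  name <- sub("^solid\\s*", "", lines[1])
  trimesh(vertices, faces, name = name)
}

read_stl_binary <- function(path) {
  size <- file.info(path)$size
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", n = 80L) # header
  n_tri <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
  if (length(n_tri) == 0L || n_tri <= 0L) {
    abort(sprintf("binary STL with zero triangles: %s", path),
          "elbow4d_empty_mesh_error")
  }
  if (size < 84 + 50 * as.numeric(n_tri)) {
    abort(sprintf("truncated binary STL: %s", path), "elbow4d_format_error")
  }
  body <- readBin(con, "raw", n = 50L * n_tri)
  # each 50-byte record: normal (3 floats), 3 vertices (9 floats), 2 attr bytes
  stride <- 50L
  float_idx <- as.vector(outer(1:48, seq(0L, stride * (n_tri - 1L), stride), "+"))
  floats <- readBin(body[float_idx], "numeric", size = 4L, n = 12L * n_tri,
                    endian = "little")
  rec <- matrix(floats, ncol = 12L, byrow = TRUE)
  vertices <- matrix(t(rec[, 4:12, drop = FALSE]), ncol = 3L, byrow = TRUE)
  faces <- matrix(seq_len(3L * n_tri), ncol = 3L, byrow = TRUE)
  trimesh(vertices, faces, name = "")
}

#' Write an STL surface
#'
#' @param mesh a [trimesh()].
#' @param path output file path.
#' @param binary write the 50-byte-record binary dialect (default ASCII,
#'   which is diff- and archive-friendly).
#' @return `path`, invisibly.
#' @export
write_stl <- function(mesh, path, binary = FALSE) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  e1 <- b - a
  e2 <- c_ - a
  n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  len <- sqrt(rowSums(n^2))
  len[len == 0] <- 1
  n <- n / len
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(c(charToRaw(sprintf("%-80s", "elbow4d binary STL"))[1:80]), con)
    writeBin(as.integer(nrow(f)), con, size = 4L, endian = "little")
    rec <- cbind(n, a, b, c_)
    for (i in seq_len(nrow(f))) {
      writeBin(as.numeric(rec[i, ]), con, size = 4L, endian = "little")
      writeBin(as.raw(c(0, 0)), con)
    }
  } else {
    name <- if (nzchar(mesh$name)) mesh$name else "mesh"
    fmt <- function(p) sprintf("      vertex %.9g %.9g %.9g", p[1], p[2], p[3])
    blocks <- vapply(seq_len(nrow(f)), function(i) {
      paste(sprintf("  facet normal %.9g %.9g %.9g", n[i, 1], n[i, 2], n[i, 3]),
            "    outer loop",
            fmt(a[i, ]), fmt(b[i, ]), fmt(c_[i, ]),
            "    endloop", "  endfacet", sep = "\n")
    }, character(1))
    writeLines(c(paste("solid", name), blocks, paste("endsolid", name)), path)
  }
  invisible(path)
}

#' Write a PLY surface with optional per-face color
#'
#' ASCII PLY with 8-bit RGB per face; used to flag impinging faces in red
#' for surgical review.
#'
#' @param mesh a [trimesh()].
#' @param path output file path.
#' @param face_color `NULL`, a single RGB triple (0-255), or an m x 3 matrix
#'   with one row per face.
#' @return `path`, invisibly.
#' @export
write_ply <- function(mesh, path, face_color = NULL) {
  v <- mesh$vertices
  f <- mesh$faces - 1L
  has_color <- !is.null(face_color)
  if (has_color) {
    if (is.null(dim(face_color))) {
      face_color <- matrix(face_color, nrow = nrow(f), ncol = 3L, byrow = TRUE)
    }
    if (nrow(face_color) != nrow(f)) {
      abort("'face_color' must have one row per face", "elbow4d_argument_error")
    }
    face_color <- round(face_color)
  }
  header <- c(
    "ply", "format ascii 1.0",
    sprintf("comment %s", if (nzchar(mesh$name)) mesh$name else "elbow4d mesh"),
    sprintf("element vertex %d", nrow(v)),
    "property float x", "property float y", "property float z",
    sprintf("element face %d", nrow(f)),
    "property list uchar int vertex_indices",
    if (has_color) c("property uchar red", "property uchar green",
                     "property uchar blue"),
    "end_header"
  )
  vlines <- sprintf("%.9g %.9g %.9g", v[, 1], v[, 2], v[, 3])
  flines <- if (has_color) {
    sprintf("3 %d %d %d %d %d %d", f[, 1], f[, 2], f[, 3],
            face_color[, 1], face_color[, 2], face_color[, 3])
  } else {
    sprintf("3 %d %d %d", f[, 1], f[, 2], f[, 3])
  }
  writeLines(c(header, vlines, flines), path)
  invisible(path)
}
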