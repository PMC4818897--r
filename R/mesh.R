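# Triangle-mesh data model and geometric predicates. All coordinates are in
# millimetres (the CT-export convention); faces wind counter-clockwise seen
# from outside, so the divergence-theorem volume of a watertight mesh is
# positive.

#' Construct a triangle mesh
#'
#' @param vertices numeric n x 3 matrix of vertex coordinates (mm).
#' @param faces integer m x 3 matrix of 1-based vertex indices, wound
#'   counter-clockwise when viewed from outside the solid.
#' @param name optional free-text label.
#' @param validate drop degenerate (zero-area) faces and check index bounds.
#' @return An object of class `trimesh`.
#' @export
trimesh <- function(vertices, faces, name = "", validate = TRUE) {
  vertices <- as_point_matrix(vertices, "vertices")
  faces <- as.matrix(faces)
  if (ncol(faces) != 3L) {
    abort("'faces' must have 3 columns of vertex indices", "elbow4d_argument_error")
  }
  storage.mode(faces) <- "integer"
  if (nrow(faces) == 0L) {
    abort("mesh has zero triangles", "elbow4d_empty_mesh_error")
  }
  if (validate) {
    if (min(faces) < 1L || max(faces) > nrow(vertices)) {
      abort("face indices out of range", "elbow4d_format_error")
    }
    a <- vertices[faces[, 1], , drop = FALSE]
    e1 <- vertices[faces[, 2], , drop = FALSE] - a
    e2 <- vertices[faces[, 3], , drop = FALSE] - a
    cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
                e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
                e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
    area2 <- sqrt(rowSums(cr^2))
    scale <- pmax(rowSums(e1^2), rowSums(e2^2), .Machine$double.eps)
    keep <- area2 > 1e-12 * scale
    faces <- faces[keep, , drop = FALSE]
    if (nrow(faces) == 0L) {
      abort("mesh has zero non-degenerate triangles", "elbow4d_empty_mesh_error")
    }
  }
  structure(list(vertices = vertices, faces = faces, name = as.character(name)),
            class = "trimesh")
}

#' @export
print.trimesh <- function(x, ...) {
  wt <- tryCatch(is_watertight(x), error = function(e) NA)
  cat(sprintf("<trimesh%s: %d vertices, %d faces, watertight: %s>\n",
              if (nzchar(x$name)) paste0(" '", x$name, "'") else "",
              nrow(x$vertices), nrow(x$faces), wt))
  invisible(x)
}

#' Axis-aligned bounding box of a mesh
#' @param mesh a [trimesh()].
#' @return list with `min` and `max` 3-vectors (mm).
#' @export
mesh_bbox <- function(mesh) {
  list(min = apply(mesh$vertices, 2, min), max = apply(mesh$vertices, 2, max))
}

#' Merge duplicated vertices
#'
#' Vertices closer than `tol` on every coordinate (by rounding to the `tol`
#' lattice) are merged and faces reindexed. The default 1e-6 mm is far below
#' any CT-derived feature size, so welding never moves the surface.
#'
#' @param mesh a [trimesh()].
#' @param tol weld tolerance in mm.
#' @return A welded `trimesh`.
#' @export
weld_vertices <- function(mesh, tol = 1e-6) {
  v <- mesh$vertices
  key <- paste(round(v[, 1] / tol), round(v[, 2] / tol), round(v[, 3] / tol))
  first <- !duplicated(key)
  map <- match(key, key[first])
  vertices <- v[first, , drop = FALSE]
  faces <- matrix(map[mesh$faces], ncol = 3L)
  trimesh(vertices, faces, name = mesh$name)
}

# Undirected edge table; a closed, consistently wound surface has every
# undirected edge shared by exactly two faces with opposite directions.
edge_audit <- function(mesh) {
  f <- mesh$faces
  from <- c(f[, 1], f[, 2], f[, 3])
  to <- c(f[, 2], f[, 3], f[, 1])
  und <- paste(pmin(from, to), pmax(from, to))
  cnt <- table(und)
  open_edges <- sum(cnt != 2L)
  dir_dup <- anyDuplicated(paste(from, to)) > 0L
  list(open_edges = open_edges, consistent = !dir_dup)
}

#' Is a mesh watertight?
#'
#' @param mesh a [trimesh()].
#' @return `TRUE` iff every edge is shared by exactly two faces with
#'   consistent winding. The count of offending edges is attached as
#'   attribute `open_edges`.
#' @export
is_watertight <- function(mesh) {
  audit <- edge_audit(mesh)
  ok <- audit$open_edges == 0L && audit$consistent
  structure(ok, open_edges = audit$open_edges)
}

require_watertight <- function(mesh, what = "mesh") {
  wt <- is_watertight(mesh)
  if (!wt) {
    abort(sprintf("%s is not watertight (%d open/non-manifold edges)",
                  what, attr(wt, "open_edges")),
          "elbow4d_precondition_error")
  }
  invisible(mesh)
}

#' Enclosed volume of a watertight mesh
#'
#' Signed volume by the divergence theorem over faces; the absolute value is
#' returned with the detected orientation ("outward" for positive signed
#' volume) attached as attribute `orientation`.
#'
#' @param mesh a watertight [trimesh()].
#' @return volume in mm^3 with attribute `orientation`.
#' @export
mesh_volume <- function(mesh) {
  require_watertight(mesh)
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  det6 <- a[, 1] * (b[, 2] * c_[, 3] - b[, 3] * c_[, 2]) -
    a[, 2] * (b[, 1] * c_[, 3] - b[, 3] * c_[, 1]) +
    a[, 3] * (b[, 1] * c_[, 2] - b[, 2] * c_[, 1])
  signed <- sum(det6) / 6
  structure(abs(signed),
            orientation = if (signed >= 0) "outward" else "inward")
}

#' Test points for containment in a watertight mesh
#'
#' Parity ray casting along a fixed jittered direction; points on the surface
#' (within 1e-9 of the bbox diagonal) are classified inside.
#'
#' @param mesh a watertight [trimesh()].
#' @param points n x 3 matrix (mm).
#' @return logical vector, `TRUE` for inside.
#' @export
points_in_mesh <- function(mesh, points) {
  require_watertight(mesh)
  if (is.null(points) || (is.matrix(points) && nrow(points) == 0L) ||
      (!is.matrix(points) && length(points) == 0L)) {
    return(logical(0))
  }
  points <- as_point_matrix(points)
  cpp_points_in_mesh(mesh$vertices, mesh$faces - 1L, points)
}

#' Voxelize a watertight mesh
#'
#' A cubic grid aligned to the mesh bounding-box minimum and padded by one
#' voxel on every side; a cell is occupied iff its center lies inside the
#' mesh, so the volume estimate is exactly `occupied * voxel_size^3`.
#'
#' @param mesh a watertight [trimesh()].
#' @param voxel_size cell edge length, mm.
#' @param max_cells resource guard on the total cell count.
#' @return An object of class `voxel_grid` with fields `origin`,
#'   `voxel_size`, `dim` and logical array `occupancy`.
#' @export
voxelize <- function(mesh, voxel_size, max_cells = 4e7) {
  if (!is.numeric(voxel_size) || length(voxel_size) != 1L || voxel_size <= 0) {
    abort("'voxel_size' must be a positive length in mm", "elbow4d_argument_error")
  }
  require_watertight(mesh)
  bb <- mesh_bbox(mesh)
  origin <- bb$min - voxel_size
  dims <- as.integer(ceiling((bb$max - origin) / voxel_size) + 1L)
  if (prod(as.numeric(dims)) > max_cells) {
    abort(sprintf(
      "voxel grid of %d x %d x %d cells exceeds the %g-cell budget; use a larger voxel_size",
      dims[1], dims[2], dims[3], max_cells), "elbow4d_resource_error")
  }
  occ <- cpp_voxel_occupancy(mesh$vertices, mesh$faces - 1L,
                             origin[1], origin[2], origin[3],
                             voxel_size, dims[1], dims[2], dims[3])
  dim(occ) <- dims
  structure(list(origin = origin, voxel_size = voxel_size, dim = dims,
                 occupancy = occ),
            class = "voxel_grid")
}

#' Volume estimate of a voxel grid
#' @param grid a [voxelize()] result.
#' @return occupied-cell count times the cell volume (mm^3).
#' @export
voxel_volume <- function(grid) {
  sum(grid$occupancy) * grid$voxel_size^3
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("<voxel_grid: %d x %d x %d at %g mm, %d occupied, %.3f mm^3>\n",
              x$dim[1], x$dim[2], x$dim[3], x$voxel_size,
              sum(x$occupancy), voxel_volume(x)))
  invisible(x)
}

# Concatenate meshes (disjoint components) into one surface.
merge_meshes <- function(..., name = "") {
  parts <- list(...)
  parts <- parts[!vapply(parts, is.null, logical(1))]
  vertices <- do.call(rbind, lapply(parts, function(m) m$vertices))
  offs <- cumsum(c(0L, vapply(parts, function(m) nrow(m$vertices), integer(1))))
  faces <- do.call(rbind, Map(function(m, o) m$faces + o, parts,
                              offs[seq_along(parts)]))
  trimesh(vertices, faces, name = name, validate = FALSE)
}
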