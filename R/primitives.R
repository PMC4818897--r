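# Watertight mesh primitives used by the phantom generator and the test
# oracles: axis-aligned box, capped cylinder (axis along x), icosphere.

#' Axis-aligned box mesh
#' @param min,max opposite corners (3-vectors, mm).
#' @param name label.
#' @return a watertight [trimesh()] with outward winding (12 triangles).
#' @export
mesh_box <- function(min = c(0, 0, 0), max = c(1, 1, 1), name = "box") {
  lo <- as.numeric(min); hi <- as.numeric(max)
  if (any(hi <= lo)) abort("box 'max' must exceed 'min'", "elbow4d_argument_error")
  v <- as.matrix(expand.grid(x = c(lo[1], hi[1]), y = c(lo[2], hi[2]),
                             z = c(lo[3], hi[3])))
  colnames(v) <- NULL
  # vertex order from expand.grid: index = 1 + (x==hi) + 2*(y==hi) + 4*(z==hi)
  quads <- rbind(
    c(1, 3, 4, 2),  # z = lo, normal -z
    c(5, 6, 8, 7),  # z = hi, normal +z
    c(1, 2, 6, 5),  # y = lo, normal -y
    c(3, 7, 8, 4),  # y = hi, normal +y
    c(1, 5, 7, 3),  # x = lo, normal -x
    c(2, 4, 8, 6)   # x = hi, normal +x
  )
  faces <- do.call(rbind, lapply(seq_len(nrow(quads)), function(i) {
    q <- quads[i, ]
    rbind(q[c(1, 2, 3)], q[c(1, 3, 4)])
  }))
  trimesh(v, faces, name = name)
}

#' Capped cylinder mesh with axis along x
#' @param radius cylinder radius (mm).
#' @param x0,x1 axial extent (mm), `x0 < x1`.
#' @param n_seg number of angular segments.
#' @param center 3-vector added to all vertices.
#' @param name label.
#' @return a watertight [trimesh()].
#' @export
mesh_cylinder <- function(radius, x0, x1, n_seg = 96, center = c(0, 0, 0),
                          name = "cylinder") {
  if (radius <= 0 || x1 <= x0 || n_seg < 3) {
    abort("invalid cylinder parameters", "elbow4d_argument_error")
  }
  ang <- 2 * pi * (seq_len(n_seg) - 1L) / n_seg
  ring0 <- cbind(x0, radius * cos(ang), radius * sin(ang))
  ring1 <- cbind(x1, radius * cos(ang), radius * sin(ang))
  v <- rbind(ring0, ring1, c(x0, 0, 0), c(x1, 0, 0))
  i0 <- seq_len(n_seg)
  i1 <- i0 + n_seg
  c0 <- 2L * n_seg + 1L
  c1 <- 2L * n_seg + 2L
  nx <- c(i0[-1], i0[1])   # next index around the ring
  n1 <- c(i1[-1], i1[1])
  side <- rbind(cbind(i0, n1, i1), cbind(i0, nx, n1))
  cap0 <- cbind(c0, nx, i0)            # x = x0 cap, normal -x
  cap1 <- cbind(c1, i1, n1)            # x = x1 cap, normal +x
  v <- sweep(v, 2, as.numeric(center), "+")
  trimesh(v, rbind(side, cap0, cap1), name = name)
}

#' Icosphere mesh
#'
#' Subdivided icosahedron with vertices projected to the sphere; faces lie
#' slightly inside the true sphere (sagitta ~ r(1-cos(e/2r)) for edge e).
#'
#' @param radius sphere radius (mm).
#' @param center 3-vector (mm).
#' @param subdivisions number of 4-to-1 face subdivisions (0 = icosahedron).
#' @param name label.
#' @return a watertight [trimesh()].
#' @export
mesh_icosphere <- function(radius = 1, center = c(0, 0, 0), subdivisions = 3,
                           name = "icosphere") {
  if (radius <= 0) abort("'radius' must be positive", "elbow4d_argument_error")
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c( phi, 0, -1), c( phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1)
  )
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2)
  )
  v <- v / sqrt(1 + phi^2)
  for (s in seq_len(subdivisions)) {
    edge_key <- function(i, j) paste(pmin(i, j), pmax(i, j))
    e1 <- edge_key(f[, 1], f[, 2])
    e2 <- edge_key(f[, 2], f[, 3])
    e3 <- edge_key(f[, 3], f[, 1])
    keys <- unique(c(e1, e2, e3))
    pair <- matrix(as.integer(unlist(strsplit(keys, " "))), ncol = 2, byrow = TRUE)
    mid <- (v[pair[, 1], , drop = FALSE] + v[pair[, 2], , drop = FALSE]) / 2
    mid <- mid / sqrt(rowSums(mid^2))
    m1 <- nrow(v) + match(e1, keys)
    m2 <- nrow(v) + match(e2, keys)
    m3 <- nrow(v) + match(e3, keys)
    v <- rbind(v, mid)
    f <- rbind(cbind(f[, 1], m1, m3), cbind(f[, 2], m2, m1),
               cbind(f[, 3], m3, m2), cbind(m1, m2, m3))
  }
  v <- v * radius
  v <- sweep(v, 2, as.numeric(center), "+")
  trimesh(v, f, name = name)
}
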