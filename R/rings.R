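# The two-rings hinge-axis method: a circle ("ring") is fitted through
# landmark points plotted on each of the two articular surfaces of the
# distal humerus (trochlea, capitellum); the flexion-extension axis is the
# line through the two ring centers.

#' Landmark set for the two-rings method
#'
#' @param trochlea n x 3 matrix (n >= 3) of points on the trochlea (mm).
#' @param capitellum n x 3 matrix (n >= 3) of points on the capitellum (mm).
#' @param source free label identifying observer/session.
#' @return object of class `landmark_set`.
#' @export
landmark_set <- function(trochlea, capitellum, source = "") {
  trochlea <- as_point_matrix(trochlea, "trochlea")
  capitellum <- as_point_matrix(capitellum, "capitellum")
  for (nm in c("trochlea", "capitellum")) {
    p <- if (nm == "trochlea") trochlea else capitellum
    if (nrow(p) < 3L) {
      abort(sprintf("degenerate landmarks: %s (need >= 3 points)", nm),
            "elbow4d_degenerate_landmarks_error", group = nm)
    }
    if (collinearity_area(p) <= collinearity_tol(p)) {
      abort(sprintf("degenerate landmarks: %s (points are collinear)", nm),
            "elbow4d_degenerate_landmarks_error", group = nm)
    }
  }
  structure(list(trochlea = trochlea, capitellum = capitellum,
                 source = as.character(source)),
            class = "landmark_set")
}

# Largest triangle area over the first three points (n = 3) or smallest
# singular-value criterion for n > 3; used only as a degeneracy check.
collinearity_area <- function(p) {
  if (nrow(p) == 3L) {
    0.5 * vnorm(cross3(p[2, ] - p[1, ], p[3, ] - p[1, ]))
  } else {
    ctr <- sweep(p, 2, colMeans(p))
    sv <- svd(ctr, nu = 0, nv = 0)$d
    sv[2]
  }
}

collinearity_tol <- function(p) {
  scale <- max(1, max(abs(sweep(p, 2, colMeans(p)))))
  1e-9 * scale^2
}

#' Circumscribed circle through three points in 3D
#'
#' The unique circle through three non-collinear points in their common
#' plane; the normal is oriented by the right-hand rule on (p1, p2, p3).
#'
#' @param p1,p2,p3 3-vectors (mm).
#' @return object of class `ring` with fields `center`, `radius`, `normal`.
#' @export
circumcircle3 <- function(p1, p2, p3) {
  p1 <- as.numeric(p1); p2 <- as.numeric(p2); p3 <- as.numeric(p3)
  e1 <- p2 - p1
  e2 <- p3 - p1
  n <- cross3(e1, e2)
  area <- 0.5 * vnorm(n)
  scale <- max(sum(e1 * e1), sum(e2 * e2), .Machine$double.eps)
  if (area <= 1e-12 * scale) {
    abort(sprintf("degenerate landmarks: collinear or coincident points (triangle area %.3g mm^2)",
                  area),
          "elbow4d_degenerate_landmarks_error", area = area)
  }
  # center = p1 + a*e1 + b*e2 with (c - p1).e1 = |e1|^2/2, (c - p1).e2 = |e2|^2/2
  g11 <- sum(e1 * e1); g12 <- sum(e1 * e2); g22 <- sum(e2 * e2)
  rhs <- c(g11 / 2, g22 / 2)
  det <- g11 * g22 - g12 * g12
  a <- (rhs[1] * g22 - rhs[2] * g12) / det
  b <- (g11 * rhs[2] - g12 * rhs[1]) / det
  center <- p1 + a * e1 + b * e2
  ring(center = center, radius = vnorm(center - p1), normal = unit(n))
}

ring <- function(center, radius, normal, rms_residual = 0) {
  structure(list(center = as.numeric(center), radius = as.numeric(radius),
                 normal = as.numeric(normal),
                 rms_residual = as.numeric(rms_residual)),
            class = "ring")
}

#' @export
print.ring <- function(x, ...) {
  cat(sprintf("<ring: center (%.3f, %.3f, %.3f) mm, radius %.3f mm, normal (%.3f, %.3f, %.3f)>\n",
              x$center[1], x$center[2], x$center[3], x$radius,
              x$normal[1], x$normal[2], x$normal[3]))
  invisible(x)
}

#' Fit a ring (3D circle) to three or more points
#'
#' With exactly three points this is [circumcircle3()]. With more, the
#' points are first reduced to their total-least-squares plane, then a
#' least-squares circle (Kasa fit) is solved in that plane; the root mean
#' square of radial + out-of-plane residuals is reported.
#'
#' @param points n x 3 matrix, n >= 3, non-collinear.
#' @return a `ring` with field `rms_residual` (mm).
#' @export
fit_ring <- function(points) {
  points <- as_point_matrix(points)
  if (nrow(points) < 3L) {
    abort("degenerate landmarks: need >= 3 points", "elbow4d_degenerate_landmarks_error")
  }
  if (nrow(points) == 3L) {
    return(circumcircle3(points[1, ], points[2, ], points[3, ]))
  }
  if (collinearity_area(points) <= collinearity_tol(points)) {
    abort("degenerate landmarks: points are collinear",
          "elbow4d_degenerate_landmarks_error")
  }
  ctr <- colMeans(points)
  q <- sweep(points, 2, ctr)
  sv <- svd(q)
  normal <- sv$v[, 3]
  # right-hand orientation from the first non-degenerate triple
  tri_n <- cross3(points[2, ] - points[1, ], points[3, ] - points[1, ])
  if (sum(tri_n * normal) < 0) normal <- -normal
  u <- sv$v[, 1]; w <- sv$v[, 2]
  x2 <- q %*% u
  y2 <- q %*% w
  # Kasa: minimize |x^2 + y^2 - 2ax - 2by - c|
  A <- cbind(2 * x2, 2 * y2, 1)
  rhs <- x2^2 + y2^2
  sol <- qr.solve(A, rhs)
  cx <- sol[1]; cy <- sol[2]
  radius <- sqrt(sol[3] + cx^2 + cy^2)
  center <- ctr + cx * u + cy * w
  radial <- sqrt((x2 - cx)^2 + (y2 - cy)^2) - radius
  offplane <- q %*% normal
  rms <- sqrt(mean(radial^2 + offplane^2))
  ring(center = center, radius = radius, normal = unit(normal),
       rms_residual = rms)
}

#' Hinge axis (point + unit direction)
#'
#' @param point 3-vector on the axis (mm).
#' @param direction 3-vector, normalized internally.
#' @param diagnostics optional named list (ring radii, inter-center distance,
#'   normal-vs-axis angles).
#' @return object of class `hinge_axis`.
#' @export
hinge_axis <- function(point, direction, diagnostics = list()) {
  structure(list(point = as.numeric(point), direction = unit(as.numeric(direction)),
                 diagnostics = diagnostics),
            class = "hinge_axis")
}

#' @export
print.hinge_axis <- function(x, ...) {
  cat(sprintf("<hinge_axis: point (%.3f, %.3f, %.3f) mm, direction (%.4f, %.4f, %.4f)>\n",
              x$point[1], x$point[2], x$point[3],
              x$direction[1], x$direction[2], x$direction[3]))
  if (length(x$diagnostics)) {
    d <- x$diagnostics
    cat(sprintf("  rings: radii %.3f / %.3f mm, centers %.3f mm apart, normal-axis angles %.3f / %.3f deg\n",
                d$trochlea_radius_mm, d$capitellum_radius_mm,
                d$inter_center_distance_mm,
                d$trochlea_normal_angle_deg, d$capitellum_normal_angle_deg))
  }
  invisible(x)
}

#' Two-rings flexion-extension axis
#'
#' Fits one ring per articular surface and draws the axis through the two
#' ring centers. The axis point is the trochlear ring center and the
#' direction points from the trochlea (medial) toward the capitellum
#' (lateral); flexion is a right-handed rotation about this direction (use
#' `flip = TRUE` for the contralateral side).
#'
#' @param landmarks a [landmark_set()].
#' @param flip reverse the axis direction (left vs right elbow convention).
#' @return a [hinge_axis()] with fit diagnostics.
#' @export
two_rings <- function(landmarks, flip = FALSE) {
  if (!inherits(landmarks, "landmark_set")) {
    landmarks <- landmark_set(landmarks$trochlea, landmarks$capitellum,
                              if (is.null(landmarks$source)) "" else landmarks$source)
  }
  rt <- fit_ring(landmarks$trochlea)
  rc <- fit_ring(landmarks$capitellum)
  sep <- rc$center - rt$center
  d <- vnorm(sep)
  if (d < 1) {
    abort(sprintf("unstable axis: ring centers only %.3f mm apart", d),
          "elbow4d_unstable_axis_error")
  }
  dir <- sep / d
  if (flip) dir <- -dir
  ang <- function(nrm) rad2deg(acos(pmin(1, abs(sum(unit(nrm) * dir)))))
  hinge_axis(
    point = rt$center, direction = dir,
    diagnostics = list(
      trochlea_radius_mm = rt$radius,
      capitellum_radius_mm = rc$radius,
      trochlea_rms_residual_mm = rt$rms_residual,
      capitellum_rms_residual_mm = rc$rms_residual,
      inter_center_distance_mm = d,
      trochlea_normal_angle_deg = ang(rt$normal),
      capitellum_normal_angle_deg = ang(rc$normal),
      source = landmarks$source
    )
  )
}

#' Angular and positional discrepancy between two hinge axes
#'
#' @param a,b [hinge_axis()] objects.
#' @return named numeric: `angle_deg` (orientation-agnostic, 0-90) and
#'   `distance_mm` (minimal distance between the two infinite lines).
#' @export
axis_error <- function(a, b) {
  d1 <- unit(a$direction); d2 <- unit(b$direction)
  angle <- rad2deg(acos(pmin(1, abs(sum(d1 * d2)))))
  w <- b$point - a$point
  cr <- cross3(d1, d2)
  ncr <- vnorm(cr)
  dist <- if (ncr < 1e-12) {
    vnorm(w - sum(w * d1) * d1)
  } else {
    abs(sum(w * cr)) / ncr
  }
  c(angle_deg = angle, distance_mm = dist)
}

#' Read a landmark JSON file
#'
#' Format: `{"trochlea": [[x,y,z],...], "capitellum": [[x,y,z],...],
#' "source": "observer1-session1"}`, coordinates in mm.
#'
#' @param path JSON file path.
#' @return a [landmark_set()].
#' @export
read_landmarks <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path), "elbow4d_file_error")
  }
  obj <- jsonlite::fromJSON(path)
  if (is.null(obj$trochlea) || is.null(obj$capitellum)) {
    abort(sprintf("landmark file must contain 'trochlea' and 'capitellum': %s", path),
          "elbow4d_format_error")
  }
  landmark_set(obj$trochlea, obj$capitellum,
               source = if (is.null(obj$source)) "" else obj$source)
}

#' Write a landmark JSON file
#' @param landmarks a [landmark_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_landmarks <- function(landmarks, path) {
  jsonlite::write_json(
    list(trochlea = unname(landmarks$trochlea),
         capitellum = unname(landmarks$capitellum),
         source = landmarks$source),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Write a hinge axis to JSON
#' @param axis a [hinge_axis()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_axis <- function(axis, path) {
  jsonlite::write_json(
    list(point = axis$point, direction = axis$direction,
         diagnostics = axis$diagnostics),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Read a hinge axis from JSON
#' @param path JSON path written by [write_axis()].
#' @return a [hinge_axis()].
#' @export
read_axis <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path), "elbow4d_file_error")
  }
  obj <- jsonlite::fromJSON(path)
  hinge_axis(obj$point, obj$direction,
             diagnostics = if (is.null(obj$diagnostics)) list() else obj$diagnostics)
}
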