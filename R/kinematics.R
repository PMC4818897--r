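# Rigid-body kinematics: the forearm (ulna + radius as one body) rotates
# about the fitted hinge axis; the humerus stays fixed. Every pose is built
# directly from the reference pose at its absolute flexion angle (never by
# chaining increments), so rotations cannot drift numerically.

#' Rigid transform (rotation + translation)
#' @param rotation 3 x 3 rotation matrix (orthonormal, det +1).
#' @param translation 3-vector (mm).
#' @return object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  if (!all(dim(rotation) == c(3L, 3L)) ||
      max(abs(crossprod(rotation) - diag(3))) > 1e-9 ||
      abs(det(rotation) - 1) > 1e-9) {
    abort("'rotation' must be orthonormal with determinant +1",
          "elbow4d_argument_error")
  }
  structure(list(rotation = rotation, translation = as.numeric(translation)),
            class = "rigid_transform")
}

#' Rotation about a hinge axis
#'
#' Axis-angle (Rodrigues) rotation by `angle_deg` about `axis$direction`
#' through `axis$point`; points on the axis are fixed.
#'
#' @param axis a [hinge_axis()].
#' @param angle_deg rotation angle in degrees (flexion positive,
#'   right-handed about the axis direction).
#' @return a [rigid_transform()].
#' @export
rotation_about_axis <- function(axis, angle_deg) {
  k <- unit(axis$direction)
  th <- deg2rad(angle_deg)
  K <- matrix(c(0, k[3], -k[2],
                -k[3], 0, k[1],
                k[2], -k[1], 0), 3, 3)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  p <- axis$point
  rigid_transform(rotation = R, translation = as.numeric(p - R %*% p))
}

#' Compose two rigid transforms (`a` applied after `b`)
#' @param a,b [rigid_transform()] objects.
#' @return a [rigid_transform()].
#' @export
compose_transforms <- function(a, b) {
  rigid_transform(rotation = a$rotation %*% b$rotation,
                  translation = as.numeric(a$rotation %*% b$translation) +
                    a$translation)
}

#' Apply a rigid transform to points or a mesh
#' @param transform a [rigid_transform()].
#' @param x an n x 3 point matrix, a 3-vector, or a [trimesh()].
#' @return the transformed object (topology of a mesh is untouched).
#' @export
apply_transform <- function(transform, x) {
  if (inherits(x, "trimesh")) {
    x$vertices <- apply_transform(transform, x$vertices)
    return(x)
  }
  p <- as_point_matrix(x, "x")
  out <- p %*% t(transform$rotation)
  out <- sweep(out, 2, transform$translation, "+")
  if (is.null(dim(x))) as.numeric(out) else out
}

#' Pose the forearm at a flexion angle
#'
#' The input mesh is taken to be in the scanned reference pose at flexion
#' `reference_angle_deg` (the patient's CT position, which must be supplied
#' from clinical measurement); the transform applied is the rotation by
#' `angle_deg - reference_angle_deg` about the axis.
#'
#' @param mesh forearm [trimesh()].
#' @param axis a [hinge_axis()].
#' @param angle_deg target flexion angle (degrees; extension deficit
#'   negative).
#' @param reference_angle_deg flexion angle of the mesh as given.
#' @return the posed [trimesh()].
#' @export
pose_forearm <- function(mesh, axis, angle_deg, reference_angle_deg = 0) {
  apply_transform(rotation_about_axis(axis, angle_deg - reference_angle_deg),
                  mesh)
}

#' Flexion-angle pose sequence
#'
#' Angles run from `start` to `stop` in steps of `step`; if the span is not
#' a multiple of `step` the final frame at `stop` is appended so both
#' endpoints are always simulated.
#'
#' @param axis a [hinge_axis()].
#' @param start,stop sweep limits (degrees, `start < stop`).
#' @param step positive increment (degrees).
#' @param reference_angle_deg flexion angle of the reference pose.
#' @return object of class `pose_sequence` with `angles` and a list of
#'   [rigid_transform()]s, one per angle, each built from the reference.
#' @export
pose_sequence <- function(axis, start, stop, step,
                          reference_angle_deg = 0) {
  if (!is.numeric(step) || step <= 0) {
    abort("'step' must be positive", "elbow4d_argument_error")
  }
  if (start >= stop) {
    abort("'start' must be below 'stop'", "elbow4d_argument_error")
  }
  angles <- seq(start, stop, by = step)
  if (utils::tail(angles, 1) < stop) angles <- c(angles, stop)
  transforms <- lapply(angles, function(a) {
    rotation_about_axis(axis, a - reference_angle_deg)
  })
  structure(list(axis = axis, angles = angles, transforms = transforms,
                 reference_angle_deg = reference_angle_deg),
            class = "pose_sequence")
}
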