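# Parametric hinge-joint phantom: an idealized "elbow" with an exactly known
# flexion-extension axis (the x-axis through the origin), articular rings,
# and optional osteophyte bosses whose first-contact flexion angle is solved
# in closed form. Shapes are idealized solids, not realistic anatomy: ground
# truth must be analytic.
#
# Geometry (axis = x-axis, angles measured so that station phi sits at
# direction u(phi) = (0, sin(phi), -cos(phi)); the forearm points at u(0),
# straight down, in the reference pose = full extension, 0 deg flexion):
#   humerus  = trochlea cylinder (radius r_t, |x| <= trochlea half-length)
#            + capitellum sphere (radius r_c at x = inter-center distance)
#            + shaft box above (+z)
#            + osteophyte bosses (spheres standing g mm off the trochlea)
#   forearm  = radial arm box whose near facet is the plane at distance
#              r_t + clearance from the axis.
# All components are pairwise disjoint closed surfaces, so parity point
# containment and divergence-theorem volumes are exact.

#' Phantom specification
#'
#' @param trochlea_radius trochlear ring radius (mm).
#' @param capitellum_radius capitellar ring radius (mm).
#' @param inter_center_distance distance between ring centers (mm).
#' @param shaft_length humeral-shaft and forearm lengths (mm).
#' @param clearance radial gap between trochlea surface and forearm near
#'   facet (mm); with no osteophytes the joint is contact-free at every
#'   angle of the designed arc (-10 to 140 degrees).
#' @param osteophytes list of osteophyte descriptors as returned by
#'   [osteophyte()] / [osteophyte_for_contact()].
#' @param mesh_resolution target facet edge length (mm) for the articular
#'   solids.
#' @param seed default RNG seed for [sample_landmarks()].
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(trochlea_radius = 10, capitellum_radius = 8,
                         inter_center_distance = 40, shaft_length = 60,
                         clearance = 0.5, osteophytes = list(),
                         mesh_resolution = 0.6, seed = 1L) {
  if (trochlea_radius <= 0 || capitellum_radius <= 0 ||
      inter_center_distance <= 0 || shaft_length <= 0 || clearance <= 0 ||
      mesh_resolution <= 0) {
    abort("all phantom dimensions must be positive", "elbow4d_spec_error")
  }
  if (inter_center_distance <= trochlea_radius + capitellum_radius) {
    abort("articular solids overlap: increase inter_center_distance",
          "elbow4d_spec_error")
  }
  spec <- structure(
    list(trochlea_radius = trochlea_radius,
         capitellum_radius = capitellum_radius,
         inter_center_distance = inter_center_distance,
         shaft_length = shaft_length,
         clearance = clearance,
         osteophytes = osteophytes,
         mesh_resolution = mesh_resolution,
         seed = as.integer(seed)),
    class = "phantom_spec")
  for (o in osteophytes) validate_osteophyte(spec, o)
  spec
}

#' Osteophyte descriptor
#'
#' A spherical boss rigid with the humerus, centered at angular station
#' `center_angle_deg` around the hinge axis, standing `standoff` mm off the
#' trochlear surface (so the boss remains a disjoint closed component).
#'
#' @param center_angle_deg angular station (degrees, same convention as
#'   flexion angles: 0 points toward the extended forearm).
#' @param size boss sphere radius (mm).
#' @param attached_to only `"humerus"` is supported in this phantom; a
#'   forearm-attached boss at fixed radius from the axis would never change
#'   its clearance under rotation in this coaxial geometry.
#' @param station_x axial position of the boss center (mm, 0 = trochlea
#'   midplane).
#' @param standoff radial gap between trochlea surface and boss sphere (mm).
#' @return a list describing the osteophyte.
#' @export
osteophyte <- function(center_angle_deg, size, attached_to = "humerus",
                       station_x = 0, standoff = 0.2) {
  if (!identical(attached_to, "humerus")) {
    abort("only humerus-attached osteophytes are supported: a forearm boss at fixed radius from the coaxial hinge cannot produce an angle-dependent contact",
          "elbow4d_spec_error")
  }
  if (size <= 0 || standoff < 0) {
    abort("osteophyte 'size' must be positive and 'standoff' >= 0",
          "elbow4d_spec_error")
  }
  list(attached_to = attached_to, center_angle_deg = center_angle_deg,
       size = size, station_x = station_x, standoff = standoff)
}

# boss center radius from the axis
osteophyte_center_radius <- function(spec, o) {
  spec$trochlea_radius + o$standoff + o$size
}

#' Closed-form contact angles of an osteophyte
#'
#' The forearm near facet is the plane at distance `r_t + clearance` from
#' the axis at the forearm's current angle. A boss of radius `s` centered at
#' radius `rho = r_t + standoff + s`, station `phi`, touches that plane when
#' `rho * cos(theta - phi) = r_t + clearance - s`, i.e. over the angular
#' interval `phi +/- alpha` with `alpha = acos((r_t + clearance - s)/rho)`.
#'
#' @param spec a [phantom_spec()].
#' @param o an [osteophyte()].
#' @return named numeric: `first_contact_deg` (= phi - alpha, the flexion
#'   angle at which contact begins), `last_contact_deg` (= phi + alpha).
#' @export
osteophyte_contact_angle <- function(spec, o) {
  rho <- osteophyte_center_radius(spec, o)
  q <- (spec$trochlea_radius + spec$clearance - o$size) / rho
  if (q >= 1) {
    return(c(first_contact_deg = NA_real_, last_contact_deg = NA_real_))
  }
  alpha <- rad2deg(acos(q))
  c(first_contact_deg = o$center_angle_deg - alpha,
    last_contact_deg = o$center_angle_deg + alpha)
}

#' Solve an osteophyte that first contacts at a chosen flexion angle
#'
#' Inverts the closed form of [osteophyte_contact_angle()]: given the
#' desired first-contact angle `theta*` and the angular lead
#' `delta = phi - theta*`, the boss radius is
#' `s = (r_t (1 - cos delta) + clearance - standoff * cos delta) /
#' (1 + cos delta)`.
#'
#' @param spec a [phantom_spec()].
#' @param contact_angle_deg desired first-contact flexion angle.
#' @param delta_deg angular lead of the boss station over the contact angle;
#'   larger leads give faster volume growth past contact but push the
#'   contact point toward the edge of the forearm facet.
#' @param station_x,standoff as in [osteophyte()].
#' @return an [osteophyte()] whose closed-form first contact is
#'   `contact_angle_deg`.
#' @export
osteophyte_for_contact <- function(spec, contact_angle_deg, delta_deg = 25,
                                   station_x = 0, standoff = 0.2) {
  cd <- cos(deg2rad(delta_deg))
  s <- (spec$trochlea_radius * (1 - cd) + spec$clearance - standoff * cd) /
    (1 + cd)
  if (s <= 0) {
    abort("no positive boss radius solves this contact angle; increase delta_deg",
          "elbow4d_spec_error")
  }
  o <- osteophyte(center_angle_deg = contact_angle_deg + delta_deg, size = s,
                  station_x = station_x, standoff = standoff)
  validate_osteophyte(spec, o)
  # the closed form assumes first contact on the facet interior, not its edge
  rho <- osteophyte_center_radius(spec, o)
  ca <- osteophyte_contact_angle(spec, o)
  alpha <- deg2rad(ca[["last_contact_deg"]] - o$center_angle_deg)
  if (rho * sin(alpha) > forearm_half_width(spec)) {
    abort("osteophyte contact point falls off the forearm facet; reduce its size or angular lead",
          "elbow4d_spec_error")
  }
  o
}

validate_osteophyte <- function(spec, o) {
  half_len <- trochlea_half_length(spec)
  if (abs(o$station_x) + o$size > half_len) {
    abort("osteophyte overhangs the trochlea axially", "elbow4d_spec_error")
  }
  invisible(o)
}

# fixed proportions of the idealized joint
trochlea_half_length <- function(spec) 0.6 * spec$trochlea_radius
forearm_half_width <- function(spec) 0.5 * spec$trochlea_radius
shaft_standoff <- function(spec) 1.6 * spec$trochlea_radius # shaft bottom radius

u_station <- function(angle_deg) {
  th <- deg2rad(angle_deg)
  c(0, sin(th), -cos(th))
}

#' Generate a phantom
#'
#' Deterministic for a given spec: builds both watertight meshes, the true
#' axis (x-axis through the origin) and the two true articular rings.
#'
#' @param spec a [phantom_spec()].
#' @return object of class `phantom`: `humerus_mesh`, `forearm_mesh`,
#'   `true_axis`, `true_rings` (list of trochlea/capitellum [fit_ring()]
#'   rings), `spec`.
#' @export
make_phantom <- function(spec) {
  if (!inherits(spec, "phantom_spec")) {
    abort("'spec' must be a phantom_spec", "elbow4d_argument_error")
  }
  r_t <- spec$trochlea_radius
  r_c <- spec$capitellum_radius
  d <- spec$inter_center_distance
  res <- spec$mesh_resolution
  half_len <- trochlea_half_length(spec)
  n_seg <- max(48L, as.integer(ceiling(2 * pi * r_t / res)))
  sph_sub <- max(2L, min(5L, as.integer(ceiling(log2(1.05 * r_c / res)))))

  trochlea <- mesh_cylinder(r_t, -half_len, half_len, n_seg = n_seg,
                            name = "trochlea")
  capitellum <- mesh_icosphere(r_c, center = c(d, 0, 0),
                               subdivisions = sph_sub, name = "capitellum")
  z0 <- shaft_standoff(spec)
  shaft_w <- 0.2 * r_t
  shaft <- mesh_box(c(-half_len, -shaft_w, z0),
                    c(d + r_c / 2, shaft_w, z0 + spec$shaft_length),
                    name = "shaft")
  bosses <- lapply(spec$osteophytes, function(o) {
    rho <- osteophyte_center_radius(spec, o)
    ctr <- rho * u_station(o$center_angle_deg) + c(o$station_x, 0, 0)
    mesh_icosphere(o$size, center = ctr, subdivisions = 3L, name = "osteophyte")
  })
  humerus <- do.call(merge_meshes,
                     c(list(trochlea, capitellum, shaft), bosses,
                       list(name = "humerus")))

  hw <- forearm_half_width(spec)
  near <- r_t + spec$clearance
  forearm <- mesh_box(c(-hw, -hw, -(near + spec$shaft_length)),
                      c(hw, hw, -near), name = "forearm")

  axis <- hinge_axis(point = c(0, 0, 0), direction = c(1, 0, 0),
                     diagnostics = list(
                       trochlea_radius_mm = r_t,
                       capitellum_radius_mm = r_c,
                       inter_center_distance_mm = d))
  rings <- list(
    trochlea = ring(center = c(0, 0, 0), radius = r_t, normal = c(1, 0, 0)),
    capitellum = ring(center = c(d, 0, 0), radius = r_c, normal = c(1, 0, 0))
  )
  structure(list(humerus_mesh = humerus, forearm_mesh = forearm,
                 true_axis = axis, true_rings = rings, spec = spec),
            class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("<phantom: trochlea r %g mm, capitellum r %g mm, centers %g mm apart, %d osteophyte(s)>\n",
              x$spec$trochlea_radius, x$spec$capitellum_radius,
              x$spec$inter_center_distance, length(x$spec$osteophytes)))
  invisible(x)
}

#' Sample landmark points on the phantom's true rings
#'
#' Draws three points per ring at seeded random ring angles (pairwise
#' separation at least 20 degrees, keeping the circle fit well-conditioned)
#' and perturbs them with isotropic Gaussian noise. The same seed reuses the
#' same ring angles and the same unit noise vectors across different
#' `noise_sd`, so noise levels are paired by seed.
#'
#' @param phantom a [make_phantom()] result.
#' @param noise_sd isotropic landmark noise standard deviation (mm).
#' @param seed RNG seed (defaults to the spec's seed).
#' @param min_separation_deg smallest allowed angular gap between the three
#'   ring angles. The 20-degree default only excludes near-collinear
#'   triples; clustered triples amplify noise into large circumcenter
#'   errors, so studies emulating deliberate operator spreading should raise
#'   this (e.g. 60).
#' @return a [landmark_set()].
#' @export
sample_landmarks <- function(phantom, noise_sd = 0, seed = phantom$spec$seed,
                             min_separation_deg = 20) {
  if (noise_sd < 0) abort("'noise_sd' must be >= 0", "elbow4d_argument_error")
  if (min_separation_deg < 0 || min_separation_deg > 120) {
    abort("'min_separation_deg' must be in [0, 120]", "elbow4d_argument_error")
  }
  with_seed(seed, {
    draw_angles <- function() {
      repeat {
        a <- sort(runif(3, 0, 360))
        gaps <- c(diff(a), 360 - (a[3] - a[1]))
        if (min(gaps) >= min_separation_deg) return(a)
      }
    }
    ang_t <- draw_angles()
    ang_c <- draw_angles()
    noise <- matrix(rnorm(18), ncol = 3)
    on_ring <- function(rg, angles) {
      th <- deg2rad(angles)
      sweep(cbind(0, rg$radius * cos(th), rg$radius * sin(th)), 2,
            rg$center, "+")
    }
    troch <- on_ring(phantom$true_rings$trochlea, ang_t) +
      noise_sd * noise[1:3, ]
    cap <- on_ring(phantom$true_rings$capitellum, ang_c) +
      noise_sd * noise[4:6, ]
    landmark_set(troch, cap,
                 source = sprintf("phantom-seed%d-sd%g", seed, noise_sd))
  })
}
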