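# The overlap operator is validated against analytic intersections (boxes,
# the equal-sphere lens) and the phantom's closed-form contact angle.

zaxis <- hinge_axis(c(0, 0, 0), c(0, 0, 1))

test_that("half-overlapping unit cubes recover 0.5 within a surface layer", {
  a <- mesh_box()
  b <- mesh_box(c(0.5, 0, 0), c(1.5, 1, 1))
  res <- overlap_volume(a, b, zaxis, 0, voxel_size = 0.05)
  # one voxel layer over the 6 faces of the 0.5 x 1 x 1 intersection slab
  bound <- 6 * 0.05 * 1
  expect_lt(abs(res$volume_mm3 - 0.5), bound)
  expect_gt(res$volume_mm3, 0)
})

test_that("disjoint bounding boxes short-circuit to a clean zero", {
  a <- mesh_box()
  b <- mesh_box(c(5, 5, 5), c(6, 6, 6))
  res <- overlap_volume(a, b, zaxis, 0, voxel_size = 0.25)
  expect_identical(res$volume_mm3, 0)
  expect_false(any(res$humerus_face_labels))
  expect_false(any(res$forearm_face_labels))
})

test_that("equal-sphere lens volume matches the closed form within 2%", {
  s1 <- mesh_icosphere(10, subdivisions = 4)
  s2 <- mesh_icosphere(10, center = c(10, 0, 0), subdivisions = 4)
  res <- overlap_volume(s1, s2, zaxis, 0, voxel_size = 0.25)
  lens <- pi * (4 * 10 + 10) * (2 * 10 - 10)^2 / 12 # 5000*pi/12
  expect_equal(res$volume_mm3, lens, tolerance = 0.02)
})

test_that("overlap is symmetric in the two bodies within one voxel layer", {
  s1 <- mesh_icosphere(6, subdivisions = 3)
  s2 <- mesh_icosphere(5, center = c(4, 2, 1), subdivisions = 3)
  h <- 0.25
  r12 <- overlap_volume(s1, s2, zaxis, 0, voxel_size = h)$volume_mm3
  r21 <- overlap_volume(s2, s1, zaxis, 0, voxel_size = h)$volume_mm3
  contact_area <- pi * 5^2
  expect_lt(abs(r12 - r21), 2 * h * contact_area)
  expect_equal(r12, r21, tolerance = 0.05)
})

test_that("labeled faces are exactly those whose centroid lies inside the other bone", {
  s1 <- mesh_icosphere(6, subdivisions = 3)
  s2 <- mesh_icosphere(5, center = c(6, 0, 0), subdivisions = 3)
  res <- overlap_volume(s1, s2, zaxis, 0, voxel_size = 0.5)
  centroid <- function(m) {
    (m$vertices[m$faces[, 1], ] + m$vertices[m$faces[, 2], ] +
       m$vertices[m$faces[, 3], ]) / 3
  }
  expect_identical(res$humerus_face_labels, points_in_mesh(s2, centroid(s1)))
  expect_identical(res$forearm_face_labels, points_in_mesh(s1, centroid(s2)))
  expect_gt(sum(res$humerus_face_labels), 0)
})

test_that("overlap is invariant under a common rigid transform of the scene", {
  ph <- osteo_phantom_120()
  base <- overlap_volume(ph$humerus_mesh, ph$forearm_mesh, ph$true_axis, 130,
                         voxel_size = 0.25, label_faces = FALSE)$volume_mm3
  set.seed(8)
  tf <- random_rigid_transform()
  moved <- overlap_volume(apply_transform(tf, ph$humerus_mesh),
                          apply_transform(tf, ph$forearm_mesh),
                          hinge_axis(apply_transform(tf, ph$true_axis$point),
                                     tf$rotation %*% ph$true_axis$direction),
                          130, voxel_size = 0.25,
                          label_faces = FALSE)$volume_mm3
  expect_gt(base, 0)
  # voxel sampling is not rotation-invariant; agreement to the surface layer
  expect_equal(moved, base, tolerance = 0.15)
})

test_that("a clearance-only phantom sweeps contact-free over the designed arc", {
  ph <- default_phantom()
  pr <- flexion_sweep(ph$humerus_mesh, ph$forearm_mesh, ph$true_axis,
                      -10, 140, 10, voxel_size = 0.5)
  expect_true(all(pr$volumes_mm3 == 0))
  expect_true(is.na(pr$first_contact_extension_deg))
  expect_true(is.na(pr$first_contact_flexion_deg))
  expect_equal(pr$impingement_free_arc_deg, 150)
})

test_that("the designed 120-degree osteophyte contact is found within one step", {
  ph <- osteo_phantom_120()
  pr <- flexion_sweep(ph$humerus_mesh, ph$forearm_mesh, ph$true_axis,
                      110, 130, 1, voxel_size = 0.2)
  expect_false(is.na(pr$first_contact_flexion_deg))
  expect_lte(abs(pr$first_contact_flexion_deg - 120), 1)
  expect_true(is.na(pr$first_contact_extension_deg))
})

test_that("raising the contact threshold can only widen the free arc", {
  ph <- osteo_phantom_120()
  p0 <- flexion_sweep(ph$humerus_mesh, ph$forearm_mesh, ph$true_axis,
                      110, 130, 2, voxel_size = 0.25, contact_threshold = 0)
  p10 <- flexion_sweep(ph$humerus_mesh, ph$forearm_mesh, ph$true_axis,
                       110, 130, 2, voxel_size = 0.25, contact_threshold = 10)
  expect_gte(p10$impingement_free_arc_deg, p0$impingement_free_arc_deg)
})

test_that("report_targets returns the 0- and 140-degree overlap results", {
  ph <- osteo_phantom_120()
  tg <- report_targets(ph$humerus_mesh, ph$forearm_mesh, ph$true_axis,
                       voxel_size = 0.25)
  expect_named(tg, c("0", "140"))
  expect_identical(tg[["0"]]$volume_mm3, 0)
  expect_gt(tg[["140"]]$volume_mm3, 0)
  again <- overlap_volume(ph$humerus_mesh, ph$forearm_mesh, ph$true_axis, 140,
                          voxel_size = 0.25)
  expect_identical(tg[["140"]]$volume_mm3, again$volume_mm3)
})
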