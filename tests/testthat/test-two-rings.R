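test_that("circumcircle through canonical triples", {
  r <- circumcircle3(c(1, 0, 0), c(0, 1, 0), c(-1, 0, 0))
  expect_equal(r$center, c(0, 0, 0), tolerance = 1e-12)
  expect_equal(r$radius, 1, tolerance = 1e-12)
  expect_equal(r$normal, c(0, 0, 1), tolerance = 1e-12)

  # right angle at (1,1,0): the first-to-second segment is a diameter
  r2 <- circumcircle3(c(0, 0, 0), c(2, 0, 0), c(1, 1, 0))
  expect_equal(r2$center, c(1, 0, 0), tolerance = 1e-12)
  expect_equal(r2$radius, 1, tolerance = 1e-12)

  expect_error(circumcircle3(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)),
               class = "elbow4d_degenerate_landmarks_error")
  expect_error(circumcircle3(c(1, 1, 1), c(1, 1, 1), c(2, 0, 0)),
               class = "elbow4d_degenerate_landmarks_error")
})

test_that("circumcircle agrees with an independent linear-system oracle", {
  set.seed(11)
  for (i in 1:100) {
    repeat {
      p <- matrix(rnorm(9, sd = 5), ncol = 3)
      a <- 0.5 * sqrt(sum(cross_ <- {
        e1 <- p[2, ] - p[1, ]; e2 <- p[3, ] - p[1, ]
        c(e1[2] * e2[3] - e1[3] * e2[2],
          e1[3] * e2[1] - e1[1] * e2[3],
          e1[1] * e2[2] - e1[2] * e2[1])
      }^2))
      if (a > 0.1) break
    }
    ring <- circumcircle3(p[1, ], p[2, ], p[3, ])
    oc <- oracle_circumcenter(p[1, ], p[2, ], p[3, ])
    expect_equal(ring$center, oc, tolerance = 1e-9)
    d <- sqrt(colSums((t(p) - ring$center)^2))
    expect_lt(max(abs(d - ring$radius)) / ring$radius, 1e-9)
  }
})

test_that("circumcircle commutes with rigid transforms", {
  set.seed(3)
  p <- matrix(rnorm(9, sd = 4), ncol = 3)
  base <- circumcircle3(p[1, ], p[2, ], p[3, ])
  for (i in 1:5) {
    tf <- random_rigid_transform()
    q <- apply_transform(tf, p)
    moved <- circumcircle3(q[1, ], q[2, ], q[3, ])
    expect_equal(moved$center, apply_transform(tf, base$center),
                 tolerance = 1e-9)
    expect_equal(moved$radius, base$radius, tolerance = 1e-9)
    expect_equal(abs(sum(moved$normal * (tf$rotation %*% base$normal))), 1,
                 tolerance = 1e-9)
  }
})

test_that("fit_ring reduces to the circumcircle at three points and recovers exact circles", {
  p <- rbind(c(1, 2, 0), c(4, 2.5, 1), c(2, -1, 3))
  a <- fit_ring(p)
  b <- circumcircle3(p[1, ], p[2, ], p[3, ])
  expect_equal(a$center, b$center)
  expect_equal(a$radius, b$radius)

  # 12 exact on-circle samples: center, radius and normal recovered
  set.seed(21)
  n <- c(1, -2, 2) / 3
  u <- c(2, 2, 1) / 3
  w <- c(-2, 1, 2) / 3 # n, u, w form an orthonormal right-handed frame
  ctr <- c(5, -3, 2)
  th <- sort(runif(12, 0, 2 * pi))
  pts <- t(sapply(th, function(t) ctr + 7 * (cos(t) * u + sin(t) * w)))
  fit <- fit_ring(pts)
  expect_equal(fit$center, ctr, tolerance = 1e-9)
  expect_equal(fit$radius, 7, tolerance = 1e-9)
  expect_equal(abs(sum(fit$normal * n)), 1, tolerance = 1e-9)
  expect_lt(fit$rms_residual, 1e-9)
})

test_that("noisy ring fits center the circle within the noise scale", {
  set.seed(99)
  errs <- replicate(200, {
    th <- sort(runif(12, 0, 2 * pi))
    pts <- cbind(10 * cos(th), 10 * sin(th), 0) +
      matrix(rnorm(36, sd = 0.1), ncol = 3)
    sqrt(sum(fit_ring(pts)$center^2))
  })
  expect_lt(median(errs), 0.1)
})

test_that("two-rings axis runs through the ring centers with fixed orientation", {
  th <- c(0, 2, 4) * 2 * pi / 6
  troch <- cbind(0, cos(th), sin(th))
  cap <- cbind(40, 3 * cos(th + 1), 3 * sin(th + 1))
  ax <- two_rings(landmark_set(troch, cap))
  expect_equal(ax$point, c(0, 0, 0), tolerance = 1e-9)
  expect_equal(ax$direction, c(1, 0, 0), tolerance = 1e-9)
  expect_equal(ax$diagnostics$inter_center_distance_mm, 40, tolerance = 1e-9)

  # permuting points within a group leaves the axis unchanged
  ax2 <- two_rings(landmark_set(troch[c(3, 1, 2), ], cap[c(2, 3, 1), ]))
  expect_equal(ax2$point, ax$point)
  expect_equal(ax2$direction, ax$direction)

  # flip flag mirrors the direction for the contralateral side
  ax3 <- two_rings(landmark_set(troch, cap), flip = TRUE)
  expect_equal(ax3$direction, -ax$direction)
})

test_that("coincident ring centers are rejected as an unstable axis", {
  th <- c(0, 2, 4) * 2 * pi / 6
  troch <- cbind(0, cos(th), sin(th))
  cap <- cbind(0, 2 * cos(th), 2 * sin(th)) # same center, different radius
  expect_error(two_rings(landmark_set(troch, cap)),
               class = "elbow4d_unstable_axis_error")
})

test_that("axis_error reports angle and line distance", {
  a <- hinge_axis(c(0, 0, 0), c(1, 0, 0))
  expect_equal(unname(axis_error(a, a)), c(0, 0))
  b <- hinge_axis(c(0, 0, 2), c(-1, 0, 0)) # antiparallel, offset 2
  expect_equal(unname(axis_error(a, b)), c(0, 2), tolerance = 1e-12)
  c_ <- hinge_axis(c(0, 0, 0), c(0, 1, 0))
  expect_equal(unname(axis_error(a, c_)), c(90, 0), tolerance = 1e-12)
})

test_that("landmark JSON round-trips", {
  lm <- sample_landmarks(default_phantom(), noise_sd = 0.2, seed = 5)
  path <- withr::local_tempfile(fileext = ".json")
  write_landmarks(lm, path)
  back <- read_landmarks(path)
  expect_equal(back$trochlea, lm$trochlea, tolerance = 1e-12)
  expect_equal(back$capitellum, lm$capitellum, tolerance = 1e-12)
  expect_equal(back$source, lm$source)
})
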