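# Fixtures built in code: an ASCII STL cube with duplicated per-facet
# corners, independent oracles for the circumcircle (linear system) and the
# ICC (aov-based ANOVA), and random rigid transforms.

ascii_cube_stl <- function(path) {
  cube <- mesh_box()
  # write with per-facet duplicated vertices (the raw STL layout)
  write_stl(cube, path, binary = FALSE)
  path
}

# circumcenter by solving the 3-equation linear system
#   (c - p1).e1 = |e1|^2/2 ; (c - p1).e2 = |e2|^2/2 ; (c - p1).n = 0
# directly with solve(); independent of the implementation's 2x2 route.
oracle_circumcenter <- function(p1, p2, p3) {
  e1 <- p2 - p1
  e2 <- p3 - p1
  n <- c(e1[2] * e2[3] - e1[3] * e2[2],
         e1[3] * e2[1] - e1[1] * e2[3],
         e1[1] * e2[2] - e1[2] * e2[1])
  A <- rbind(e1, e2, n)
  b <- c(sum(e1^2) / 2, sum(e2^2) / 2, 0)
  p1 + as.numeric(solve(A, b))
}

# one- and two-way mean squares via stats::aov, assembled from model output
oracle_icc <- function(m) {
  n <- nrow(m); k <- ncol(m)
  df <- data.frame(
    y = as.vector(m),
    subject = factor(rep(seq_len(n), times = k)),
    rater = factor(rep(seq_len(k), each = n))
  )
  a1 <- summary(stats::aov(y ~ subject, data = df))[[1]]
  bms <- a1["subject", "Mean Sq"]
  wms <- a1["Residuals", "Mean Sq"]
  a2 <- summary(stats::aov(y ~ subject + rater, data = df))[[1]]
  jms <- a2["rater", "Mean Sq"]
  ems <- a2["Residuals", "Mean Sq"]
  list(
    icc11 = (bms - wms) / (bms + (k - 1) * wms),
    icc21 = (bms - ems) / (bms + (k - 1) * ems + k * (jms - ems) / n)
  )
}

random_rigid_transform <- function() {
  ax <- hinge_axis(point = rnorm(3, sd = 5), direction = rnorm(3))
  rotation_about_axis(ax, runif(1, -180, 180))
}

default_phantom <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- make_phantom(phantom_spec())
    cache
  }
})

osteo_phantom_120 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      spec <- phantom_spec()
      spec <- phantom_spec(osteophytes = list(osteophyte_for_contact(spec, 120)))
      cache <<- make_phantom(spec)
    }
    cache
  }
})
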