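# Shared helpers: classed errors, vector algebra, seeded evaluation.

abort <- function(message, class, ...) {
  stop(structure(
    class = c(class, "elbow4d_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  ))
}

#' @noRd
vnorm <- function(v) sqrt(sum(v * v))

unit <- function(v) {
  n <- vnorm(v)
  if (n == 0) abort("cannot normalize a zero vector", "elbow4d_argument_error")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

# round() uses banker's rounding; printed clinical means round half away
# from zero.
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Evaluate `expr` under a given RNG seed without disturbing the caller's
# RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

as_point_matrix <- function(points, arg = "points") {
  if (is.null(dim(points))) {
    if (length(points) != 3L) {
      abort(sprintf("'%s' must be a 3-vector or an n x 3 matrix", arg),
            "elbow4d_argument_error")
    }
    points <- matrix(points, ncol = 3L)
  }
  points <- as.matrix(points)
  if (ncol(points) != 3L) {
    abort(sprintf("'%s' must have 3 columns (x, y, z in mm)", arg),
          "elbow4d_argument_error")
  }
  storage.mode(points) <- "double"
  dimnames(points) <- NULL
  points
}
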