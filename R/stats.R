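# Reliability and cohort statistics: one-way and two-way random intraclass
# correlation on ratings matrices (single-measure, absolute-agreement forms
# ICC(1,1) and ICC(2,1), the standard reading for duplicate measurements by
# two observers), with F-based 95% confidence intervals, plus cohort
# summaries and paired / Welch t-tests for pre/post outcome tables.

icc_interpretation <- function(estimate) {
  if (estimate > 0.75) "excellent"
  else if (estimate >= 0.4) "fair to good"
  else "poor"
}

validate_ratings <- function(m) {
  m <- as.matrix(m)
  storage.mode(m) <- "double"
  if (anyNA(m)) {
    bad <- which(is.na(m), arr.ind = TRUE)
    abort(sprintf("ratings matrix has missing cells at (%s)",
                  paste(sprintf("%d,%d", bad[, 1], bad[, 2]), collapse = "; ")),
          "elbow4d_data_error")
  }
  if (nrow(m) < 2L || ncol(m) < 2L) {
    abort("ratings matrix needs at least 2 subjects and 2 raters/sessions",
          "elbow4d_data_error")
  }
  m
}

icc_result <- function(model, estimate, ci, anova_table, n, k) {
  structure(list(model = model, estimate = estimate,
                 interpretation = icc_interpretation(estimate),
                 conf_low = ci[1], conf_high = ci[2], conf_level = 0.95,
                 anova_table = anova_table, n_subjects = n, n_raters = k),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC %s: %.3f (95%% CI %.3f-%.3f), %s agreement, %d subjects x %d raters\n",
              x$model, x$estimate, x$conf_low, x$conf_high,
              x$interpretation, x$n_subjects, x$n_raters))
  invisible(x)
}

# one- and two-way mean squares from scratch
anova_ms <- function(m) {
  n <- nrow(m); k <- ncol(m)
  grand <- mean(m)
  rowm <- rowMeans(m)
  colm <- colMeans(m)
  bms <- k * sum((rowm - grand)^2) / (n - 1)
  wms <- sum((m - rowm)^2) / (n * (k - 1))
  jms <- n * sum((colm - grand)^2) / (k - 1)
  resid <- sweep(sweep(m, 1, rowm), 2, colm) + grand
  ems <- sum(resid^2) / ((n - 1) * (k - 1))
  list(n = n, k = k, BMS = bms, WMS = wms, JMS = jms, EMS = ems)
}

#' One-way random single-measure ICC, ICC(1,1)
#'
#' `(BMS - WMS) / (BMS + (k-1) WMS)` from the one-way ANOVA decomposition
#' (subjects random, rater folded into error): the model for intraobserver
#' (test-retest) reliability. Interpretation thresholds: above 0.75
#' excellent, 0.4-0.75 fair to good, below 0.4 poor.
#'
#' @param m numeric n x k matrix: n subjects by k repeated measurements.
#' @return an `icc_result` with estimate, interpretation, 95% CI and the
#'   ANOVA mean squares.
#' @export
icc_oneway_random <- function(m) {
  m <- validate_ratings(m)
  ms <- anova_ms(m)
  if (ms$BMS <= 0 && ms$WMS <= 0) {
    abort("undefined ICC: ratings have zero total variance", "elbow4d_undefined_icc_error")
  }
  est <- (ms$BMS - ms$WMS) / (ms$BMS + (ms$k - 1) * ms$WMS)
  ci <- if (ms$WMS == 0) c(NA_real_, NA_real_) else {
    f_obs <- ms$BMS / ms$WMS
    fl <- f_obs / qf(0.975, ms$n - 1, ms$n * (ms$k - 1))
    fu <- f_obs * qf(0.975, ms$n * (ms$k - 1), ms$n - 1)
    c((fl - 1) / (fl + ms$k - 1), (fu - 1) / (fu + ms$k - 1))
  }
  tab <- data.frame(
    term = c("between_subjects", "within_subjects"),
    df = c(ms$n - 1, ms$n * (ms$k - 1)),
    mean_square = c(ms$BMS, ms$WMS)
  )
  icc_result("oneway_random", est, ci, tab, ms$n, ms$k)
}

#' Two-way random single-measure absolute-agreement ICC, ICC(2,1)
#'
#' `(BMS - EMS) / (BMS + (k-1) EMS + k (JMS - EMS) / n)` from the two-way
#' ANOVA (subjects and raters both random): the model for interobserver
#' reliability. The 95% CI uses the F forms with Satterthwaite degrees of
#' freedom.
#'
#' @param m numeric n x k matrix: n subjects by k raters.
#' @return an `icc_result`.
#' @export
icc_twoway_random <- function(m) {
  m <- validate_ratings(m)
  ms <- anova_ms(m)
  if (ms$BMS <= 0 && ms$JMS <= 0 && ms$EMS <= 0) {
    abort("undefined ICC: ratings have zero total variance", "elbow4d_undefined_icc_error")
  }
  n <- ms$n; k <- ms$k
  denom <- ms$BMS + (k - 1) * ms$EMS + k * (ms$JMS - ms$EMS) / n
  if (denom == 0) {
    abort("undefined ICC: degenerate variance decomposition", "elbow4d_undefined_icc_error")
  }
  est <- (ms$BMS - ms$EMS) / denom
  ci <- if (ms$EMS == 0 || est >= 1) c(NA_real_, NA_real_) else {
    a <- k * est / (n * (1 - est))
    b <- 1 + k * est * (n - 1) / (n * (1 - est))
    v <- (a * ms$JMS + b * ms$EMS)^2 /
      ((a * ms$JMS)^2 / (k - 1) + (b * ms$EMS)^2 / ((n - 1) * (k - 1)))
    f1 <- qf(0.975, n - 1, v)
    f2 <- qf(0.975, v, n - 1)
    lower <- n * (ms$BMS - f1 * ms$EMS) /
      (f1 * (k * ms$JMS + (k * n - k - n) * ms$EMS) + n * ms$BMS)
    upper <- n * (f2 * ms$BMS - ms$EMS) /
      (k * ms$JMS + (k * n - k - n) * ms$EMS + n * f2 * ms$BMS)
    c(lower, upper)
  }
  tab <- data.frame(
    term = c("between_subjects", "between_raters", "residual"),
    df = c(n - 1, k - 1, (n - 1) * (k - 1)),
    mean_square = c(ms$BMS, ms$JMS, ms$EMS)
  )
  icc_result("twoway_random", est, ci, tab, n, k)
}

#' Cohort summary: mean, sample SD, n
#'
#' Values are reported as mean (+/- SD); the printed mean is rounded half
#' away from zero to `digits` decimals, matching clinical-table convention.
#'
#' @param values numeric vector (n >= 1).
#' @param digits decimals for the rounded presentation.
#' @return object of class `cohort_summary`: `mean`, `sd`, `n`,
#'   `mean_rounded`, `sd_rounded`.
#' @export
cohort_summary <- function(values, digits = 0) {
  values <- as.numeric(values)
  if (length(values) == 0L) {
    abort("'values' must be non-empty", "elbow4d_argument_error")
  }
  m <- mean(values)
  s <- if (length(values) >= 2L) sd(values) else NA_real_
  structure(list(mean = m, sd = s, n = length(values),
                 mean_rounded = round_half_up(m, digits),
                 sd_rounded = if (is.na(s)) NA_real_ else round_half_up(s, digits)),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("%g (±%g), n = %d\n", x$mean_rounded, x$sd_rounded, x$n))
  invisible(x)
}

#' Paired t-test on pre/post measurements
#'
#' Two-sided paired Student t-test on within-subject differences
#' (df = n - 1). All-zero differences return t = 0, p = 1; constant nonzero
#' differences have no variance to test against and raise an error.
#'
#' @param pre,post equal-length numeric vectors (n >= 2).
#' @return named list: `t`, `df`, `p`, `mean_difference`.
#' @export
paired_t <- function(pre, post) {
  pre <- as.numeric(pre); post <- as.numeric(post)
  if (length(pre) != length(post) || length(pre) < 2L) {
    abort("'pre' and 'post' must be equal-length vectors with n >= 2",
          "elbow4d_argument_error")
  }
  d <- post - pre
  if (all(d == 0)) {
    return(list(t = 0, df = length(d) - 1L, p = 1, mean_difference = 0))
  }
  if (var(d) == 0) {
    abort("degenerate paired test: all differences identical and nonzero",
          "elbow4d_degenerate_test_error")
  }
  tt <- t.test(post, pre, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean_difference = mean(d))
}

#' Welch two-sample t-test for independent group contrasts
#'
#' Used for open-vs-arthroscopic style comparisons, where subjects differ
#' between groups.
#'
#' @param x,y numeric vectors (each n >= 2).
#' @return named list: `t`, `df`, `p`, `mean_difference` (x - y).
#' @export
group_t <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) < 2L || length(y) < 2L) {
    abort("both groups need n >= 2", "elbow4d_argument_error")
  }
  if (var(x) == 0 && var(y) == 0) {
    if (mean(x) == mean(y)) {
      return(list(t = 0, df = length(x) + length(y) - 2L, p = 1,
                  mean_difference = 0))
    }
    abort("degenerate group test: both groups constant", "elbow4d_degenerate_test_error")
  }
  tt <- t.test(x, y)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean_difference = mean(x) - mean(y))
}

#' Read a ratings CSV (subject id column + one column per rater/session)
#'
#' @param path CSV path; first column subject id, remaining columns numeric
#'   measurements.
#' @return numeric matrix with subject ids as row names.
#' @export
read_ratings <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path), "elbow4d_file_error")
  }
  df <- utils::read.csv(path, check.names = FALSE)
  if (ncol(df) < 3L) {
    abort("ratings CSV needs a subject column plus >= 2 rating columns",
          "elbow4d_data_error")
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df[[1]])
  validate_ratings(m)
}

#' Read a per-patient range-of-motion table
#'
#' Expected columns: `case`, `flexion_pre`, `extension_pre`, `arc_pre`,
#' `flexion_post`, `extension_post`, `arc_post`, and optionally `group` and
#' score columns. Extension deficits are signed (<= 0) and every record must
#' satisfy arc = flexion + extension; violations are reported by row.
#'
#' @param path CSV path.
#' @return the validated data frame.
#' @export
read_rom_table <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path), "elbow4d_file_error")
  }
  df <- utils::read.csv(path)
  need <- c("flexion_pre", "extension_pre", "arc_pre",
            "flexion_post", "extension_post", "arc_post")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    abort(sprintf("ROM table lacks columns: %s",
                  paste(missing_cols, collapse = ", ")), "elbow4d_data_error")
  }
  for (when in c("pre", "post")) {
    bad <- which(df[[paste0("arc_", when)]] !=
                   df[[paste0("flexion_", when)]] + df[[paste0("extension_", when)]])
    if (length(bad)) {
      abort(sprintf("arc != flexion + extension (%s) in rows: %s",
                    when, paste(bad, collapse = ", ")), "elbow4d_data_error")
    }
  }
  df
}
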