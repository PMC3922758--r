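## Intra-measurer reliability: two-way random-effects, absolute-agreement,
## single-measure intraclass correlation — ICC(2,1) in Shrout-Fleiss
## notation — with an F-based 95% confidence interval.

#' ICC(2,1) with confidence interval
#'
#' Two-way random-effects, absolute-agreement, single-measure intraclass
#' correlation for an n-subjects by k-measurements matrix:
#' \deqn{ICC = \frac{MS_R - MS_E}{MS_R + (k-1) MS_E + \frac{k}{n}(MS_C - MS_E)}}
#' where \eqn{MS_R}, \eqn{MS_C} and \eqn{MS_E} are the subject, measurement
#' and error mean squares of the two-way ANOVA decomposition. The confidence
#' interval uses the Shrout-Fleiss F-based formulation with a
#' Satterthwaite-approximated denominator degree of freedom.
#'
#' @param m numeric matrix, subjects in rows (n >= 2), repeated measurements
#'   in columns (k >= 2), no missing cells.
#' @param conf_level confidence level (default 0.95).
#' @return Object of class `icc_result`: `icc`, `ci_low`, `ci_high`,
#'   `variance_components` (subjects, raters, error), the three mean
#'   squares, `n`, `k`. If the matrix has zero total variance the ICC is
#'   undefined and reported as `NA` with a `reason`.
#' @export
icc_2_1 <- function(m, conf_level = 0.95) {
  m <- as.matrix(m)
  storage.mode(m) <- "double"
  n <- nrow(m); k <- ncol(m)
  if (n < 2L || k < 2L) stop("need at least 2 subjects and 2 measurements", call. = FALSE)
  if (anyNA(m)) stop("ratings matrix must not contain missing cells", call. = FALSE)

  grand <- mean(m)
  if (all(m == grand)) {
    return(structure(
      list(icc = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
           variance_components = c(subjects = 0, raters = 0, error = 0),
           ms = c(MSR = 0, MSC = 0, MSE = 0), n = n, k = k,
           reason = "zero total variance: ICC undefined"),
      class = "icc_result"
    ))
  }

  row_m <- rowMeans(m); col_m <- colMeans(m)
  MSR <- k * sum((row_m - grand)^2) / (n - 1)
  MSC <- n * sum((col_m - grand)^2) / (k - 1)
  SSE <- sum((m - outer(row_m, rep(1, k)) - outer(rep(1, n), col_m) + grand)^2)
  MSE <- SSE / ((n - 1) * (k - 1))

  icc <- (MSR - MSE) / (MSR + (k - 1) * MSE + (k / n) * (MSC - MSE))

  alpha <- 1 - conf_level
  if (icc >= 1) { # error and rater variance both zero: degenerate interval
    lo <- hi <- 1
    return(structure(
      list(icc = 1, ci_low = lo, ci_high = hi,
           variance_components = c(subjects = (MSR - MSE) / k, raters = 0, error = 0),
           ms = c(MSR = MSR, MSC = MSC, MSE = MSE),
           n = n, k = k, conf_level = conf_level, reason = NA_character_),
      class = "icc_result"
    ))
  }
  ## Shrout-Fleiss interval for ICC(2,1)
  a <- (k * icc) / (n * (1 - icc))
  b <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
  v <- (a * MSC + b * MSE)^2 /
    ((a * MSC)^2 / (k - 1) + (b * MSE)^2 / ((n - 1) * (k - 1)))
  FU <- stats::qf(1 - alpha / 2, n - 1, v)
  FL <- stats::qf(1 - alpha / 2, v, n - 1)
  lo <- n * (MSR - FU * MSE) /
    (FU * (k * MSC + (k * n - k - n) * MSE) + n * MSR)
  hi <- n * (FL * MSR - MSE) /
    (k * MSC + (k * n - k - n) * MSE + n * FL * MSR)

  structure(
    list(icc = icc, ci_low = lo, ci_high = hi,
         variance_components = c(subjects = (MSR - MSE) / k,
                                 raters = (MSC - MSE) / n,
                                 error = MSE),
         ms = c(MSR = MSR, MSC = MSC, MSE = MSE),
         n = n, k = k, conf_level = conf_level, reason = NA_character_),
    class = "icc_result"
  )
}

#' @export
print.icc_result <- function(x, ...) {
  if (is.na(x$icc)) {
    cat("<icc_result> undefined:", x$reason, "\n")
  } else {
    cat(sprintf("<icc_result> ICC(2,1) = %.3f, %d%% CI (%.3f, %.3f), n = %d, k = %d\n",
                x$icc, round(100 * x$conf_level), x$ci_low, x$ci_high, x$n, x$k))
  }
  invisible(x)
}
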