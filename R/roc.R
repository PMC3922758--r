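## Empirical ROC analysis and cutoff-grid diagnostics for a single
## continuous marker (typically the F-diameter) against a binary status.

check_binary <- function(labels) {
  labels <- as.integer(as.logical(labels))
  if (length(unique(labels[!is.na(labels)])) < 2L) {
    stop("both classes must be present", call. = FALSE)
  }
  labels
}

#' Empirical ROC curve and AUC
#'
#' Builds the empirical ROC over all distinct score thresholds. The area
#' under the curve is computed by the trapezoid rule, which on the empirical
#' curve equals the rank statistic (concordant pairs plus half ties over
#' `n1 * n0`). An approximate two-sided p-value for AUC = 0.5 is obtained
#' from the normal approximation to the Mann-Whitney statistic (with tie
#' correction); it is approximate by construction.
#'
#' @param scores numeric marker values.
#' @param labels binary status (logical or 0/1); `TRUE`/1 is the positive
#'   class.
#' @param direction `"higher"` (default): larger scores indicate the
#'   positive class; `"lower"` reverses this.
#' @return Object of class `roc_curve`: `points` (data frame with
#'   `threshold`, `fpr`, `tpr`), `auc`, `p_value`, `direction`, `n_pos`,
#'   `n_neg`.
#' @export
roc_curve <- function(scores, labels, direction = c("higher", "lower")) {
  direction <- match.arg(direction)
  labels <- check_binary(labels)
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]; labels <- labels[keep]
  s <- if (direction == "higher") scores else -scores

  thr <- sort(unique(s), decreasing = TRUE)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  tpr <- vapply(thr, function(t) sum(s >= t & labels == 1L) / n1, numeric(1))
  fpr <- vapply(thr, function(t) sum(s >= t & labels == 0L) / n0, numeric(1))
  pts <- rbind(data.frame(threshold = NA, fpr = 0, tpr = 0),
               data.frame(threshold = if (direction == "higher") thr else -thr,
                          fpr = fpr, tpr = tpr))
  auc <- sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) + utils::tail(pts$tpr, -1)) / 2)

  ## normal approximation to the Mann-Whitney U under H0, tie-corrected
  N <- n0 + n1
  ties <- base::table(s)
  tie_term <- sum(ties^3 - ties) / (N * (N - 1))
  varU <- n0 * n1 / 12 * ((N + 1) - tie_term)
  U <- auc * n0 * n1
  z <- (U - n0 * n1 / 2) / sqrt(varU)
  p <- if (varU <= 0) NA_real_ else 2 * stats::pnorm(-abs(z))

  structure(
    list(points = pts, auc = auc, p_value = p, direction = direction,
         n_pos = n1, n_neg = n0),
    class = "roc_curve"
  )
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("<roc_curve> AUC = %.3f (p = %.3g), %d positives / %d negatives\n",
              x$auc, x$p_value, x$n_pos, x$n_neg))
  invisible(x)
}

#' Diagnostic metrics at a single cutoff
#'
#' A record is called positive when its score is at or above the cutoff
#' (direction `"higher"`; at or below for `"lower"`). Sensitivity,
#' specificity, PPV and NPV are computed from the confusion counts; a
#' predictive value whose denominator is zero is reported as `NA`, not 0.
#'
#' @inheritParams roc_curve
#' @param cutoff numeric cutoff (same units as `scores`).
#' @return Object of class `cutoff_metrics` with the four metrics, the
#'   confusion counts `tp`, `fp`, `tn`, `fn`, and `youden` (J = sens +
#'   spec - 1).
#' @export
metrics_at_cutoff <- function(scores, labels, cutoff,
                              direction = c("higher", "lower")) {
  direction <- match.arg(direction)
  labels <- check_binary(labels)
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]; labels <- labels[keep]
  pos_call <- if (direction == "higher") scores >= cutoff else scores <= cutoff

  tp <- sum(pos_call & labels == 1L); fp <- sum(pos_call & labels == 0L)
  fn <- sum(!pos_call & labels == 1L); tn <- sum(!pos_call & labels == 0L)
  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  ppv <- if (tp + fp == 0) NA_real_ else tp / (tp + fp)
  npv <- if (tn + fn == 0) NA_real_ else tn / (tn + fn)
  structure(
    list(cutoff = cutoff, sensitivity = sens, specificity = spec,
         ppv = ppv, npv = npv, youden = sens + spec - 1,
         tp = tp, fp = fp, tn = tn, fn = fn, n = tp + fp + tn + fn,
         direction = direction),
    class = "cutoff_metrics"
  )
}

#' @export
print.cutoff_metrics <- function(x, ...) {
  cat(sprintf(
    "<cutoff_metrics> cutoff %.2f: sens %.1f%%, spec %.1f%%, PPV %s, NPV %s\n",
    x$cutoff, 100 * x$sensitivity, 100 * x$specificity,
    if (is.na(x$ppv)) "NA" else sprintf("%.1f%%", 100 * x$ppv),
    if (is.na(x$npv)) "NA" else sprintf("%.1f%%", 100 * x$npv)
  ))
  invisible(x)
}

#' Cutoff grid search
#'
#' Evaluates diagnostic metrics on the grid `start + k * step` (k positive
#' and negative) extended to span the observed score range, and returns the
#' cutoff optimising the chosen criterion. `"youden"` maximises
#' J = sensitivity + specificity - 1; `"balanced"` minimises
#' |sensitivity - specificity|. Ties go to the smaller cutoff. Both optima
#' are always reported alongside the full grid.
#'
#' @inheritParams roc_curve
#' @param start grid anchor (default 42.5 mm, a first estimate of the
#'   condition cutoff from group mean differences).
#' @param step grid increment (default 0.1 mm).
#' @param criterion `"youden"` or `"balanced"` — which optimum `best` points
#'   at.
#' @return Object of class `cutoff_grid`: `best` (a `cutoff_metrics`),
#'   `best_youden`, `best_balanced`, and `grid` (data frame over all
#'   cutoffs).
#' @export
cutoff_grid_search <- function(scores, labels, start = 42.5, step = 0.1,
                               criterion = c("youden", "balanced"),
                               direction = c("higher", "lower")) {
  criterion <- match.arg(criterion)
  direction <- match.arg(direction)
  check_binary(labels)
  keep <- !is.na(scores)
  if (!any(keep)) stop("no scores", call. = FALSE)
  rng <- range(scores[keep])
  k_lo <- floor((rng[1L] - step - start) / step)
  k_hi <- ceiling((rng[2L] + step - start) / step)
  cutoffs <- start + (k_lo:k_hi) * step
  if (!length(cutoffs)) stop("empty cutoff grid", call. = FALSE)

  rows <- lapply(cutoffs, function(ct) {
    m <- metrics_at_cutoff(scores, labels, ct, direction)
    data.frame(cutoff = ct, sensitivity = m$sensitivity,
               specificity = m$specificity, ppv = m$ppv, npv = m$npv,
               youden = m$youden)
  })
  grid <- do.call(rbind, rows)

  pick <- function(obj) { # ties -> smaller cutoff (grid is ascending)
    metrics_at_cutoff(scores, labels, grid$cutoff[which.max(obj)], direction)
  }
  best_youden <- pick(grid$youden)
  best_balanced <- pick(-abs(grid$sensitivity - grid$specificity))
  structure(
    list(best = if (criterion == "youden") best_youden else best_balanced,
         best_youden = best_youden, best_balanced = best_balanced,
         criterion = criterion, grid = grid),
    class = "cutoff_grid"
  )
}

#' @export
print.cutoff_grid <- function(x, ...) {
  cat(sprintf("<cutoff_grid> %d cutoffs, criterion '%s'\n",
              nrow(x$grid), x$criterion))
  print(x$best)
  invisible(x)
}
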