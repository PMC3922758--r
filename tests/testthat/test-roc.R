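test_that("AUC matches pair counting on simple and tied cases", {
  r1 <- roc_curve(c(1, 2, 3, 4), c(0, 0, 1, 1))
  expect_equal(r1$auc, 1)
  r2 <- roc_curve(c(1, 2, 3, 4), c(0, 1, 0, 1))
  expect_equal(r2$auc, 0.75)
  expect_equal(r2$auc, auc_pairs_oracle(c(1, 2, 3, 4), c(0, 1, 0, 1)))
  # flipping the direction maps AUC to 1 - AUC
  r3 <- roc_curve(c(1, 2, 3, 4), c(0, 1, 0, 1), direction = "lower")
  expect_equal(r3$auc, 1 - r2$auc)
  expect_error(roc_curve(1:4, c(1, 1, 1, 1)), "both classes")
})

test_that("trapezoid AUC equals the rank statistic on random data", {
  set.seed(31)
  for (i in 1:15) {
    n <- sample(20:60, 1)
    labels <- sample(0:1, n, replace = TRUE)
    if (length(unique(labels)) < 2) next
    scores <- if (i %% 2 == 0) round(rnorm(n), 1) else rnorm(n) # with/without ties
    r <- roc_curve(scores, labels)
    expect_equal(r$auc, auc_pairs_oracle(scores, labels), tolerance = 1e-12)
    # ROC points are monotone nondecreasing in both coordinates
    expect_true(all(diff(r$points$fpr) >= 0))
    expect_true(all(diff(r$points$tpr) >= 0))
    expect_true(r$auc >= 0 && r$auc <= 1)
  }
})

test_that("empirical AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(32)
  scores <- c(rnorm(60, 40, 2), rnorm(70, 43, 2.5))
  labels <- rep(c(0, 1), c(60, 70))
  mine <- roc_curve(scores, labels)$auc
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, direction = "<",
                                        quiet = TRUE)))
  expect_equal(mine, ref, tolerance = 1e-12)
})

test_that("binormal AUC converges to the closed form", {
  set.seed(33)
  n <- 5000
  scores <- c(rnorm(n, 40, 2), rnorm(n, 44, 2))
  labels <- rep(c(0, 1), each = n)
  expected <- pnorm(4 / sqrt(8))
  expect_equal(roc_curve(scores, labels)$auc, expected, tolerance = 0.02)
})

test_that("cutoff metrics come straight from the confusion counts", {
  # perfect separation
  m <- metrics_at_cutoff(c(1, 2, 8, 9), c(0, 0, 1, 1), 5)
  expect_equal(c(m$sensitivity, m$specificity, m$ppv, m$npv), rep(1, 4))
  # constructed confusion table: TP 46, FN 21, TN 44, FP 18
  scores <- c(rep(43, 46), rep(40, 21), rep(40, 44), rep(43, 18))
  labels <- rep(c(1, 1, 0, 0), c(46, 21, 44, 18))
  m2 <- metrics_at_cutoff(scores, labels, 41.8)
  expect_equal(m2$tp, 46); expect_equal(m2$fn, 21)
  expect_equal(m2$tn, 44); expect_equal(m2$fp, 18)
  expect_equal(m2$sensitivity, 46 / 67)
  expect_equal(m2$npv, 44 / 65)
  expect_equal(m2$ppv, 46 / 64)
  expect_equal(m2$specificity, 44 / 62)
  # cutoff below every score: everything called positive
  m3 <- metrics_at_cutoff(c(1, 2, 3), c(0, 1, 1), 0)
  expect_equal(m3$sensitivity, 1)
  expect_equal(m3$specificity, 0)
  # no predicted positives: PPV undefined, not zero
  m4 <- metrics_at_cutoff(c(1, 2, 3), c(0, 1, 1), 99)
  expect_true(is.na(m4$ppv))
  expect_equal(m4$n, 3)
})

test_that("sensitivity falls and specificity rises with the cutoff", {
  set.seed(34)
  scores <- rnorm(200, 42, 3)
  labels <- rbinom(200, 1, plogis((scores - 42) / 2))
  if (length(unique(labels)) < 2) skip("degenerate draw")
  cuts <- seq(35, 49, by = 0.5)
  sens <- spec <- numeric(length(cuts))
  for (i in seq_along(cuts)) {
    m <- metrics_at_cutoff(scores, labels, cuts[i])
    sens[i] <- m$sensitivity; spec[i] <- m$specificity
  }
  expect_true(all(diff(sens) <= 1e-12))
  expect_true(all(diff(spec) >= -1e-12))
})

test_that("grid search finds the binormal density-crossing optimum", {
  set.seed(35)
  n <- 2000
  scores <- c(rnorm(n, 40, 2), rnorm(n, 44, 2))
  labels <- rep(c(0, 1), each = n)
  g <- cutoff_grid_search(scores, labels, start = 42.5, step = 0.1)
  expect_lt(abs(g$best$cutoff - 42), 0.3) # equal-variance crossing at 42
  expect_identical(g$best$cutoff, g$best_youden$cutoff)
  expect_s3_class(g$grid, "data.frame")
})

test_that("degenerate identical scores give J = 0 at the smallest cutoff", {
  g <- cutoff_grid_search(rep(5, 10), rep(c(0, 1), 5), start = 5, step = 0.1)
  expect_true(all(abs(g$grid$youden) < 1e-12))
  expect_equal(g$best$cutoff, min(g$grid$cutoff))
})

test_that("grid optimum equals exhaustive evaluation at score midpoints", {
  set.seed(36)
  scores <- sample(30:55, 120, replace = TRUE) # integer gaps > grid step
  labels <- rbinom(120, 1, plogis((scores - 42) / 4))
  if (length(unique(labels)) < 2) skip("degenerate draw")
  g <- cutoff_grid_search(scores, labels, start = 42.5, step = 0.1)
  ds <- sort(unique(scores))
  mids <- c(min(ds) - 0.5, (head(ds, -1) + tail(ds, -1)) / 2, max(ds) + 0.5)
  bestJ <- max(vapply(mids, function(ct) {
    metrics_at_cutoff(scores, labels, ct)$youden
  }, numeric(1)))
  expect_equal(g$best$youden, bestJ, tolerance = 1e-12)
})
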