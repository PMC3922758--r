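make_groups <- function(values, labels) {
  data.frame(dog_id = sprintf("d%d", seq_along(values)), f_diameter = values,
             cm_grade = labels,
             cm_group = factor(paste0("CM", labels), levels = c("CM0", "CM1", "CM2")),
             stringsAsFactors = FALSE)
}

test_that("one-way ANOVA matches hand sums of squares", {
  # identical groups: no between-group variation
  tb <- make_groups(c(1, 2, 3, 1, 2, 3), rep(0:1, each = 3))
  a <- oneway_anova(tb, "f_diameter", "cm_group")
  expect_equal(a$F, 0)
  expect_equal(a$p, 1)

  tb2 <- make_groups(c(0, 0, 1, 1, 2, 2, 3, 3), rep(0:1, each = 4))
  a2 <- oneway_anova(tb2, "f_diameter", "cm_group")
  expect_equal(a2$F, anova_oracle(tb2$f_diameter, tb2$cm_group), tolerance = 1e-12)
  expect_equal(a2$F, 24) # SSB = 8 (df 1), SSW = 2 (df 6)

  set.seed(11)
  for (i in 1:10) {
    y <- rnorm(30); g <- sample(0:2, 30, replace = TRUE, prob = c(.3, .3, .4))
    if (length(unique(g)) < 2) next
    tb3 <- make_groups(y, g)
    expect_equal(oneway_anova(tb3, "f_diameter", "cm_group")$F,
                 anova_oracle(y, g), tolerance = 1e-10)
    # permutation within groups leaves F unchanged
    perm <- unlist(lapply(split(seq_along(y), g), sample))
    tb4 <- make_groups(y[perm], g[perm])
    expect_equal(oneway_anova(tb4, "f_diameter", "cm_group")$F,
                 oneway_anova(tb3, "f_diameter", "cm_group")$F, tolerance = 1e-10)
  }
})

test_that("stepwise selection keeps signal and drops noise", {
  set.seed(21)
  n <- 60
  df <- data.frame(
    x = c(rnorm(n, 0), rnorm(n, 10)),
    z = rnorm(2 * n),
    sm_status = factor(rep(c("SM_NO", "SM_YES"), each = n),
                       levels = c("SM_NO", "SM_YES"))
  )
  m <- stepwise_lda(df, c("x", "z"), "sm_status")
  expect_identical(m$variables, "x")
  expect_identical(ncol(m$coefficients), 1L)
  expect_gt(m$coefficients["x", 1], 0) # largest coefficient made positive

  # exhaustive Wilks comparison: {x} must beat {z} and adding z must fail
  # the entry threshold
  W <- function(vars) {
    X <- as.matrix(df[, vars, drop = FALSE])
    s <- sscp_oracle(X, df$sm_status)
    det(s$W) / det(s$W + s$B)
  }
  expect_lt(W("x"), W("z"))
  lam_ratio <- W(c("x", "z")) / W("x")
  f_enter_z <- ((2 * n - 2 - 1) / 1) * (1 - lam_ratio) / lam_ratio
  expect_lt(f_enter_z, 3.84)
})

test_that("no informative variable yields an empty model", {
  set.seed(22)
  df <- data.frame(z = rnorm(40),
                   sm_status = factor(rep(c("SM_NO", "SM_YES"), 20)))
  expect_warning(m <- stepwise_lda(df, "z", "sm_status"), "empty")
  expect_true(m$empty)
  df1 <- df[df$sm_status == "SM_NO", ]
  expect_error(stepwise_lda(df1, "z", "sm_status"), "two groups")
})

test_that("canonical solution equals the generalized-eigen oracle", {
  set.seed(23)
  for (i in 1:5) {
    X <- cbind(rnorm(90, rep(c(0, 2, 4), each = 30), 1.3),
               rnorm(90, rep(c(0, 1, 0.5), each = 30), 0.8))
    g <- factor(rep(c("CM0", "CM1", "CM2"), each = 30))
    df <- data.frame(v1 = X[, 1], v2 = X[, 2], cm_group = g)
    m <- stepwise_lda(df, c("v1", "v2"), "cm_group",
                      f_enter = 1e-4, f_remove = 5e-5)
    s <- sscp_oracle(X, g)
    ev <- geneigen2_oracle(s$B, s$W)
    expect_equal(unname(m$eigenvalues), ev, tolerance = 1e-6)
    dir1 <- rayleigh_direction_oracle(s$B, s$W)
    a1 <- m$coefficients[, 1]
    cosang <- abs(sum(a1 * dir1)) / sqrt(sum(a1^2) * sum(dir1^2))
    expect_gt(cosang, 1 - 1e-6)
  }
})

test_that("discriminant scores have unit pooled within-group variance", {
  set.seed(24)
  tbl <- build_sm_cohort(gen_study_table(24))
  m <- stepwise_lda(tbl, grouping = "cm_group")
  X <- as.matrix(tbl[, m$variables, drop = FALSE])
  g <- tbl$cm_group
  keep <- stats::complete.cases(as.matrix(tbl[, measurement_variables()])) & !is.na(g)
  X <- X[keep, , drop = FALSE]; g <- droplevels(g[keep])
  S <- X %*% m$coefficients + matrix(m$constants, nrow(X), ncol(m$coefficients),
                                     byrow = TRUE)
  for (j in seq_len(ncol(S))) {
    ssw <- sum(unlist(lapply(levels(g), function(lev) {
      s <- S[g == lev, j]; sum((s - mean(s))^2)
    })))
    expect_equal(ssw / (nrow(X) - nlevels(g)), 1, tolerance = 1e-8)
  }
})

test_that("three collinear groups leave the second function non-significant", {
  set.seed(25)
  X <- cbind(rnorm(150, rep(c(0, 3, 6), each = 50)),
             rnorm(150, rep(c(0, 0, 0), each = 50)))
  df <- data.frame(v1 = X[, 1], v2 = X[, 2],
                   cm_group = factor(rep(c("CM0", "CM1", "CM2"), each = 50)))
  m <- stepwise_lda(df, c("v1", "v2"), "cm_group", f_enter = 1e-4, f_remove = 5e-5)
  expect_identical(length(m$eigenvalues), 2L)
  expect_lt(m$eigenvalues[2], 0.05)
  expect_gt(m$fn_p_values[2], 0.05)
  expect_lt(m$fn_p_values[1], 1e-10)
})

test_that("classification agrees with a brute-force Mahalanobis rule", {
  set.seed(26)
  X <- cbind(rnorm(120, rep(c(0, 2, 4), each = 40), 1.5),
             rnorm(120, rep(c(0, 2, 1), each = 40), 1.2))
  g <- factor(rep(c("CM0", "CM1", "CM2"), each = 40))
  df <- data.frame(v1 = X[, 1], v2 = X[, 2], cm_group = g)
  m <- stepwise_lda(df, c("v1", "v2"), "cm_group", f_enter = 1e-4, f_remove = 5e-5)
  new <- data.frame(v1 = rnorm(50, 2, 2), v2 = rnorm(50, 1, 2))
  pred <- classify(m, new)
  mu <- lapply(levels(g), function(lev) colMeans(X[g == lev, ]))
  Sw <- m$pooled_cov
  d2 <- sapply(mu, function(mk) stats::mahalanobis(as.matrix(new), mk, Sw))
  expect_identical(as.character(pred), levels(g)[apply(d2, 1, which.min)])
})

test_that("classification ties go to the lowest group index", {
  df <- data.frame(v = c(0, 0.5, 1, 1.5, 2, 8, 8.5, 9, 9.5, 10),
                   cm_group = factor(rep(c("CM0", "CM1"), each = 5)))
  m <- stepwise_lda(df, "v", "cm_group", f_enter = 1e-4, f_remove = 5e-5)
  mid <- data.frame(v = mean(c(mean(df$v[1:5]), mean(df$v[6:10]))))
  expect_identical(as.character(classify(m, mid)), "CM0")
  # a record at a centroid classifies to that group
  at0 <- data.frame(v = mean(df$v[1:5]))
  expect_identical(as.character(classify(m, at0)), "CM0")
})

test_that("records missing a selected variable are skipped with a reason", {
  df <- data.frame(v = c(rnorm(20), rnorm(20, 8)),
                   cm_group = factor(rep(c("CM0", "CM1"), each = 20)))
  m <- stepwise_lda(df, "v", "cm_group", f_enter = 1e-4, f_remove = 5e-5)
  new <- data.frame(dog_id = c("ok", "gap"), v = c(0, NA))
  pred <- classify(m, new)
  expect_identical(as.character(pred), c("CM0", NA))
  expect_match(attr(pred, "skipped"), "gap: missing v")
})

test_that("LOOCV is perfect on separated data and chance-level on shuffled labels", {
  set.seed(27)
  df <- data.frame(v = c(rnorm(25, 0), rnorm(25, 30)),
                   sm_status = factor(rep(c("SM_NO", "SM_YES"), each = 25),
                                      levels = c("SM_NO", "SM_YES")))
  cv <- loocv(df, "v", "sm_status")
  expect_equal(cv$overall, 1)
  expect_equal(unname(cv$per_group), c(1, 1))

  shuf <- data.frame(v = rnorm(200),
                     sm_status = factor(rep(c("SM_NO", "SM_YES"), each = 100),
                                        levels = c("SM_NO", "SM_YES")))
  cv2 <- loocv(shuf, "v", "sm_status", f_enter = 0.01, f_remove = 0.005)
  expect_gte(cv2$overall, 0.4)
  expect_lte(cv2$overall, 0.6)
})

test_that("LOOCV rates are invariant to record order", {
  set.seed(28)
  df <- data.frame(v = c(rnorm(30, 0), rnorm(30, 1.5)), w = rnorm(60),
                   sm_status = factor(rep(c("SM_NO", "SM_YES"), each = 30),
                                      levels = c("SM_NO", "SM_YES")))
  cv1 <- loocv(df, c("v", "w"), "sm_status", f_enter = 0.01, f_remove = 0.005)
  perm <- sample(nrow(df))
  cv2 <- loocv(df[perm, ], c("v", "w"), "sm_status", f_enter = 0.01, f_remove = 0.005)
  expect_equal(cv2$overall, cv1$overall)
  expect_equal(cv2$per_group, cv1$per_group)
})

test_that("reference functions evaluate by direct arithmetic", {
  pf <- published_functions()
  dogs <- example_dogs()
  sc <- apply_published_functions(dogs, pf)
  expect_equal(sc$cm_function_1[sc$dog_id == "A"],
               -0.351 * 38 + 0.112 * 81.8 + 6.968, tolerance = 1e-12)
  expect_equal(sc$cm_function_1[sc$dog_id == "A"], 2.7916, tolerance = 1e-6)
  expect_equal(sc$sm_function[sc$dog_id == "H"], 2.101, tolerance = 1e-6)
  # all-zero record: scores collapse to the constants
  zero <- data.frame(dog_id = "z", f_diameter = 0, angle2 = 0, angle5 = 0)
  sz <- apply_published_functions(zero, pf)
  expect_equal(sz$cm_function_1, 6.968)
  expect_equal(sz$cm_function_2, -26.357)
  expect_equal(sz$sm_function, -10.757)
  # missing input: that score (and only that score) is NA
  gap <- data.frame(dog_id = "g", f_diameter = 40, angle2 = NA_real_, angle5 = 45)
  sg <- apply_published_functions(gap, pf)
  expect_true(is.na(sg$cm_function_1))
  expect_false(is.na(sg$sm_function))
})

test_that("parameter recovery: fitted direction approaches the Bayes direction", {
  set.seed(29)
  n <- 500
  Sig <- matrix(c(4, 1.5, 1.5, 2), 2)
  mu <- c(3, 2)
  X <- rbind(MASS::mvrnorm(n, c(0, 0), Sig), MASS::mvrnorm(n, mu, Sig))
  df <- data.frame(x1 = X[, 1], x2 = X[, 2],
                   sm_status = factor(rep(c("SM_NO", "SM_YES"), each = n),
                                      levels = c("SM_NO", "SM_YES")))
  m <- stepwise_lda(df, c("x1", "x2"), "sm_status", f_enter = 0.02, f_remove = 0.01)
  a <- m$coefficients[c("x1", "x2"), 1]
  bayes <- solve(Sig, mu)
  expect_gt(abs(sum(a * bayes)) / sqrt(sum(a^2) * sum(bayes^2)), 0.99)
})
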