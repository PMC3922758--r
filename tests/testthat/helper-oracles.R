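# Shared independent oracles and small generators used across test files.

# Brute-force constrained minimum enclosing circle: scan the centre position
# along the baseline on a fine grid and take the min-max vertex distance.
grid_circle_oracle <- function(bl, contour, step = 1e-4) {
  tp <- (contour[, 1] - bl$origin[1]) * bl$direction[1] +
    (contour[, 2] - bl$origin[2]) * bl$direction[2]
  ts <- seq(min(tp), max(tp), by = step)
  cx <- bl$origin[1] + ts * bl$direction[1]
  cy <- bl$origin[2] + ts * bl$direction[2]
  g <- rep(0, length(ts))
  for (i in seq_len(nrow(contour))) {
    g <- pmax(g, sqrt((cx - contour[i, 1])^2 + (cy - contour[i, 2])^2))
  }
  list(radius = min(g), t = ts[which.min(g)])
}

# Random dorsal contour (y > 0) over a random x span.
random_contour <- function(n_vertices = 8) {
  x <- sort(stats::runif(n_vertices, -10, 30))
  y <- stats::runif(n_vertices, 0.5, 25)
  cbind(x, y)
}

# Rigid motion (rotation by theta + translation) applied to an n x 2 matrix.
rigid <- function(m, theta, shift) {
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2)
  t(R %*% t(m)) + matrix(shift, nrow(m), 2, byrow = TRUE)
}

# Hand sums-of-squares one-way ANOVA F.
anova_oracle <- function(y, g) {
  g <- factor(g)
  grand <- mean(y)
  ssb <- sum(tapply(y, g, function(v) length(v) * (mean(v) - grand)^2))
  ssw <- sum(tapply(y, g, function(v) sum((v - mean(v))^2)))
  dfb <- nlevels(g) - 1
  dfw <- length(y) - nlevels(g)
  (ssb / dfb) / (ssw / dfw)
}

# Within/total SSCP for the generalized-eigen oracle.
sscp_oracle <- function(X, g) {
  g <- factor(g)
  Tm <- crossprod(scale(X, scale = FALSE))
  W <- matrix(0, ncol(X), ncol(X))
  for (lev in levels(g)) {
    W <- W + crossprod(scale(X[g == lev, , drop = FALSE], scale = FALSE))
  }
  list(W = W, B = Tm - W)
}

# Eigenvalues of W^{-1} B for p = 2 via the characteristic polynomial
# det(B - lambda W) = 0 (quadratic), solved in closed form.
geneigen2_oracle <- function(B, W) {
  c2 <- det(W)
  c1 <- -(B[1, 1] * W[2, 2] + B[2, 2] * W[1, 1] -
            B[1, 2] * W[2, 1] - B[2, 1] * W[1, 2])
  c0 <- det(B)
  disc <- sqrt(max(c1^2 - 4 * c2 * c0, 0))
  sort((-c1 + c(-1, 1) * disc) / (2 * c2), decreasing = TRUE)
}

# Leading generalized eigenvector by maximizing the Rayleigh quotient
# a'Ba / a'Wa over the direction angle (1-D scan + refine).
rayleigh_direction_oracle <- function(B, W) {
  q <- function(th) {
    a <- c(cos(th), sin(th))
    drop(a %*% B %*% a) / drop(a %*% W %*% a)
  }
  coarse <- seq(0, pi, length.out = 2000)
  th0 <- coarse[which.max(vapply(coarse, q, numeric(1)))]
  opt <- stats::optimize(q, c(th0 - 0.01, th0 + 0.01), maximum = TRUE, tol = 1e-12)
  c(cos(opt$maximum), sin(opt$maximum))
}

# AUC by brute-force pair counting (concordant + half ties).
auc_pairs_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

# Two-way ANOVA variance-component ICC(2,1) oracle (independent route via
# explicit cell-by-cell decomposition).
icc_oracle <- function(m) {
  n <- nrow(m); k <- ncol(m)
  grand <- mean(m)
  msr <- k / (n - 1) * sum((rowMeans(m) - grand)^2)
  msc <- n / (k - 1) * sum((colMeans(m) - grand)^2)
  sse <- 0
  for (i in 1:n) for (j in 1:k) {
    sse <- sse + (m[i, j] - rowMeans(m)[i] - colMeans(m)[j] + grand)^2
  }
  mse <- sse / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + k / n * (msc - mse))
}

# Cohort-shaped measurement frame without the generator (direct assembly).
quick_table <- function(n, sm, age, cm = NULL, f = NULL) {
  data.frame(
    dog_id = sprintf("d%03d", seq_len(n)),
    age_years = age, sm_grade = sm,
    cm_grade = if (is.null(cm)) rep(1L, n) else cm,
    f_diameter = if (is.null(f)) stats::runif(n, 35, 48) else f,
    stringsAsFactors = FALSE
  )
}
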