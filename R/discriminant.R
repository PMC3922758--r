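## One-way ANOVA screening, stepwise Wilks-lambda canonical discriminant
## analysis, nearest-centroid classification and leave-one-out
## cross-validation.

grouping_vector <- function(table, grouping = c("cm_group", "sm_status")) {
  grouping <- match.arg(grouping)
  if (!grouping %in% names(table)) {
    stop("table lacks a '", grouping, "' column; run build_sm_cohort() first",
         call. = FALSE)
  }
  g <- table[[grouping]]
  if (grouping == "sm_status") {
    g[g == "EXCLUDED"] <- NA # excluded dogs never enter an analysis
    g <- droplevels(factor(g, levels = c("SM_NO", "SM_YES")))
  }
  g
}

#' One-way analysis of variance for a single variable
#'
#' Classical between/within mean-square F ratio across the CM groups or the
#' SM status groups, after listwise deletion of records missing that
#' variable (or the group). Fitting is delegated to `stats::lm`/`anova`.
#'
#' @param table a [build_sm_cohort()] cohort table.
#' @param variable measurement column name, e.g. `"f_diameter"`.
#' @param grouping `"cm_group"` or `"sm_status"`.
#' @return Object of class `anova_result`: `variable`, `F`, `p`, `df`,
#'   `group_means`, `n_per_group`.
#' @export
oneway_anova <- function(table, variable, grouping = c("cm_group", "sm_status")) {
  grouping <- match.arg(grouping)
  stopifnot(variable %in% names(table))
  g <- grouping_vector(table, grouping)
  y <- table[[variable]]
  keep <- !is.na(y) & !is.na(g)
  y <- y[keep]; g <- droplevels(g[keep])
  cnt <- base::table(g)
  if (nlevels(g) < 2L) stop("fewer than two groups after listwise deletion", call. = FALSE)
  if (any(cnt < 2L)) {
    stop("group ", names(cnt)[cnt < 2L][1L], " has fewer than two observations",
         call. = FALSE)
  }
  at <- stats::anova(stats::lm(y ~ g))
  Fv <- at$`F value`[1L]
  if (!is.finite(Fv)) Fv <- 0
  structure(
    list(variable = variable, F = Fv,
         p = if (Fv == 0) 1 else at$`Pr(>F)`[1L],
         df = c(between = at$Df[1L], within = at$Df[2L]),
         group_means = tapply(y, g, mean),
         n_per_group = as.vector(cnt, mode = "integer")),
    class = "anova_result"
  )
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("<anova_result> %s: F(%d, %d) = %.3f, p = %.4g\n",
              x$variable, x$df[1L], x$df[2L], x$F, x$p))
  invisible(x)
}

## Within-group (W) and total (T) SSCP matrices for columns X given groups g.
sscp_matrices <- function(X, g) {
  Xc_tot <- scale(X, center = TRUE, scale = FALSE)
  Tm <- crossprod(Xc_tot)
  W <- matrix(0, ncol(X), ncol(X))
  for (lev in levels(g)) {
    Xi <- X[g == lev, , drop = FALSE]
    Xi <- scale(Xi, center = TRUE, scale = FALSE)
    W <- W + crossprod(Xi)
  }
  dimnames(W) <- dimnames(Tm) <- list(colnames(X), colnames(X))
  list(W = W, T = Tm, B = Tm - W)
}

wilks_lambda <- function(X, g, vars) {
  if (!length(vars)) return(1)
  m <- sscp_matrices(X[, vars, drop = FALSE], g)
  dW <- det(m$W); dT <- det(m$T)
  if (dT <= 0) return(NA_real_)
  dW / dT
}

## Partial F for adding one variable to a selected set of size p
## (g groups, n cases): F = ((n - g - p) / (g - 1)) * (1 - l) / l,
## with l = Lambda(selected + v) / Lambda(selected).
partial_f <- function(lambda_ratio, n, g, p) {
  if (is.na(lambda_ratio) || lambda_ratio <= 0) return(Inf)
  if (lambda_ratio >= 1) return(0)
  ((n - g - p) / (g - 1)) * (1 - lambda_ratio) / lambda_ratio
}

#' Stepwise canonical discriminant analysis (Wilks' lambda)
#'
#' Forward-stepping with removal: at each step the candidate variable with
#' the largest partial F enters if it reaches `f_enter`; after every entry,
#' any selected variable whose partial F falls below `f_remove` is removed.
#' On the selected variables the canonical functions are obtained from the
#' eigen-decomposition of the within-to-between problem; coefficient vectors
#' are scaled so discriminant scores have pooled within-group variance 1,
#' each function's constant is minus the coefficients times the grand mean,
#' and functions are ordered by eigenvalue. Function-wise significance uses
#' Bartlett's chi-square approximation. Listwise deletion over the candidate
#' variables is applied first and reported.
#'
#' @param table cohort table.
#' @param variables candidate variable labels (default all 15).
#' @param grouping `"cm_group"` or `"sm_status"`.
#' @param f_enter,f_remove partial-F thresholds (classic defaults 3.84 and
#'   2.71); `f_remove` must be below `f_enter`.
#' @param priors `"equal"` or `"proportional"` (used by [classify()]).
#' @param sign_convention `"largest_positive"` (default) flips each function
#'   so its largest-magnitude coefficient is positive; `"none"` keeps the raw
#'   eigenvector orientation.
#' @return Object of class `discriminant_model` with fields `variables`
#'   (in order of entry), `coefficients` (p x m), `constants`, `centroids`,
#'   `eigenvalues`, `fn_p_values`, `priors`, `pooled_cov`, `grand_mean`,
#'   `n_used`, `n_dropped`, `levels`.
#' @export
stepwise_lda <- function(table, variables = measurement_variables(),
                         grouping = c("cm_group", "sm_status"),
                         f_enter = 3.84, f_remove = 2.71,
                         priors = c("equal", "proportional"),
                         sign_convention = c("largest_positive", "none")) {
  grouping <- match.arg(grouping)
  priors <- match.arg(priors)
  sign_convention <- match.arg(sign_convention)
  if (f_remove >= f_enter) stop("f_remove must be below f_enter", call. = FALSE)
  variables <- intersect(variables, names(table))
  if (!length(variables)) stop("no candidate variables present in table", call. = FALSE)

  g <- grouping_vector(table, grouping)
  X <- as.matrix(table[, variables, drop = FALSE])
  keep <- stats::complete.cases(X) & !is.na(g)
  n_dropped <- sum(!keep)
  X <- X[keep, , drop = FALSE]
  g <- droplevels(g[keep])
  n <- nrow(X); ng <- nlevels(g)
  if (ng < 2L) stop("need at least two groups", call. = FALSE)

  ## --- stepwise selection ---
  selected <- character(0)
  history <- character(0)
  lambda_sel <- 1
  repeat {
    moved <- FALSE
    candidates <- setdiff(variables, selected)
    if (length(candidates)) {
      lam <- vapply(candidates, function(v) {
        wilks_lambda(X, g, c(selected, v))
      }, numeric(1))
      Fs <- vapply(lam / lambda_sel, partial_f, numeric(1),
                   n = n, g = ng, p = length(selected))
      best <- which.max(Fs)
      if (length(best) && Fs[best] >= f_enter) {
        selected <- c(selected, candidates[best])
        lambda_sel <- lam[best]
        history <- c(history, paste0("+", candidates[best]))
        moved <- TRUE
      }
    }
    if (length(selected) > 1L) {
      repeat {
        lam_wo <- vapply(selected, function(v) {
          wilks_lambda(X, g, setdiff(selected, v))
        }, numeric(1))
        Fs_rm <- vapply(lambda_sel / lam_wo, partial_f, numeric(1),
                        n = n, g = ng, p = length(selected) - 1L)
        worst <- which.min(Fs_rm)
        if (Fs_rm[worst] < f_remove) {
          history <- c(history, paste0("-", selected[worst]))
          lambda_sel <- lam_wo[worst]
          selected <- setdiff(selected, selected[worst])
        } else break
      }
    }
    if (!moved || length(history) > 10 * length(variables)) break
  }

  if (!length(selected)) {
    out <- structure(
      list(variables = character(0), empty = TRUE, levels = levels(g),
           n_used = n, n_dropped = n_dropped, history = history),
      class = "discriminant_model"
    )
    warning("no variable reached f_enter; returning an empty model")
    return(out)
  }

  fit <- canonical_fit(X[, selected, drop = FALSE], g,
                       sign_convention = sign_convention)
  pr <- if (priors == "equal") {
    rep(1 / ng, ng)
  } else {
    as.vector(base::table(g)) / n
  }
  names(pr) <- levels(g)

  structure(
    c(fit,
      list(variables = selected, empty = FALSE, priors = pr,
           prior_type = priors, grouping = grouping,
           n_used = n, n_dropped = n_dropped, history = history,
           f_enter = f_enter, f_remove = f_remove)),
    class = "discriminant_model"
  )
}

## Canonical discriminant solution on a fixed variable set. Returns
## coefficients scaled to unit pooled within-group variance, constants,
## centroids, eigenvalues and Bartlett p-values.
canonical_fit <- function(X, g, sign_convention = "largest_positive") {
  n <- nrow(X); ng <- nlevels(g); p <- ncol(X)
  m <- sscp_matrices(X, g)
  Sw <- m$W / (n - ng) # pooled within-group covariance
  ## symmetric reduction: W^{-1} B via Cholesky of W
  R <- tryCatch(chol(m$W), error = function(e) {
    stop("singular pooled within-group SSCP; remove collinear variables",
         call. = FALSE)
  })
  Ri <- backsolve(R, diag(p))
  M <- t(Ri) %*% m$B %*% Ri
  M <- (M + t(M)) / 2
  es <- eigen(M, symmetric = TRUE)
  m_fn <- min(ng - 1L, p)
  ord <- seq_len(m_fn)
  evals <- pmax(es$values[ord], 0)
  A <- Ri %*% es$vectors[, ord, drop = FALSE] # raw directions
  ## scale: score variance (pooled within) = a' Sw a = 1
  for (j in seq_len(m_fn)) {
    s <- sqrt(drop(t(A[, j]) %*% Sw %*% A[, j]))
    A[, j] <- A[, j] / s
    if (sign_convention == "largest_positive") {
      k <- which.max(abs(A[, j]))
      if (A[k, j] < 0) A[, j] <- -A[, j]
    }
  }
  rownames(A) <- colnames(X)
  colnames(A) <- paste0("fn", seq_len(m_fn))
  grand <- colMeans(X)
  consts <- -drop(t(A) %*% grand)
  scores <- X %*% A + matrix(consts, n, m_fn, byrow = TRUE)
  centroids <- apply(scores, 2L, function(s) tapply(s, g, mean))
  centroids <- matrix(centroids, nrow = ng,
                      dimnames = list(levels(g), colnames(A)))
  ## Bartlett chi-square for functions k..m
  fn_p <- vapply(seq_len(m_fn), function(k) {
    V <- (n - 1 - (p + ng) / 2) * sum(log(1 + evals[k:m_fn]))
    df <- (p - k + 1) * (ng - k)
    stats::pchisq(V, df, lower.tail = FALSE)
  }, numeric(1))

  list(coefficients = A, constants = consts, centroids = centroids,
       eigenvalues = evals, fn_p_values = fn_p,
       pooled_cov = Sw, grand_mean = grand, levels = levels(g))
}

#' @export
print.discriminant_model <- function(x, ...) {
  if (isTRUE(x$empty)) {
    cat("<discriminant_model> empty (no variable reached f_enter)\n")
    return(invisible(x))
  }
  cat(sprintf("<discriminant_model> %d function(s) on %s\n",
              ncol(x$coefficients), paste(x$variables, collapse = " + ")))
  for (j in seq_len(ncol(x$coefficients))) {
    terms <- sprintf("%+.3f*%s", x$coefficients[, j], x$variables)
    cat(sprintf("  D%d = %s %+0.3f   [p = %.3g]\n",
                j, paste(terms, collapse = " "), x$constants[j], x$fn_p_values[j]))
  }
  cat(sprintf("  n used = %d (dropped %d, listwise)\n", x$n_used, x$n_dropped))
  invisible(x)
}

#' Classify records with a discriminant model
#'
#' Projects each record into discriminant-score space and assigns the group
#' whose centroid is nearest (squared distance penalised by `-2 log prior`
#' for proportional priors). Exact ties go to the lowest group index.
#' Records missing a selected variable get `NA` with the reason recorded in
#' the `"skipped"` attribute.
#'
#' @param model a [stepwise_lda()] model.
#' @param newdata data frame containing the model's variables.
#' @return Factor of group labels (levels as in the training grouping).
#' @export
classify <- function(model, newdata) {
  stopifnot(inherits(model, "discriminant_model"))
  if (isTRUE(model$empty)) stop("cannot classify with an empty model", call. = FALSE)
  X <- as.matrix(newdata[, model$variables, drop = FALSE])
  out <- rep(NA_character_, nrow(X))
  skipped <- character(0)
  ok <- stats::complete.cases(X)
  if (any(!ok)) {
    ids <- if ("dog_id" %in% names(newdata)) newdata$dog_id[!ok] else which(!ok)
    skipped <- paste0(ids, ": missing ", vapply(which(!ok), function(i) {
      paste(model$variables[is.na(X[i, ])], collapse = ",")
    }, character(1)))
  }
  if (any(ok)) {
    S <- X[ok, , drop = FALSE] %*% model$coefficients +
      matrix(model$constants, sum(ok), ncol(model$coefficients), byrow = TRUE)
    penalty <- -2 * log(model$priors)
    d2 <- sapply(seq_len(nrow(model$centroids)), function(k) {
      rowSums((S - matrix(model$centroids[k, ], nrow(S), ncol(S), byrow = TRUE))^2) +
        penalty[k]
    })
    d2 <- matrix(d2, nrow = sum(ok))
    out[ok] <- model$levels[apply(d2, 1L, which.min)] # which.min: first = lowest index
  }
  res <- factor(out, levels = model$levels)
  attr(res, "skipped") <- skipped
  res
}

#' Leave-one-out cross-validated classification rates
#'
#' The variable set is fixed from the full-data stepwise fit (the standard
#' behaviour of classical discriminant software); for every record the
#' canonical coefficients are refitted without it and the held-out record is
#' classified. `strict_selection = TRUE` instead redoes the stepwise
#' selection inside every fold.
#'
#' @inheritParams stepwise_lda
#' @param strict_selection redo variable selection per fold (slow,
#'   non-default).
#' @return Object of class `loocv_result`: `overall` rate, `per_group`
#'   rates, `confusion` matrix, `n`, and the full-data `model`.
#' @export
loocv <- function(table, variables = measurement_variables(),
                  grouping = c("cm_group", "sm_status"),
                  f_enter = 3.84, f_remove = 2.71,
                  priors = c("equal", "proportional"),
                  strict_selection = FALSE) {
  grouping <- match.arg(grouping)
  priors <- match.arg(priors)
  model <- stepwise_lda(table, variables, grouping,
                        f_enter = f_enter, f_remove = f_remove, priors = priors)
  if (isTRUE(model$empty)) stop("stepwise selection produced an empty model", call. = FALSE)

  g <- grouping_vector(table, grouping)
  vars_all <- intersect(variables, names(table))
  Xall <- as.matrix(table[, vars_all, drop = FALSE])
  keep <- stats::complete.cases(Xall) & !is.na(g)
  Xall <- Xall[keep, , drop = FALSE]
  g <- droplevels(g[keep])
  n <- nrow(Xall); ng <- nlevels(g)

  pred <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    gi <- droplevels(g[-i])
    if (nlevels(gi) < ng) { # left-out record was the last of its group
      pred[i] <- NA
      next
    }
    vars_i <- model$variables
    if (strict_selection) {
      df_i <- as.data.frame(Xall[-i, , drop = FALSE])
      df_i[[grouping]] <- g[-i]
      m_i <- suppressWarnings(
        stepwise_lda(df_i, vars_all, grouping, f_enter = f_enter,
                     f_remove = f_remove, priors = priors)
      )
      if (isTRUE(m_i$empty)) { pred[i] <- NA; next }
      vars_i <- m_i$variables
    }
    fit <- canonical_fit(Xall[-i, vars_i, drop = FALSE], gi)
    pr <- if (priors == "equal") rep(1 / ng, ng) else as.vector(base::table(gi)) / (n - 1)
    sub <- list(coefficients = fit$coefficients, constants = fit$constants,
                centroids = fit$centroids, priors = stats::setNames(pr, fit$levels),
                levels = fit$levels, variables = vars_i, empty = FALSE)
    class(sub) <- "discriminant_model"
    pred[i] <- as.character(classify(sub, as.data.frame(Xall[i, , drop = FALSE])))
  }

  pred <- factor(pred, levels = levels(g))
  confusion <- base::table(actual = g, predicted = pred, useNA = "no")
  correct <- !is.na(pred) & pred == g
  per_group <- vapply(split(correct, g), mean, numeric(1))
  structure(
    list(overall = mean(correct), per_group = per_group,
         n_per_group = as.vector(base::table(g)), confusion = confusion,
         n = n, model = model),
    class = "loocv_result"
  )
}

#' @export
print.loocv_result <- function(x, ...) {
  cat(sprintf("<loocv_result> overall correct classification %.1f%% (n = %d)\n",
              100 * x$overall, x$n))
  for (lev in names(x$per_group)) {
    cat(sprintf("  %s: %.1f%%\n", lev, 100 * x$per_group[[lev]]))
  }
  invisible(x)
}
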