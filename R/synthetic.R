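## Seeded generators for every input the pipeline consumes: group-structured
## measurement tables, forward-constructed landmark geometries with known
## measurement values, and rater-replicate matrices for ICC studies.
## Every generator is a pure function of (specification, seed).

#' Specification of one synthetic dog group
#'
#' @param label group label (used to build dog ids).
#' @param n number of dogs (>= 1).
#' @param mean named mean vector over the 15 measurement variables (any
#'   subset; unnamed variables fall back to the package's base means).
#' @param cov covariance matrix over the same variables; default diagonal
#'   from `sd`.
#' @param sd named vector of standard deviations (used when `cov` is NULL).
#' @param cm_grade,sm_grade grades assigned to every dog of the group.
#' @param age_range uniform age range (years) for non-young dogs.
#' @param n_young how many of the `n` dogs get a "young" age.
#' @param young_range uniform age range for the young dogs.
#' @return Object of class `group_spec`.
#' @export
group_spec <- function(label, n, mean, cov = NULL, sd = NULL,
                       cm_grade = NA_integer_, sm_grade = NA_integer_,
                       age_range = c(3, 12.6), n_young = 0L,
                       young_range = c(1.1, 2.95)) {
  if (n < 1L) stop("group '", label, "': n must be >= 1", call. = FALSE)
  if (n_young > n) stop("n_young cannot exceed n", call. = FALSE)
  vars <- measurement_variables()
  mu <- base_means()
  mu[names(mean)] <- mean
  mu <- mu[vars]
  if (is.null(cov)) {
    s <- base_sds()
    if (!is.null(sd)) s[names(sd)] <- sd
    cov <- diag(s[vars]^2)
    dimnames(cov) <- list(vars, vars)
  } else {
    cov <- as.matrix(cov)
    if (!isTRUE(all.equal(cov, t(cov))) || any(eigen(cov, symmetric = TRUE,
                                                     only.values = TRUE)$values < -1e-8)) {
      stop("covariance must be symmetric positive semi-definite", call. = FALSE)
    }
  }
  structure(
    list(label = label, n = as.integer(n), mean = mu, cov = cov,
         cm_grade = as.integer(cm_grade), sm_grade = as.integer(sm_grade),
         age_range = age_range, n_young = as.integer(n_young),
         young_range = young_range),
    class = "group_spec"
  )
}

## Base means/SDs for the 15 variables (mm / degrees); anchored on the five
## significant variables of the 14 printed example dogs, with plausible
## small-breed values for the remainder. Illustrative, not population
## parameters.
base_means <- function() {
  c(f_diameter = 40, ab = 27, ac = 34, ad = 46, ae = 30.7, ah = 36, ai = 24,
    bc = 12, bd = 25, fg = 30,
    angle1 = 100, angle2 = 76, angle3 = 82, angle4 = 50, angle5 = 46)
}

base_sds <- function() {
  c(f_diameter = 4.5, ab = 2.5, ac = 2.5, ad = 2.5, ae = 2.5, ah = 2.5,
    ai = 2.5, bc = 2.5, bd = 2.5, fg = 2.5,
    angle1 = 7, angle2 = 7, angle3 = 7, angle4 = 7, angle5 = 7)
}

#' Default study-shaped group specification
#'
#' Nine CM-by-SM joint groups reproducing the study margins: 155 dogs, CM
#' groups of 31/32/92, SM grades 55/33/67 with exactly 20 grade-0 dogs under
#' three years of age (so the SM cohort builder retains 135). Group mean
#' shifts on F-diameter, angle 2, angle 5, AE and angle 3 are anchored on
#' the printed example dogs; all other variables carry no group effect.
#'
#' @return List of [group_spec()] objects.
#' @export
default_study_specs <- function() {
  cm_f <- c(`0` = 0, `1` = 0.8, `2` = 1.6)
  cm_a2 <- c(`0` = 0, `1` = -2, `2` = -8)
  sm_f <- c(`0` = 0, `1` = 0.4, `2` = 3.5)
  sm_a5 <- c(`0` = 0, `1` = -0.8, `2` = -3.7)
  sm_ae <- c(`0` = 0, `1` = 0.3, `2` = 3)
  sm_a3 <- c(`0` = 0, `1` = 1, `2` = 3)
  layout <- list( # cm, sm, n, n_young
    c(0, 0, 25, 5), c(0, 1, 4, 0), c(0, 2, 2, 0),
    c(1, 0, 18, 7), c(1, 1, 8, 0), c(1, 2, 6, 1),
    c(2, 0, 12, 8), c(2, 1, 21, 2), c(2, 2, 59, 10)
  )
  lapply(layout, function(row) {
    cm <- as.character(row[1L]); sm <- as.character(row[2L])
    group_spec(
      label = sprintf("cm%s_sm%s", cm, sm),
      n = row[3L], n_young = row[4L],
      mean = c(f_diameter = 40 + cm_f[[cm]] + sm_f[[sm]],
               angle2 = 76 + cm_a2[[cm]],
               angle5 = 46 + sm_a5[[sm]],
               ae = 30.7 + sm_ae[[sm]],
               angle3 = 82 + sm_a3[[sm]]),
      cm_grade = row[1L], sm_grade = row[2L]
    )
  })
}

#' Generate a group-structured measurement table
#'
#' Seeded multivariate-normal draws per group; rows violating the
#' measurement contracts (non-positive lengths, angles outside (0, 180])
#' are redrawn. Grades and ages are attached per the group rule.
#'
#' @param specs list of [group_spec()] objects.
#' @param seed integer seed (all randomness derives from it).
#' @param missing optional list of `list(vars = <labels>, n = <count>)`
#'   entries; each blanks the named variables in `n` randomly chosen rows
#'   (emulating unreadable scans).
#' @return Measurement data frame (validated).
#' @export
gen_measurement_table <- function(specs, seed, missing = NULL) {
  stopifnot(length(specs) >= 1L)
  for (sp in specs) if (!inherits(sp, "group_spec")) stop("specs must be group_spec objects")
  set.seed(as.integer(seed))
  vars <- measurement_variables()
  angle_vars <- grep("^angle", vars, value = TRUE)

  blocks <- lapply(specs, function(sp) {
    X <- MASS::mvrnorm(sp$n, mu = sp$mean, Sigma = sp$cov)
    X <- matrix(X, nrow = sp$n, dimnames = list(NULL, vars))
    for (tries in seq_len(100L)) {
      bad <- apply(X, 1L, function(r) {
        any(r[setdiff(vars, angle_vars)] <= 0) ||
          any(r[angle_vars] <= 0 | r[angle_vars] > 180)
      })
      if (!any(bad)) break
      X[bad, ] <- MASS::mvrnorm(sum(bad), mu = sp$mean, Sigma = sp$cov)
    }
    ages <- stats::runif(sp$n, sp$age_range[1L], sp$age_range[2L])
    if (sp$n_young > 0L) {
      ages[seq_len(sp$n_young)] <- stats::runif(sp$n_young, sp$young_range[1L],
                                                sp$young_range[2L])
    }
    df <- data.frame(dog_id = sprintf("%s_%03d", sp$label, seq_len(sp$n)),
                     age_years = ages, cm_grade = sp$cm_grade,
                     sm_grade = sp$sm_grade, stringsAsFactors = FALSE)
    cbind(df, as.data.frame(X))
  })
  out <- do.call(rbind, blocks)
  rownames(out) <- NULL
  if (!is.null(missing)) {
    for (mspec in missing) {
      rows <- sample(nrow(out), mspec$n)
      for (v in mspec$vars) out[rows, v] <- NA_real_
    }
  }
  validate_measurements(out)
  out
}

#' Study-shaped synthetic table
#'
#' Convenience wrapper: [default_study_specs()] through
#' [gen_measurement_table()], with the study's missingness pattern (five
#' dogs without optic-canal variables fg/angle4/angle5, eleven without
#' line AH).
#'
#' @param seed integer seed.
#' @return Measurement data frame with 155 rows.
#' @export
gen_study_table <- function(seed) {
  gen_measurement_table(
    default_study_specs(), seed,
    missing = list(list(vars = c("fg", "angle4", "angle5"), n = 5L),
                   list(vars = "ah", n = 11L))
  )
}

#' Template for a forward-constructed landmark geometry
#'
#' @param dog_id identifier.
#' @param f_diameter target occipital-circle diameter (mm).
#' @param angle2,angle5 target angles (degrees, in (0, 180)); hit exactly by
#'   closed-form placement of C and G.
#' @param base_length distance H to A (mm).
#' @param f_offset distance from A to the circle centre F along the extended
#'   base line (mm).
#' @param ac,fg distances A-C and F-G (mm).
#' @param n_arc number of occipital-contour vertices (placed on the target
#'   circle, symmetric about the vertical through F, so the constrained fit
#'   recovers the circle exactly).
#' @param jitter_sd Gaussian jitter (mm) applied to every coordinate.
#' @param seed seed used when `jitter_sd > 0`.
#' @return Object of class `geometry_template`.
#' @export
geometry_template <- function(dog_id = "sim", f_diameter = 40, angle2 = 70,
                              angle5 = 46, base_length = 60, f_offset = 15,
                              ac = 30, fg = 28, n_arc = 7L, jitter_sd = 0,
                              seed = 1L) {
  if (f_diameter <= 0) stop("f_diameter must be positive", call. = FALSE)
  for (a in c(angle2, angle5)) {
    if (a <= 0 || a >= 180) stop("target angles must lie in (0, 180)", call. = FALSE)
  }
  if (base_length <= 0 || f_offset <= 0 || ac <= 0 || fg <= 0) {
    stop("lengths must be positive", call. = FALSE)
  }
  structure(
    list(dog_id = dog_id, f_diameter = f_diameter, angle2 = angle2,
         angle5 = angle5, base_length = base_length, f_offset = f_offset,
         ac = ac, fg = fg, n_arc = n_arc, jitter_sd = jitter_sd, seed = seed),
    class = "geometry_template"
  )
}

#' Forward-construct a landmark set with known measurement values
#'
#' Places H at the origin and A on the positive x axis (the base line),
#' chooses F on the extended base line with radius `f_diameter / 2`, emits
#' the occipital contour as vertices on that circle (symmetric about the
#' vertical through F, which guarantees the constrained minimum enclosing
#' circle recovers it), places C and G in closed form so angles 2 and 5 hit
#' their targets exactly, places B and D at plausible fixed offsets, and
#' adds a cerebellar contour that crosses the circle so point E exists.
#' Optional Gaussian jitter perturbs every coordinate afterwards.
#'
#' @param t a [geometry_template()].
#' @return A [landmark_set()].
#' @export
gen_landmark_geometry <- function(t) {
  stopifnot(inherits(t, "geometry_template"))
  r <- t$f_diameter / 2
  jitter <- t$jitter_sd > 0
  if (jitter) set.seed(as.integer(t$seed))
  jit <- function(m) {
    if (jitter) m + stats::rnorm(length(m), 0, t$jitter_sd) else m
  }

  ## pose: the base line itself is jittered first; everything the circle
  ## construction depends on is then built relative to the jittered frame,
  ## so the target diameter remains the construction's exact ground truth
  H <- jit(c(0, 0))
  A <- jit(c(t$base_length, 0))
  d <- (A - H) / sqrt(sum((A - H)^2))
  nv <- c(-d[2L], d[1L]) # dorsal normal
  frame <- function(th) cbind(cos(th), sin(th)) %*% rbind(d, nv)

  Fc <- A + t$f_offset * d
  ## occipital contour on the circle, symmetric about the dorsal normal
  ## through F; under jitter the vertices slide tangentially along the
  ## boundary (radial noise on these extreme points would instead bias the
  ## enclosing-circle fit upward by the expected maximum of the errors)
  th <- seq(35, 145, length.out = max(3L, t$n_arc)) * pi / 180
  if (jitter) th <- th + stats::rnorm(length(th), 0, t$jitter_sd / r)
  occ <- matrix(Fc, length(th), 2L, byrow = TRUE) + r * frame(th)
  ## C: rotate the A->F direction by angle2, dorsal side (exact placement;
  ## jitter applied on top)
  a2 <- t$angle2 * pi / 180
  C <- jit(A + t$ac * drop(frame(a2)))
  ## G: at F the ray to A points along -d; rotate by angle5 dorsally
  a5 <- t$angle5 * pi / 180
  G <- jit(Fc + t$fg * drop(frame(pi - a5)))
  ## B, D: plausible offsets (angles 1, 3, 4 emerge, not targeted)
  B <- jit(A + 14 * d - 3 * nv)
  D <- jit(Fc + 0.6 * r * d + 1.2 * r * nv)
  ## cerebellar dorsum: from inside the circle to outside, crossing it
  cer <- jit(rbind(Fc + drop(-0.3 * r * d + 0.4 * r * nv),
                   Fc + drop(0.1 * r * d + 0.8 * r * nv),
                   Fc + drop(0.5 * r * d + 1.2 * r * nv)))
  landmark_set(
    dog_id = t$dog_id,
    points = list(A = A, B = B, C = C, D = D, G = G, H = H),
    occipital_dorsum = occ, cerebellum_dorsum = cer
  )
}

#' Generate a rater-replicate ratings matrix with known reliability
#'
#' Simulates the two-way random model `y_ij = mu + s_i + r_j + e_ij` with
#' variance components solved so the population ICC(2,1) equals `true_icc`:
#' the subject variance is `true_icc / (1 - true_icc)` times the sum of the
#' rater and error variances.
#'
#' @param true_icc target population ICC, in (0, 1).
#' @param n subjects; `k` repeated measurements.
#' @param k number of measurement columns.
#' @param seed integer seed.
#' @param mean grand mean (default 30, a line-AE-like value in mm).
#' @param error_sd residual SD (mm); `rater_sd` defaults to 30% of it.
#' @param rater_sd systematic between-measurement SD.
#' @return n x k numeric matrix.
#' @export
gen_rater_data <- function(true_icc, n, k, seed, mean = 30,
                           error_sd = 0.5, rater_sd = 0.3 * error_sd) {
  if (is.na(true_icc) || true_icc <= 0 || true_icc >= 1) {
    stop("true_icc must lie strictly inside (0, 1); the requested reliability is unattainable otherwise",
         call. = FALSE)
  }
  stopifnot(n >= 2L, k >= 2L)
  set.seed(as.integer(seed))
  noise_var <- rater_sd^2 + error_sd^2
  subj_sd <- sqrt(true_icc / (1 - true_icc) * noise_var)
  s <- stats::rnorm(n, 0, subj_sd)
  r <- stats::rnorm(k, 0, rater_sd)
  e <- matrix(stats::rnorm(n * k, 0, error_sd), n, k)
  mean + outer(s, rep(1, k)) + outer(rep(1, n), r) + e
}
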