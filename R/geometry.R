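## Geometric construction of the measurement framework: cranial base line
## (H -> A, extended), occipital-lobe circle centred on that line, derived
## points E, F, I, and the line/angle variables.

#' Cranial base line through two landmarks
#'
#' The base line runs through H (most caudal point of the olfactory bulb) and
#' A (dorsum of the spheno-occipital synchondrosis) and is extended beyond A.
#'
#' @param origin,towards length-2 numeric points (mm); for the cranial base
#'   line these are H and A.
#' @return An object of class `baseline`: origin plus unit direction vector.
#' @export
baseline_through <- function(origin, towards) {
  origin <- as_point(origin, "origin")
  towards <- as_point(towards, "towards")
  d <- towards - origin
  len <- sqrt(sum(d^2))
  if (len == 0) stop("degenerate baseline: the two landmarks coincide", call. = FALSE)
  structure(list(origin = origin, direction = d / len), class = "baseline")
}

## Scalar projection parameter t of points onto the baseline (mm from origin)
## and the perpendicular (signed, +ve to the left of the direction) offset.
project_t <- function(bl, pts) {
  pts <- matrix(pts, ncol = 2L)
  (pts[, 1L] - bl$origin[1L]) * bl$direction[1L] +
    (pts[, 2L] - bl$origin[2L]) * bl$direction[2L]
}

signed_offset <- function(bl, pts) {
  pts <- matrix(pts, ncol = 2L)
  n <- c(-bl$direction[2L], bl$direction[1L]) # left normal
  (pts[, 1L] - bl$origin[1L]) * n[1L] + (pts[, 2L] - bl$origin[2L]) * n[2L]
}

point_on <- function(bl, t) bl$origin + t * bl$direction

#' Fit the occipital-lobe circle
#'
#' Finds the minimum-radius circle that encloses every vertex of the dorsal
#' occipital-lobe contour subject to its centre (point F) lying on the
#' cranial base line. The enclosing radius as a function of the centre's
#' position along the line, `g(t) = max_i |c(t) - v_i|`, is convex, so the
#' minimum is located by golden-section search (to `tol` mm in `t`).
#' Enclosure is evaluated at the annotated contour vertices.
#'
#' @param baseline a [baseline_through()] object (H towards A).
#' @param contour n x 2 matrix of occipital-dorsum vertices (mm).
#' @param tol golden-section convergence tolerance on the centre position.
#' @return Object of class `occipital_circle` with fields `center` (point F),
#'   `radius`, `f_diameter`, `touching_index` (a vertex at distance = radius)
#'   and the `baseline` used.
#' @export
fit_occipital_circle <- function(baseline, contour, tol = 1e-9) {
  if (!inherits(baseline, "baseline")) stop("'baseline' must come from baseline_through()")
  contour <- as_contour(contour, "contour", min_vertices = 1L)

  g <- function(t) {
    cx <- baseline$origin[1L] + t * baseline$direction[1L]
    cy <- baseline$origin[2L] + t * baseline$direction[2L]
    max(sqrt((contour[, 1L] - cx)^2 + (contour[, 2L] - cy)^2))
  }

  ## the optimum projection lies within the range of vertex projections
  tp <- project_t(baseline, contour)
  lo <- min(tp); hi <- max(tp)
  if (hi - lo < tol) {
    t_star <- (lo + hi) / 2
  } else {
    phi <- (sqrt(5) - 1) / 2
    a <- lo; b <- hi
    x1 <- b - phi * (b - a); x2 <- a + phi * (b - a)
    f1 <- g(x1); f2 <- g(x2)
    while (b - a > tol) {
      if (f1 <= f2) {
        b <- x2; x2 <- x1; f2 <- f1
        x1 <- b - phi * (b - a); f1 <- g(x1)
      } else {
        a <- x1; x1 <- x2; f1 <- f2
        x2 <- a + phi * (b - a); f2 <- g(x2)
      }
    }
    t_star <- (a + b) / 2
  }

  center <- point_on(baseline, t_star)
  d <- sqrt((contour[, 1L] - center[1L])^2 + (contour[, 2L] - center[2L])^2)
  radius <- max(d)
  if (radius == 0) stop("degenerate contour: all vertices coincide with the centre", call. = FALSE)
  structure(
    list(center = center, radius = radius, f_diameter = 2 * radius,
         touching_index = which.max(d), t = t_star, baseline = baseline),
    class = "occipital_circle"
  )
}

#' @export
print.occipital_circle <- function(x, ...) {
  cat(sprintf("<occipital_circle> F = (%.3f, %.3f) mm, F-diameter = %.3f mm\n",
              x$center[1L], x$center[2L], x$f_diameter))
  invisible(x)
}

#' Most dorsal intersection of a contour with the occipital circle (point E)
#'
#' Solves the segment-circle quadratic for every segment of the cerebellar
#' dorsal contour and returns the intersection with maximal y (ties broken by
#' maximal x, i.e. dorsal-then-rostral under the package's coordinate
#' convention). Tangency counts as an intersection.
#'
#' @param circle an [fit_occipital_circle()] result.
#' @param contour n x 2 matrix (cerebellar dorsum).
#' @param tol tolerance on the quadratic discriminant for tangency.
#' @return Point E as a length-2 named numeric. If the contour does not meet
#'   the circle an error of class `cmmorph_no_E` is signalled carrying the
#'   minimum contour-to-circle distance in field `min_distance`.
#' @export
intersect_circle_contour <- function(circle, contour, tol = 1e-9) {
  stopifnot(inherits(circle, "occipital_circle"))
  contour <- as_contour(contour, "contour", min_vertices = 1L)
  ctr <- circle$center; r <- circle$radius

  hits <- list()
  if (nrow(contour) == 1L) {
    if (abs(sqrt(sum((contour[1L, ] - ctr)^2)) - r) <= tol) hits[[1L]] <- contour[1L, ]
  }
  for (i in seq_len(nrow(contour) - 1L)) {
    p <- contour[i, ]; q <- contour[i + 1L, ]
    dvec <- q - p; f <- p - ctr
    aa <- sum(dvec^2)
    if (aa == 0) { # zero-length segment: treat as a point
      if (abs(sqrt(sum(f^2)) - r) <= tol) hits[[length(hits) + 1L]] <- p
      next
    }
    bb <- 2 * sum(f * dvec)
    cc <- sum(f^2) - r^2
    disc <- bb^2 - 4 * aa * cc
    if (disc < -tol * aa) next
    disc <- max(disc, 0)
    for (s in (-bb + c(-1, 1) * sqrt(disc)) / (2 * aa)) {
      if (s >= -tol && s <= 1 + tol) {
        hits[[length(hits) + 1L]] <- p + min(max(s, 0), 1) * dvec
      }
    }
  }
  if (!length(hits)) {
    dmin <- min(abs(segment_circle_distances(contour, ctr) - r))
    cond <- structure(
      class = c("cmmorph_no_E", "error", "condition"),
      list(message = sprintf(
             "no E point: contour does not meet the occipital circle (min distance %.3f mm)",
             dmin),
           call = sys.call(-1), min_distance = dmin)
    )
    stop(cond)
  }
  hm <- do.call(rbind, hits)
  ord <- order(hm[, 2L], hm[, 1L], decreasing = TRUE) # dorsal, then rostral
  as_point(hm[ord[1L], ], "point E")
}

## distance from circle centre to each contour vertex / segment (vertex-based,
## adequate for the error diagnostic)
segment_circle_distances <- function(contour, ctr) {
  sqrt((contour[, 1L] - ctr[1L])^2 + (contour[, 2L] - ctr[2L])^2)
}

#' Derive point I on the extended base line
#'
#' The occipital circle, centred on the base line, meets that line at
#' F +/- radius * direction. Point I is taken as `F - radius * direction`
#' (the intersection on the origin side of F); the alternative intersection
#' is available via `which = "far"` since the anatomical definition of I
#' fixes only that it lies on the extended H-A line.
#'
#' @param baseline the base line the circle was fitted on.
#' @param circle an [fit_occipital_circle()] result.
#' @param which `"near"` (default, towards the origin) or `"far"`.
#' @return Point I, length-2 named numeric.
#' @export
derive_point_I <- function(baseline, circle, which = c("near", "far")) {
  which <- match.arg(which)
  stopifnot(inherits(baseline, "baseline"), inherits(circle, "occipital_circle"))
  sgn <- if (which == "near") -1 else 1
  as_point(circle$center + sgn * circle$radius * baseline$direction, "point I")
}

#' Angle at a vertex between two rays
#'
#' Returns the angle in degrees at `vertex` between the rays towards `p` and
#' `q`: the arccosine of the normalised dot product, in (0, 180]. Invariant
#' under rigid motion and uniform scaling.
#'
#' @param vertex,p,q length-2 numeric points.
#' @return Angle in degrees.
#' @export
angle_at <- function(vertex, p, q) {
  vertex <- as_point(vertex, "vertex"); p <- as_point(p, "p"); q <- as_point(q, "q")
  u <- p - vertex; v <- q - vertex
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) {
    stop("zero-length ray: a ray endpoint coincides with the vertex", call. = FALSE)
  }
  cosang <- sum(u * v) / (nu * nv)
  cosang <- min(max(cosang, -1), 1)
  acos(cosang) * 180 / pi
}

#' Compute the full measurement framework for one dog
#'
#' Builds the cranial base line H -> A, fits the occipital circle (centre F),
#' derives E (most dorsal cerebellum-circle intersection) and I (circle-base
#' line intersection), and fills every configured line (Euclidean distances
#' between named points, E/F/I included where referenced) and the five
#' angles: angle 1 = ABC, 2 = CAF, 3 = AID, 4 = AGH, 5 = AFG (vertex is the
#' middle letter). Any variable whose defining point is unavailable is
#' reported as missing rather than failing the whole record.
#'
#' @param lm a [landmark_set()].
#' @param lines character vector of two-letter line labels
#'   (default [default_line_set()]).
#' @param point_I `"near"` or `"far"`, see [derive_point_I()].
#' @return Object of class `framework_result`: derived points, the fitted
#'   circle, and named `lines` / `angles` vectors (NA where missing).
#'   `as.data.frame()` turns it into a one-row measurement table.
#' @export
compute_framework <- function(lm, lines = default_line_set(),
                              point_I = c("near", "far")) {
  stopifnot(inherits(lm, "landmark_set"))
  point_I <- match.arg(point_I)
  lines <- toupper(lines)

  pts <- lm$points
  bl <- baseline_through(pts[["H"]], pts[["A"]])
  circ <- fit_occipital_circle(bl, lm$occipital_dorsum)
  pts[["F"]] <- circ$center
  pts[["I"]] <- derive_point_I(bl, circ, which = point_I)
  pts[["E"]] <- tryCatch(
    intersect_circle_contour(circ, lm$cerebellum_dorsum),
    cmmorph_no_E = function(e) NULL
  )

  getp <- function(lb) if (lb %in% names(pts) && !is.null(pts[[lb]])) pts[[lb]] else NULL

  line_vals <- vapply(lines, function(lb) {
    a <- getp(substr(lb, 1L, 1L)); b <- getp(substr(lb, 2L, 2L))
    if (is.null(a) || is.null(b)) NA_real_ else sqrt(sum((a - b)^2))
  }, numeric(1))
  names(line_vals) <- tolower(lines)

  angle_vals <- vapply(names(ANGLE_DEFS), function(an) {
    trip <- lapply(ANGLE_DEFS[[an]], getp)
    if (any(vapply(trip, is.null, logical(1)))) return(NA_real_)
    angle_at(trip[[2L]], trip[[1L]], trip[[3L]])
  }, numeric(1))

  structure(
    list(dog_id = lm$dog_id, baseline = bl, circle = circ,
         points = pts, f_diameter = circ$f_diameter,
         lines = line_vals, angles = angle_vals,
         age_years = lm$age_years, cm_grade = lm$cm_grade, sm_grade = lm$sm_grade),
    class = "framework_result"
  )
}

#' @export
print.framework_result <- function(x, ...) {
  cat(sprintf("<framework_result> dog %s: F-diameter %.2f mm\n", x$dog_id, x$f_diameter))
  cat("  lines (mm): ",
      paste(sprintf("%s=%.2f", names(x$lines), x$lines), collapse = " "), "\n")
  cat("  angles (deg): ",
      paste(sprintf("%s=%.1f", sub("angle", "", names(x$angles)), x$angles),
            collapse = " "), "\n")
  invisible(x)
}

#' @export
as.data.frame.framework_result <- function(x, ...) {
  out <- data.frame(
    dog_id = x$dog_id, age_years = x$age_years,
    cm_grade = x$cm_grade, sm_grade = x$sm_grade,
    f_diameter = x$f_diameter, stringsAsFactors = FALSE
  )
  for (v in names(x$lines)) out[[v]] <- x$lines[[v]]
  for (v in names(x$angles)) out[[v]] <- x$angles[[v]]
  out
}
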