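## Landmark containers and measurement-variable conventions.
##
## Coordinate convention (used everywhere in the package): 2-D midsagittal
## plane, x increases rostrally, y increases dorsally, units are millimetres.
## "Most dorsal" therefore always means maximal y.

POINT_LABELS <- c("A", "B", "C", "D", "G", "H")
REQUIRED_POINTS <- c("A", "H")

#' Measurement variable labels
#'
#' The 15 morphometric variables of the framework: the occipital-circle
#' diameter (`f_diameter`), nine point-to-point lines and five angles. The
#' framework attests seven lines directly (F-diameter, AB, AE, AH, BC, BD,
#' FG); AC, AD and AI complete the default ten-line set and the line set is
#' configurable in [compute_framework()].
#'
#' @param lines line labels to use (each two landmark letters, e.g. `"AB"`).
#' @return Character vector of variable labels in canonical order.
#' @export
measurement_variables <- function(lines = default_line_set()) {
  c("f_diameter", tolower(lines), paste0("angle", 1:5))
}

#' @rdname measurement_variables
#' @export
default_line_set <- function() {
  c("AB", "AC", "AD", "AE", "AH", "AI", "BC", "BD", "FG")
}

## Angle definitions: middle label is the vertex.
ANGLE_DEFS <- list(
  angle1 = c("A", "B", "C"),
  angle2 = c("C", "A", "F"),
  angle3 = c("A", "I", "D"),
  angle4 = c("A", "G", "H"),
  angle5 = c("A", "F", "G")
)

as_point <- function(p, what = "point") {
  p <- as.numeric(p)
  if (length(p) != 2L || !all(is.finite(p))) {
    stop(sprintf("%s must be two finite coordinates (mm)", what), call. = FALSE)
  }
  names(p) <- c("x", "y")
  p
}

as_contour <- function(m, what = "contour", min_vertices = 2L) {
  m <- as.matrix(m)
  if (is.null(dim(m)) || ncol(m) != 2L) {
    stop(sprintf("%s must be an n x 2 matrix of coordinates", what), call. = FALSE)
  }
  storage.mode(m) <- "double"
  if (nrow(m) < min_vertices) {
    stop(sprintf("%s needs at least %d vertices", what, min_vertices), call. = FALSE)
  }
  if (!all(is.finite(m))) {
    stop(sprintf("%s contains non-finite coordinates", what), call. = FALSE)
  }
  dimnames(m) <- list(NULL, c("x", "y"))
  m
}

#' Landmark annotations for one dog
#'
#' Bundles the named midsagittal landmarks (A dorsum of the spheno-occipital
#' synchondrosis, B basion, C rostral edge of the dorsal lamina of the atlas,
#' D supraoccipital/occipital-crest junction, G optic-canal point, H most
#' caudal point of the olfactory bulb), the dorsal contours of the occipital
#' lobes and of the cerebellum, and optional metadata. Points A and H (the
#' cranial base line) are required; the others may be absent, in which case
#' the variables that depend on them are reported as missing downstream.
#'
#' @param dog_id identifier string.
#' @param points named list of length-2 numeric vectors (mm); labels among
#'   A, B, C, D, G, H (case-insensitive).
#' @param occipital_dorsum n x 2 matrix, ordered polyline of the dorsal
#'   occipital-lobe contour (>= 3 vertices, at least one dorsal to the A-H
#'   baseline).
#' @param cerebellum_dorsum n x 2 matrix, ordered polyline of the dorsal
#'   cerebellar contour (>= 2 vertices).
#' @param age_years,cm_grade,sm_grade optional metadata; grades are
#'   observer-assigned integers 0-2.
#' @return An object of class `landmark_set`.
#' @export
landmark_set <- function(dog_id, points, occipital_dorsum, cerebellum_dorsum,
                         age_years = NA_real_, cm_grade = NA_integer_,
                         sm_grade = NA_integer_) {
  stopifnot(is.character(dog_id), length(dog_id) == 1L)
  if (is.null(names(points)) || any(!nzchar(names(points)))) {
    stop("'points' must be a named list", call. = FALSE)
  }
  names(points) <- toupper(names(points))
  unknown <- setdiff(names(points), POINT_LABELS)
  if (length(unknown)) {
    warning("ignoring unknown landmark label(s): ", paste(unknown, collapse = ", "))
    points <- points[names(points) %in% POINT_LABELS]
  }
  missing_req <- setdiff(REQUIRED_POINTS, names(points))
  if (length(missing_req)) {
    stop("missing landmark ", paste(missing_req, collapse = ", "), call. = FALSE)
  }
  points <- lapply(stats::setNames(nm = names(points)), function(lb) {
    as_point(points[[lb]], sprintf("point %s", lb))
  })
  occ <- as_contour(occipital_dorsum, "occipital_dorsum", min_vertices = 3L)
  cer <- as_contour(cerebellum_dorsum, "cerebellum_dorsum", min_vertices = 2L)

  ## the occipital dorsum must lie (at least partly) dorsal to the baseline
  bl <- baseline_through(points[["H"]], points[["A"]])
  off <- signed_offset(bl, occ)
  if (!any(off > 0)) {
    stop("occipital_dorsum lies entirely ventral to the A-H baseline", call. = FALSE)
  }

  if (!is.na(age_years) && age_years <= 0) stop("age_years must be positive", call. = FALSE)
  for (g in list(cm_grade, sm_grade)) {
    if (!is.na(g) && !(g %in% 0:2)) stop("grades must be 0, 1 or 2", call. = FALSE)
  }

  structure(
    list(
      dog_id = dog_id, points = points,
      occipital_dorsum = occ, cerebellum_dorsum = cer,
      age_years = as.numeric(age_years),
      cm_grade = as.integer(cm_grade), sm_grade = as.integer(sm_grade)
    ),
    class = "landmark_set"
  )
}

#' @export
print.landmark_set <- function(x, ...) {
  cat(sprintf(
    "<landmark_set> dog %s: points {%s}, occipital dorsum %d vx, cerebellum %d vx\n",
    x$dog_id, paste(names(x$points), collapse = ","),
    nrow(x$occipital_dorsum), nrow(x$cerebellum_dorsum)
  ))
  if (!is.na(x$age_years)) cat(sprintf("  age %.1f y", x$age_years))
  if (!is.na(x$cm_grade)) cat(sprintf("  CM%d", x$cm_grade))
  if (!is.na(x$sm_grade)) cat(sprintf("  SM%d", x$sm_grade))
  if (!is.na(x$age_years) || !is.na(x$cm_grade) || !is.na(x$sm_grade)) cat("\n")
  invisible(x)
}

#' Validate a table of morphometric measurements
#'
#' Checks a per-dog measurement table against the variable contracts: all
#' present line lengths strictly positive and all present angles in
#' (0, 180] degrees. Blank cells are missing values (`NA`), never zeros.
#'
#' @param df data frame with a `dog_id` column plus any subset of the
#'   columns named by [measurement_variables()] and the metadata columns
#'   `age_years`, `cm_grade`, `sm_grade`.
#' @return `df`, invisibly, with names normalised to lower case.
#' @export
validate_measurements <- function(df) {
  stopifnot(is.data.frame(df))
  names(df) <- tolower(names(df))
  if (!"dog_id" %in% names(df)) stop("measurement table needs a dog_id column", call. = FALSE)
  vars <- measurement_variables()
  angle_vars <- grep("^angle", vars, value = TRUE)
  length_vars <- setdiff(vars, angle_vars)
  for (v in intersect(length_vars, names(df))) {
    bad <- !is.na(df[[v]]) & df[[v]] <= 0
    if (any(bad)) {
      stop(sprintf("non-positive %s for dog(s): %s", v,
                   paste(df$dog_id[bad], collapse = ", ")), call. = FALSE)
    }
  }
  for (v in intersect(angle_vars, names(df))) {
    bad <- !is.na(df[[v]]) & (df[[v]] <= 0 | df[[v]] > 180)
    if (any(bad)) {
      stop(sprintf("%s outside (0, 180] for dog(s): %s", v,
                   paste(df$dog_id[bad], collapse = ", ")), call. = FALSE)
    }
  }
  invisible(df)
}
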