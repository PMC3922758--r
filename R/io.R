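## File IO for landmark annotations and measurement tables.
##
## Landmark JSON schema:
##   {"dog_id": str, "units": "mm",
##    "points": {"A": [x, y], ...},
##    "contours": {"occipital_dorsum": [[x, y], ...],
##                 "cerebellum_dorsum": [[x, y], ...]},
##    "age_years": num, "cm_grade": int, "sm_grade": int}
##
## Landmark CSV schema (long form): columns dog_id, kind, label, x, y where
## kind is "point", "occipital_dorsum" or "cerebellum_dorsum"; contour rows
## are ordered; optional columns age_years, cm_grade, sm_grade (first
## non-blank value is used).

#' Read landmark annotations
#'
#' @param path file path.
#' @param format `"json"` or `"csv"`; inferred from the extension by default.
#' @return A [landmark_set()].
#' @export
read_landmarks <- function(path, format = c("auto", "json", "csv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "json") read_landmarks_json(path) else read_landmarks_csv(path)
}

read_landmarks_json <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (is.null(x$points)) stop("landmark JSON lacks a 'points' object", call. = FALSE)
  pts <- lapply(x$points, as.numeric)
  contours <- x$contours %||% list()
  landmark_set(
    dog_id = as.character(x$dog_id %||% "unknown"),
    points = pts,
    occipital_dorsum = matrix(unlist(contours$occipital_dorsum),
                              ncol = 2L, byrow = is.list(contours$occipital_dorsum)),
    cerebellum_dorsum = matrix(unlist(contours$cerebellum_dorsum),
                               ncol = 2L, byrow = is.list(contours$cerebellum_dorsum)),
    age_years = as.numeric(x$age_years %||% NA_real_),
    cm_grade = as.integer(x$cm_grade %||% NA_integer_),
    sm_grade = as.integer(x$sm_grade %||% NA_integer_)
  )
}

read_landmarks_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  names(df) <- tolower(names(df))
  need <- c("dog_id", "kind", "label", "x", "y")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("landmark CSV lacks column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  for (cc in c("x", "y")) {
    if (!is.numeric(df[[cc]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(df[[cc]]))) & !is.na(df[[cc]]))
      stop(sprintf("non-numeric %s coordinate at row %d", cc, bad[1L]), call. = FALSE)
    }
  }
  pr <- df[df$kind == "point", , drop = FALSE]
  pts <- stats::setNames(
    lapply(seq_len(nrow(pr)), function(i) c(pr$x[i], pr$y[i])),
    pr$label
  )
  meta <- function(col, cast) {
    if (col %in% names(df)) {
      v <- df[[col]][!is.na(df[[col]])]
      if (length(v)) return(cast(v[1L]))
    }
    cast(NA)
  }
  landmark_set(
    dog_id = as.character(df$dog_id[1L]),
    points = pts,
    occipital_dorsum = as.matrix(df[df$kind == "occipital_dorsum", c("x", "y")]),
    cerebellum_dorsum = as.matrix(df[df$kind == "cerebellum_dorsum", c("x", "y")]),
    age_years = meta("age_years", as.numeric),
    cm_grade = meta("cm_grade", as.integer),
    sm_grade = meta("sm_grade", as.integer)
  )
}

#' Write landmark annotations
#'
#' Round-trips losslessly through [read_landmarks()] at full double
#' precision for both formats.
#'
#' @param lm a [landmark_set()].
#' @param path output path.
#' @param format `"json"` or `"csv"`; inferred from the extension by default.
#' @return `path`, invisibly.
#' @export
write_landmarks <- function(lm, path, format = c("auto", "json", "csv")) {
  stopifnot(inherits(lm, "landmark_set"))
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  if (format == "json") {
    ## serialized by hand so doubles carry 17 significant digits (lossless
    ## decimal round trip, which jsonlite's writer does not guarantee)
    num <- function(v) sprintf("%.17g", v)
    pair <- function(p) sprintf("[%s, %s]", num(p[1L]), num(p[2L]))
    contour_json <- function(m) {
      sprintf("[%s]", paste(apply(m, 1L, pair), collapse = ", "))
    }
    parts <- c(
      sprintf("\"dog_id\": %s", jsonlite::toJSON(lm$dog_id, auto_unbox = TRUE)),
      "\"units\": \"mm\"",
      sprintf("\"points\": {%s}",
              paste(sprintf("\"%s\": %s", names(lm$points),
                            vapply(lm$points, pair, character(1))),
                    collapse = ", ")),
      sprintf(
        "\"contours\": {\"occipital_dorsum\": %s, \"cerebellum_dorsum\": %s}",
        contour_json(lm$occipital_dorsum), contour_json(lm$cerebellum_dorsum)
      )
    )
    if (!is.na(lm$age_years)) parts <- c(parts, sprintf("\"age_years\": %s", num(lm$age_years)))
    if (!is.na(lm$cm_grade)) parts <- c(parts, sprintf("\"cm_grade\": %d", lm$cm_grade))
    if (!is.na(lm$sm_grade)) parts <- c(parts, sprintf("\"sm_grade\": %d", lm$sm_grade))
    writeLines(sprintf("{%s}", paste(parts, collapse = ", ")), path)
  } else {
    rows <- rbind(
      data.frame(kind = "point", label = names(lm$points),
                 x = vapply(lm$points, `[`, numeric(1), 1L),
                 y = vapply(lm$points, `[`, numeric(1), 2L),
                 stringsAsFactors = FALSE),
      data.frame(kind = "occipital_dorsum", label = "",
                 x = lm$occipital_dorsum[, 1L], y = lm$occipital_dorsum[, 2L],
                 stringsAsFactors = FALSE),
      data.frame(kind = "cerebellum_dorsum", label = "",
                 x = lm$cerebellum_dorsum[, 1L], y = lm$cerebellum_dorsum[, 2L],
                 stringsAsFactors = FALSE)
    )
    rows <- cbind(dog_id = lm$dog_id, rows)
    rows$age_years <- c(lm$age_years, rep(NA, nrow(rows) - 1L))
    rows$cm_grade <- c(lm$cm_grade, rep(NA, nrow(rows) - 1L))
    rows$sm_grade <- c(lm$sm_grade, rep(NA, nrow(rows) - 1L))
    rows$x <- sprintf("%.17g", rows$x)
    rows$y <- sprintf("%.17g", rows$y)
    utils::write.csv(rows, path, row.names = FALSE, na = "")
  }
  invisible(path)
}

MEASUREMENT_COLUMNS <- c(
  "dog_id", "age_years", "cm_grade", "sm_grade", "f_diameter",
  "ab", "ac", "ad", "ae", "ah", "ai", "bc", "bd", "fg",
  paste0("angle", 1:5)
)

#' Read a per-dog measurement table
#'
#' Reads a CSV/TSV table with one row per dog and (case-insensitive) columns
#' `dog_id, age_years, cm_grade, sm_grade, f_diameter, ab, ac, ad, ae, ah,
#' ai, bc, bd, fg, angle1..angle5`. Blank cells become `NA` (missing), never
#' zeros; unknown columns are dropped with a warning; rows violating the
#' measurement contracts (non-positive lengths, angles outside (0, 180])
#' raise an error naming the offending dogs.
#'
#' @param path file path.
#' @param dialect `"csv"` or `"tsv"`; inferred from the extension by default.
#' @return A validated data frame with lower-case column names.
#' @export
read_measurement_table <- function(path, dialect = c("auto", "csv", "tsv")) {
  dialect <- match.arg(dialect)
  if (dialect == "auto") {
    dialect <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "tsv" else "csv"
  }
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- if (dialect == "tsv") {
    utils::read.delim(path, stringsAsFactors = FALSE)
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE)
  }
  names(df) <- tolower(names(df))
  unknown <- setdiff(names(df), MEASUREMENT_COLUMNS)
  if (length(unknown)) {
    warning("ignoring unknown column(s): ", paste(unknown, collapse = ", "))
    df <- df[, setdiff(names(df), unknown), drop = FALSE]
  }
  df$dog_id <- as.character(df$dog_id)
  num_cols <- setdiff(intersect(MEASUREMENT_COLUMNS, names(df)), "dog_id")
  for (cc in num_cols) df[[cc]] <- as.numeric(df[[cc]])
  validate_measurements(df)
  df
}

#' Write a measurement table
#'
#' @param df measurement data frame.
#' @param path output path (`.csv` or `.tsv`).
#' @return `path`, invisibly.
#' @export
write_measurement_table <- function(df, path) {
  stopifnot(is.data.frame(df))
  out <- df
  for (cc in names(out)) {
    if (is.numeric(out[[cc]])) out[[cc]] <- sprintf("%.17g", out[[cc]])
  }
  out[out == "NA"] <- NA
  if (grepl("\\.tsv$", path, ignore.case = TRUE)) {
    utils::write.table(out, path, sep = "\t", row.names = FALSE, na = "", quote = FALSE)
  } else {
    utils::write.csv(out, path, row.names = FALSE, na = "")
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
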