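## Reference ("published") discriminant functions and the packaged
## example-dog fixture.

#' Reference discriminant functions
#'
#' Loads a set of named linear discriminant functions (coefficient map plus
#' constant each) from a JSON config. The packaged default carries the
#' reference functions reported for Griffon Bruxellois CM/SM screening:
#' two CM functions on F-diameter and angle 2, and one SM function on
#' F-diameter and angle 5. Coefficient labels must match measurement-table
#' column names.
#'
#' @param path JSON config path; default is the packaged config.
#' @return Object of class `published_functions`: a named list of
#'   `list(coefficients = <named numeric>, constant = <numeric>)`.
#' @export
published_functions <- function(path = system.file("extdata", "published_functions.json",
                                                   package = "cmmorph")) {
  cfg <- jsonlite::fromJSON(path)
  cfg$description <- NULL
  fns <- lapply(cfg, function(f) {
    coefs <- unlist(f$coefficients)
    bad <- setdiff(names(coefs), measurement_variables())
    if (length(bad)) {
      stop("unknown coefficient label(s): ", paste(bad, collapse = ", "), call. = FALSE)
    }
    list(coefficients = coefs, constant = as.numeric(f$constant))
  })
  structure(fns, class = "published_functions")
}

#' @export
print.published_functions <- function(x, ...) {
  cat(sprintf("<published_functions> %d function(s)\n", length(x)))
  for (nm in names(x)) {
    terms <- sprintf("%+g*%s", x[[nm]]$coefficients, names(x[[nm]]$coefficients))
    cat(sprintf("  %s = %s %+g\n", nm, paste(terms, collapse = " "), x[[nm]]$constant))
  }
  invisible(x)
}

#' Evaluate reference discriminant functions on measurement records
#'
#' Direct linear evaluation of each function on each row. A score whose
#' input variable is missing in a row is `NA` for that row.
#'
#' @param records measurement data frame (needs the variables the functions
#'   reference, e.g. `f_diameter`, `angle2`, `angle5`).
#' @param pf a [published_functions()] object.
#' @return Data frame: `dog_id` plus one score column per function.
#' @export
apply_published_functions <- function(records, pf = published_functions()) {
  stopifnot(is.data.frame(records), inherits(pf, "published_functions"))
  names(records) <- tolower(names(records))
  out <- data.frame(dog_id = as.character(records$dog_id), stringsAsFactors = FALSE)
  for (nm in names(pf)) {
    coefs <- pf[[nm]]$coefficients
    vars <- names(coefs)
    if (!all(vars %in% names(records))) {
      out[[nm]] <- NA_real_
      next
    }
    X <- as.matrix(records[, vars, drop = FALSE])
    out[[nm]] <- drop(X %*% coefs) + pf[[nm]]$constant
  }
  out
}

#' Packaged example-dog measurements
#'
#' Fourteen example dogs with known CM/SM status: eight Griffon Bruxellois
#' spanning the affectedness range and six other-breed comparators (one
#' Beagle, two Australian Terriers — mesaticephalic — and three
#' Affenpinschers — brachycephalic), with the five significant variables
#' (F-diameter, line AE, angles 2, 3 and 5).
#'
#' @return Data frame with columns `dog_id`, `breed`, `cm_grade`,
#'   `sm_grade`, `f_diameter`, `ae`, `angle2`, `angle3`, `angle5`.
#' @export
example_dogs <- function() {
  path <- system.file("extdata", "example_dogs.csv", package = "cmmorph")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$dog_id <- as.character(df$dog_id)
  df
}
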