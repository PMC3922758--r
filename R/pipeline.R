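## Orchestration: chain measurement input -> cohort -> ANOVA screening ->
## stepwise discriminant analysis + LOOCV -> ROC / cutoff grid -> reference
## function scoring, with a machine-readable JSON report.

#' Pipeline configuration
#'
#' @param seed integer seed driving every stochastic stage.
#' @param table optional measurement data frame; if `NULL` and `table_path`
#'   is `NULL`, a study-shaped synthetic table is generated from the seed.
#' @param table_path optional CSV path read with [read_measurement_table()].
#' @param variables candidate variables for the discriminant analyses.
#' @param f_enter,f_remove stepwise partial-F thresholds.
#' @param priors `"equal"` or `"proportional"`.
#' @param roc_start,roc_step cutoff grid anchor and increment (mm).
#' @param out_dir optional directory for `report.json` (and `cohort.csv`).
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, table = NULL, table_path = NULL,
                            variables = measurement_variables(),
                            f_enter = 3.84, f_remove = 2.71,
                            priors = c("equal", "proportional"),
                            roc_start = 42.5, roc_step = 0.1,
                            out_dir = NULL) {
  priors <- match.arg(priors)
  if (!is.null(table_path) && !file.exists(table_path)) {
    stop("table_path does not exist: ", table_path, call. = FALSE)
  }
  structure(
    list(seed = as.integer(seed), table = table, table_path = table_path,
         variables = variables, f_enter = f_enter, f_remove = f_remove,
         priors = priors, roc_start = roc_start, roc_step = roc_step,
         out_dir = out_dir),
    class = "pipeline_config"
  )
}

#' Run the full analysis pipeline
#'
#' Stages, in order: obtain the measurement table (supplied, read from file,
#' or simulated from the seed), build the SM cohort (age-conditional
#' exclusions logged per dog), screen all variables by one-way ANOVA for
#' both the CM 3-group and SM 2-group analyses, fit the stepwise
#' discriminant models with leave-one-out cross-validation, run the
#' F-diameter ROC and cutoff-grid analyses (CM positive = grade > 0 over
#' all dogs; SM positive = `SM_YES` within the cohort), and score the
#' packaged example dogs with the reference functions. The report is fully
#' determined by the configuration and seed (no timestamps).
#'
#' @param cfg a [pipeline_config()].
#' @return Object of class `pipeline_report` (a nested list); written as
#'   JSON to `out_dir` when configured.
#' @export
run_pipeline <- function(cfg = pipeline_config()) {
  stopifnot(inherits(cfg, "pipeline_config"))
  tbl <- if (!is.null(cfg$table)) {
    validate_measurements(cfg$table)
    cfg$table
  } else if (!is.null(cfg$table_path)) {
    read_measurement_table(cfg$table_path)
  } else {
    gen_study_table(cfg$seed)
  }

  cohort <- build_sm_cohort(tbl)
  excl <- cohort[cohort$sm_status == "EXCLUDED", c("dog_id", "exclusion_reason")]

  vars <- intersect(cfg$variables, names(cohort))
  anova_tab <- function(grouping) {
    rows <- lapply(vars, function(v) {
      a <- tryCatch(oneway_anova(cohort, v, grouping), error = function(e) NULL)
      if (is.null(a)) return(NULL)
      data.frame(variable = v, F = a$F, p = a$p, stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  }
  anova_cm <- anova_tab("cm_group")
  anova_sm <- anova_tab("sm_status")

  run_lda <- function(grouping) {
    cv <- loocv(cohort, vars, grouping, f_enter = cfg$f_enter,
                f_remove = cfg$f_remove, priors = cfg$priors)
    m <- cv$model
    list(selected = m$variables,
         coefficients = apply(m$coefficients, 2L, identity, simplify = FALSE),
         constants = as.numeric(m$constants),
         centroids = apply(m$centroids, 2L, identity, simplify = FALSE),
         fn_p_values = as.numeric(m$fn_p_values),
         n_used = m$n_used, n_dropped = m$n_dropped,
         loocv_overall = cv$overall,
         loocv_per_group = as.list(cv$per_group))
  }
  lda_cm <- run_lda("cm_group")
  lda_sm <- run_lda("sm_status")

  ## ROC on F-diameter
  cm_pos <- cohort$cm_grade > 0
  roc_cm <- roc_curve(cohort$f_diameter, cm_pos)
  in_cohort <- cohort$sm_status != "EXCLUDED"
  sm_pos <- cohort$sm_status[in_cohort] == "SM_YES"
  roc_sm <- roc_curve(cohort$f_diameter[in_cohort], sm_pos)
  grid_sm <- cutoff_grid_search(cohort$f_diameter[in_cohort], sm_pos,
                                start = cfg$roc_start, step = cfg$roc_step)
  grid_cm <- cutoff_grid_search(cohort$f_diameter, cm_pos,
                                start = cfg$roc_start, step = cfg$roc_step)

  fixture <- apply_published_functions(example_dogs())

  report <- structure(
    list(
      seed = cfg$seed,
      package_version = as.character(utils::packageVersion("cmmorph")),
      counts = list(total = nrow(cohort),
                    sm_no = sum(cohort$sm_status == "SM_NO"),
                    sm_yes = sum(cohort$sm_status == "SM_YES"),
                    excluded = sum(cohort$sm_status == "EXCLUDED")),
      exclusions = excl,
      anova = list(cm = anova_cm, sm = anova_sm),
      discriminant = list(cm = lda_cm, sm = lda_sm),
      roc = list(
        cm = list(auc = roc_cm$auc, p = roc_cm$p_value,
                  best_cutoff = grid_cm$best$cutoff,
                  sensitivity = grid_cm$best$sensitivity,
                  specificity = grid_cm$best$specificity,
                  ppv = grid_cm$best$ppv, npv = grid_cm$best$npv),
        sm = list(auc = roc_sm$auc, p = roc_sm$p_value,
                  best_cutoff = grid_sm$best$cutoff,
                  sensitivity = grid_sm$best$sensitivity,
                  specificity = grid_sm$best$specificity,
                  ppv = grid_sm$best$ppv, npv = grid_sm$best$npv)
      ),
      reference_scores = fixture
    ),
    class = "pipeline_report"
  )

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(unclass(report),
                         file.path(cfg$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows",
                         pretty = TRUE)
    write_measurement_table(as.data.frame(cohort),
                            file.path(cfg$out_dir, "cohort.csv"))
  }
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>\n")
  cat(sprintf("  dogs: %d total, %d SM_NO, %d SM_YES, %d excluded\n",
              x$counts$total, x$counts$sm_no, x$counts$sm_yes, x$counts$excluded))
  cat(sprintf("  CM LDA: %s; LOOCV overall %.1f%%\n",
              paste(x$discriminant$cm$selected, collapse = " + "),
              100 * x$discriminant$cm$loocv_overall))
  cat(sprintf("  SM LDA: %s; LOOCV overall %.1f%%\n",
              paste(x$discriminant$sm$selected, collapse = " + "),
              100 * x$discriminant$sm$loocv_overall))
  cat(sprintf("  ROC (F-diameter): CM AUC %.3f, SM AUC %.3f, SM best cutoff %.1f mm\n",
              x$roc$cm$auc, x$roc$sm$auc, x$roc$sm$best_cutoff))
  invisible(x)
}
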