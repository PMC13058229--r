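#' Summarise cohort outcomes
#'
#' Counts and rates of transmural lesions and steam pops, with per-variable
#' medians and quartiles split by pop status and Wilcoxon rank-sum p-values
#' (see [compare_groups()]). Transmural rates are reported to the nearest
#' integer percent, pop rates to one decimal; both rounded half-up.
#'
#' @param data cohort data frame with `transmural` and `steam_pop` columns.
#' @param variables variables to compare by pop status (defaults to the
#'   candidate predictors present in `data`).
#' @param tm_digits,pop_digits decimal places for the reported transmural
#'   and pop rates. The defaults (integer transmural, one-decimal pop)
#'   match the usual reporting convention; set `pop_digits = 0` for
#'   integer-percent pop rates.
#' @return list of class `cohort_summary`: `n`, `n_transmural`,
#'   `rate_transmural` (%), `n_pop`, `rate_pop` (%), and `by_pop` (the
#'   comparison table, `NULL` when either group is empty).
#' @export
summarize_outcomes <- function(data, variables = NULL, tm_digits = 0,
                               pop_digits = 1) {
  if (nrow(data) < 1) stop_input("empty table")
  tm <- check_binary(data$transmural, "transmural")
  pop <- check_binary(data$steam_pop, "steam_pop")
  variables <- variables %||%
    intersect(c("rf_power", "init_impedance", "thickness",
                "imp_drop5", "pct_imp_drop5"), names(data))
  by_pop <- if (all(pop == 0) || all(pop == 1) || !length(variables)) NULL
            else compare_groups(data, by = "steam_pop", variables = variables)
  structure(list(
    n = nrow(data),
    n_transmural = sum(tm),
    rate_transmural = round_half_up(100 * mean(tm), tm_digits),
    n_pop = sum(pop),
    rate_pop = round_half_up(100 * mean(pop), pop_digits),
    by_pop = by_pop
  ), class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("n = %d applications: transmural %d (%g%%), steam pop %d (%g%%)\n",
              x$n, x$n_transmural, x$rate_transmural, x$n_pop, x$rate_pop))
  if (!is.null(x$by_pop)) {
    cat("\nby steam-pop status (median [q1-q3], rank-sum p):\n")
    tab <- x$by_pop
    num <- vapply(tab, is.numeric, TRUE)
    tab[num] <- lapply(tab[num], signif, 4)
    print(tab)
  }
  invisible(x)
}

#' Compare variables between two outcome groups
#'
#' Per variable: group medians and quartiles (linear-interpolation
#' quantiles, `type = 7`) and the two-sided Wilcoxon rank-sum p-value —
#' exact enumeration when both groups are below 10 observations and the
#' data are tie-free, normal approximation with tie correction otherwise.
#'
#' @param data data frame.
#' @param by name of the 0/1 grouping column.
#' @param variables character vector of numeric columns to compare.
#' @return data frame: one row per variable with medians/quartiles of the
#'   event (`g1`) and non-event (`g0`) groups and `p_value`.
#' @export
compare_groups <- function(data, by = "steam_pop", variables) {
  g <- check_binary(data[[by]], by)
  if (all(g == 0) || all(g == 1))
    stop_input("degenerate groups: both levels of '", by, "' must be present")
  qs <- function(x) stats::quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  rows <- lapply(variables, function(v) {
    x1 <- data[[v]][g == 1]
    x0 <- data[[v]][g == 0]
    q1 <- qs(x1)
    q0 <- qs(x0)
    exact <- length(x1) < 10 && length(x0) < 10 &&
      !anyDuplicated(c(x1, x0))
    p <- stats::wilcox.test(x1, x0, exact = exact, correct = !exact)$p.value
    data.frame(variable = v,
               median_g1 = q1[2], q1_g1 = q1[1], q3_g1 = q1[3],
               median_g0 = q0[2], q1_g0 = q0[1], q3_g0 = q0[3],
               p_value = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Export model-search and attribution tables
#'
#' Writes the full model-evaluation table (predictor checkmark matrix plus
#' AUCs and CIs), a long-format forest-plot table (`model`, `auc`, `lo`,
#' `hi`), and the attribution table, each as CSV and as a single combined
#' JSON document. Numeric columns are written with 12 significant digits so
#' a read-back round trip is lossless at that precision.
#'
#' @param evaluations an [evaluate_all()] result.
#' @param attributions an [attribute_auc()] result (optional).
#' @param path output directory (created if needed).
#' @param prefix file-name prefix.
#' @return invisibly, the named vector of files written.
#' @export
export_tables <- function(evaluations, attributions = NULL, path,
                          prefix = "rf") {
  if (nrow(evaluations) < 1) stop_input("empty evaluation table")
  if (!dir.exists(path) &&
      !dir.create(path, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", path)
  sig <- function(d) {
    num <- vapply(d, is.numeric, TRUE)
    d[num] <- lapply(d[num], function(x) signif(x, 12))
    d
  }
  files <- c(models = file.path(path, paste0(prefix, "_models.csv")),
             forest = file.path(path, paste0(prefix, "_forest.csv")),
             json = file.path(path, paste0(prefix, "_report.json")))
  utils::write.csv(sig(as.data.frame(evaluations)), files["models"],
                   row.names = FALSE)
  forest <- data.frame(model = evaluations$model,
                       auc = evaluations$auc_val,
                       lo = evaluations$ci_val_lo,
                       hi = evaluations$ci_val_hi,
                       stringsAsFactors = FALSE)
  utils::write.csv(sig(forest), files["forest"], row.names = FALSE)
  doc <- list(models = as.data.frame(evaluations), forest = forest)
  if (!is.null(attributions)) {
    files["attribution"] <- file.path(path, paste0(prefix, "_attribution.csv"))
    utils::write.csv(sig(as.data.frame(attributions)), files["attribution"],
                     row.names = FALSE)
    doc$attribution <- as.data.frame(attributions)
    doc$auc_full <- attr(attributions, "auc_full")
  }
  writeLines(jsonlite::toJSON(doc, dataframe = "rows", auto_unbox = TRUE,
                              digits = NA), files["json"])
  invisible(files)
}

#' Run the full seeded analysis pipeline
#'
#' End-to-end demo: simulate a development (factorial grid) and a validation
#' (boundary-adjacent) cohort, summarise both, run the exhaustive model
#' search and the AUC attribution for both outcomes, compute the printed
#' risk-boundary quantities, and invert the top transmurality model to
#' depth curves. Everything downstream of the two seeds is deterministic.
#'
#' @param seed master seed; the two cohorts use `seed` and `seed + 1`.
#' @param n_dev_per_cell applications per cell of the 36-cell development
#'   grid.
#' @param n_val validation applications.
#' @param config base [generator_config()].
#' @param out_dir optional directory: when given, all tables are exported
#'   there via [export_tables()] and [write_cohort()].
#' @return list with `dev`, `val`, `summary_dev`, `summary_val`,
#'   `search_transmural`, `search_pop`, `attribution_transmural`,
#'   `attribution_pop`, `boundary` (curve data frame), `depth_curves`.
#' @export
run_rf_analysis <- function(seed = 1L, n_dev_per_cell = 6, n_val = 120,
                            config = generator_config(), out_dir = NULL) {
  dev_cfg <- config
  val_cfg <- config
  val_cfg$design <- "boundary_adjacent"
  dev <- generate_cohort(dev_cfg, n_per_cell = n_dev_per_cell, seed = seed)
  val <- generate_cohort(val_cfg, n_total = n_val, seed = seed + 1L)

  exclusions <- list("rf_duration")  # fixed at 60 s in the validation design
  search_tm <- evaluate_all(dev, val, "transmural", exclusions = exclusions)
  search_sp <- evaluate_all(dev, val, "steam_pop", exclusions = exclusions)
  attr_tm <- attribute_auc(dev, val, "transmural")
  attr_sp <- attribute_auc(dev, val, "steam_pop")

  tm_fit <- fit_logistic(dev, "transmural",
                         c("rf_power", "init_impedance", "rf_duration",
                           "thickness"))
  depth <- depth_curves(tm_fit,
                        impedance_intercept = config$impedance_intercept,
                        impedance_slope = config$impedance_slope)
  bnd <- boundary_curve()

  res <- list(dev = dev, val = val,
              summary_dev = summarize_outcomes(dev),
              summary_val = summarize_outcomes(val),
              search_transmural = search_tm, search_pop = search_sp,
              attribution_transmural = attr_tm, attribution_pop = attr_sp,
              transmural_model = tm_fit,
              boundary = bnd, depth_curves = depth)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_cohort(dev, file.path(out_dir, "development.csv"), seed = seed)
    write_cohort(val, file.path(out_dir, "validation.csv"), seed = seed + 1L)
    export_tables(search_tm, attr_tm, out_dir, prefix = "transmural")
    export_tables(search_sp, attr_sp, out_dir, prefix = "steam_pop")
    utils::write.csv(bnd, file.path(out_dir, "boundary_curve.csv"),
                     row.names = FALSE)
    utils::write.csv(depth, file.path(out_dir, "depth_curves.csv"),
                     row.names = FALSE)
  }
  res
}
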