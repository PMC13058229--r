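#' Enumerate all non-empty predictor subsets
#'
#' Produces every one of the `2^p - 1` non-empty subsets of the candidate
#' predictors as character vectors, in a deterministic order: by subset
#' size, then lexicographically in the order the predictors were supplied.
#' With the six standard candidates this yields the 63 candidate models.
#'
#' @param predictors character vector of candidate predictor names
#'   (1 to 16, no duplicates).
#' @return list of character vectors.
#' @export
enumerate_predictor_subsets <- function(predictors = RF_PREDICTORS) {
  p <- length(predictors)
  if (p < 1) stop_input("predictors must be non-empty")
  if (p > 16) stop_input("at most 16 predictors supported")
  if (anyDuplicated(predictors)) stop_input("duplicate predictor names")
  out <- list()
  for (k in seq_len(p)) {
    combos <- utils::combn(seq_len(p), k, simplify = FALSE)
    out <- c(out, lapply(combos, function(ix) predictors[ix]))
  }
  out
}

spec_label <- function(predictors) paste(predictors, collapse = "+")

#' Fit every predictor subset on a development cohort and score it on a
#' validation cohort
#'
#' The exhaustive-model-search machinery: each non-empty subset of
#' `predictors` is fitted as a logistic model for `outcome` on `dev`, then
#' scored on `val`. Discrimination is summarised as validation AUC with its
#' DeLong 95% CI, in-sample (train) AUC with DeLong CI, and the validation
#' sensitivity/specificity at the operating point chosen by `op_rule`.
#'
#' Models whose every predictor is constant across the validation cohort
#' (and, more generally, models whose validation scores are all tied) are
#' completely uninformative there: by convention they are reported with AUC
#' exactly 0.500 and the degenerate CI 0.500–0.500, and flagged `excluded`
#' with a reason. Subsets listed in `exclusions` are dropped a priori (e.g.
#' a duration-only model when the validation design fixes the duration).
#'
#' @param dev,val development and validation cohorts (data frames).
#' @param outcome outcome column name (0/1 in both cohorts).
#' @param predictors candidate predictor names (default the six standard
#'   candidates).
#' @param exclusions list of character vectors; any subset matching one of
#'   them (as a set) is dropped from the output.
#' @param op_rule operating-point rule, `"youden"` or `"prob0.5"`.
#' @param sort sort rows by decreasing validation AUC (ties broken by model
#'   label) to mirror the ranked model tables.
#' @param ... passed to [fit_logistic()].
#' @return data frame of class `rf_model_ranking`: one row per subset with
#'   logical predictor membership columns, `model`, `n_predictors`,
#'   `auc_val`, `ci_val_lo`, `ci_val_hi`, `auc_train`, `ci_train_lo`,
#'   `ci_train_hi`, `sensitivity`, `specificity`, `log_lik_train`,
#'   `converged`, `excluded`, `reason`.
#' @export
evaluate_all <- function(dev, val, outcome = "steam_pop",
                         predictors = RF_PREDICTORS, exclusions = NULL,
                         op_rule = "youden", sort = TRUE, ...) {
  for (d in list(dev, val)) {
    y <- check_binary(d[[outcome]], outcome)
    if (all(y == 1) || all(y == 0))
      stop_input("degenerate outcome '", outcome, "' in a cohort")
  }
  specs <- enumerate_predictor_subsets(predictors)
  if (!is.null(exclusions)) {
    excl_lab <- vapply(lapply(exclusions, sort), paste, "", collapse = "+")
    keep <- !vapply(specs, function(s) paste(sort(s), collapse = "+") %in% excl_lab, TRUE)
    specs <- specs[keep]
  }
  y_val <- as.numeric(val[[outcome]])
  y_dev <- as.numeric(dev[[outcome]])

  rows <- lapply(specs, function(s) {
    fit <- suppressWarnings(fit_logistic(dev, outcome, s, ...))
    sc_tr <- predict(fit, dev, type = "link")
    sc_va <- predict(fit, val, type = "link")
    roc_tr <- roc_auc(sc_tr, y_dev)
    const_val <- all(vapply(s, function(p) length(unique(val[[p]])) == 1, TRUE))
    tied <- diff(range(sc_va)) < 1e-12
    if (tied) {
      roc_va <- list(auc = 0.5, ci95 = c(0.5, 0.5))
      op <- list(sensitivity = NA_real_, specificity = NA_real_)
      reason <- if (const_val) "all predictors constant in validation"
                else "constant score in validation"
      excluded <- TRUE
    } else {
      roc_va <- roc_auc(sc_va, y_val)
      op <- operating_point(stats::plogis(sc_va), y_val, rule = op_rule)
      reason <- ""
      excluded <- FALSE
    }
    cbind(data.frame(model = spec_label(s), n_predictors = length(s),
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(stats::setNames(predictors %in% s, predictors))),
          data.frame(auc_val = roc_va$auc, ci_val_lo = roc_va$ci95[1],
                     ci_val_hi = roc_va$ci95[2],
                     auc_train = roc_tr$auc, ci_train_lo = roc_tr$ci95[1],
                     ci_train_hi = roc_tr$ci95[2],
                     sensitivity = op$sensitivity, specificity = op$specificity,
                     log_lik_train = fit$log_likelihood,
                     converged = fit$converged,
                     excluded = excluded, reason = reason,
                     stringsAsFactors = FALSE))
  })
  out <- do.call(rbind, rows)
  if (sort) out <- out[order(-out$auc_val, out$model), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("rf_model_ranking", "data.frame")
  out
}

#' @export
print.rf_model_ranking <- function(x, n = 10, digits = 3, ...) {
  cat("Exhaustive model search:", nrow(x), "candidate models\n")
  top <- utils::head(as.data.frame(x)[, c("model", "auc_val", "ci_val_lo",
                                          "ci_val_hi", "auc_train")], n)
  top[-1] <- lapply(top[-1], round, digits)
  print(top)
  if (nrow(x) > n) cat("... and", nrow(x) - n, "more rows\n")
  invisible(x)
}
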