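#' Attribute validation AUC to individual predictors
#'
#' Treats each predictor as a player in a cooperative game whose value
#' function `v(S)` is the validation AUC of the logistic model fitted on the
#' development cohort with predictor subset `S`, with `v(empty) = 0.5`
#' (chance discrimination). Each predictor's contribution is the weighted
#' mean of its marginal AUC gains `v(S + i) - v(S)` over all subsets `S` of
#' the remaining predictors:
#'
#' * `weighting = "shapley"` (default): Shapley kernel weights
#'   `|S|! (p - |S| - 1)! / p!`, which satisfy efficiency
#'   (contributions sum to `AUC(full) - 0.5`), symmetry and the dummy axiom;
#' * `weighting = "uniform"`: plain average `1 / 2^(p-1)` over the
#'   `2^(p-1)` subsets — simpler, but efficiency is not guaranteed.
#'
#' Exact enumeration over all `2^p` subsets; collinear subsets (e.g. a
#' duplicated column) are handled by the fitter's minimal-ridge fallback so
#' the game value is always defined.
#'
#' @param dev,val development and validation cohorts.
#' @param outcome outcome column name.
#' @param predictors predictor universe (p <= 12).
#' @param weighting `"shapley"` or `"uniform"`.
#' @param ... passed to [fit_logistic()].
#' @return data frame of class `rf_attribution`, sorted by decreasing
#'   contribution: `predictor`, `contribution`, `n_subsets`, `weighting`.
#'   The full-model AUC is attached as attribute `auc_full`.
#' @export
attribute_auc <- function(dev, val, outcome = "steam_pop",
                          predictors = RF_PREDICTORS,
                          weighting = c("shapley", "uniform"), ...) {
  weighting <- match.arg(weighting)
  p <- length(predictors)
  if (p < 1) stop_input("predictors must be non-empty")
  if (p > 12) stop_input("exact enumeration limited to 12 predictors")
  y_val <- check_binary(val[[outcome]], outcome)

  # game value for every subset, indexed by bitmask; v(0) = 0.5
  v <- numeric(2^p)
  v[1] <- 0.5
  for (mask in seq_len(2^p - 1)) {
    s <- predictors[bitwAnd(mask, bitwShiftL(1, seq_len(p) - 1)) != 0]
    fit <- suppressWarnings(fit_logistic(dev, outcome, s, ...))
    sc <- predict(fit, val, type = "link")
    v[mask + 1] <- if (diff(range(sc)) < 1e-12) 0.5 else roc_auc(sc, y_val)$auc
  }

  fact <- factorial(0:p)
  contrib <- numeric(p)
  for (i in seq_len(p)) {
    bit_i <- bitwShiftL(1, i - 1)
    others <- 0:(2^p - 1)
    others <- others[bitwAnd(others, bit_i) == 0]
    sizes <- vapply(others, function(m) sum(bitwAnd(m, bitwShiftL(1, 0:(p - 1))) != 0), 0)
    w <- if (weighting == "shapley")
      fact[sizes + 1] * fact[p - sizes] / fact[p + 1]
    else rep(1 / 2^(p - 1), length(others))
    gains <- v[others + bit_i + 1] - v[others + 1]
    contrib[i] <- sum(w * gains)
  }

  out <- data.frame(predictor = predictors, contribution = contrib,
                    n_subsets = 2^(p - 1), weighting = weighting,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$contribution, out$predictor), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "auc_full") <- v[2^p]
  class(out) <- c("rf_attribution", "data.frame")
  out
}

#' @export
print.rf_attribution <- function(x, digits = 4, ...) {
  cat("Validation-AUC attribution (", x$weighting[1], " weighting), full-model AUC ",
      round(attr(x, "auc_full"), digits), "\n", sep = "")
  tab <- as.data.frame(x)[, c("predictor", "contribution")]
  tab$contribution <- round(tab$contribution, digits)
  print(tab)
  invisible(x)
}
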