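#' AUC with DeLong variance and 95% confidence interval
#'
#' Computes the area under the ROC curve by the midrank Mann–Whitney
#' statistic (ties count one half) together with its nonparametric DeLong
#' variance from the positive- and negative-class structural components, and
#' a normal-approximation 95% CI clipped to \[0, 1\].
#'
#' Scores are oriented so that *larger scores indicate the positive class*;
#' no automatic direction flipping is performed, so an anti-predictive score
#' honestly yields AUC < 0.5 (essential when scoring a model on an external
#' validation cohort).
#'
#' @param scores numeric vector of risk scores (finite).
#' @param labels 0/1 vector of true classes, same length as `scores`.
#' @param conf_level confidence level for the interval (default 0.95).
#' @return object of class `roc_result`: a list with `auc`,
#'   `delong_variance`, `ci95` (length-2, clipped), `n_pos`, `n_neg`, and the
#'   per-case structural components `v10`, `v01` used by the paired test.
#' @references DeLong, DeLong and Clarke-Pearson (1988), Biometrics 44:837;
#'   Sun and Xu (2014), IEEE Signal Processing Letters 21:1389 (midrank
#'   formulation).
#' @examples
#' roc_auc(c(0.9, 0.8, 0.3, 0.2), c(1, 1, 0, 0))
#' @export
roc_auc <- function(scores, labels, conf_level = 0.95) {
  labels <- check_binary(labels, "labels")
  if (length(scores) != length(labels))
    stop_input("scores and labels differ in length")
  if (!all(is.finite(scores))) stop_input("scores must be finite")
  if (all(labels == 1) || all(labels == 0))
    stop_input("degenerate labels: need at least one case in each class")

  comp <- delong_components(scores, labels)
  m <- comp$n_pos
  n <- comp$n_neg
  auc <- comp$auc
  s10 <- if (m > 1) stats::var(comp$v10) else 0
  s01 <- if (n > 1) stats::var(comp$v01) else 0
  v <- s10 / m + s01 / n
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  ci <- c(max(0, auc - zq * sqrt(v)), min(1, auc + zq * sqrt(v)))
  structure(list(auc = auc, delong_variance = v, ci95 = ci,
                 n_pos = m, n_neg = n, v10 = comp$v10, v01 = comp$v01),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, digits = 3, ...) {
  cat(sprintf("AUC %.*f (95%% CI %.*f-%.*f), %d pos / %d neg, DeLong var %.3g\n",
              digits, x$auc, digits, x$ci95[1], digits, x$ci95[2],
              x$n_pos, x$n_neg, x$delong_variance))
  invisible(x)
}

# midrank structural components; O(n log n)
# v10[i] = P(score_i > Y) + 0.5 P(tie) over negatives Y, and symmetrically
delong_components <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  m <- length(pos)
  n <- length(neg)
  r_all <- rank(c(pos, neg), ties.method = "average")
  r_pos <- rank(pos, ties.method = "average")
  r_neg <- rank(neg, ties.method = "average")
  v10 <- (r_all[seq_len(m)] - r_pos) / n
  v01 <- 1 - (r_all[m + seq_len(n)] - r_neg) / m
  auc <- (sum(r_all[seq_len(m)]) - m * (m + 1) / 2) / (m * n)
  list(v10 = v10, v01 = v01, auc = auc, n_pos = m, n_neg = n)
}

#' Paired DeLong test for the difference of two correlated AUCs
#'
#' Tests whether two risk scores evaluated on the *same* labelled cases have
#' equal AUC, accounting for their correlation via the covariance of the
#' DeLong structural components.
#'
#' @param scores_a,scores_b numeric score vectors on the same cases.
#' @param labels 0/1 class labels shared by both score vectors.
#' @return list with `auc_a`, `auc_b`, `auc_diff`, `variance` (of the
#'   difference), `z` and the two-sided `p_value`. When the variance of the
#'   difference is exactly zero (e.g. identical or rank-equivalent scores)
#'   the result is reported as an exact tie with `p_value = 1`.
#' @export
delong_paired_test <- function(scores_a, scores_b, labels) {
  if (length(scores_a) != length(scores_b))
    stop_input("scores_a and scores_b differ in length")
  labels <- check_binary(labels, "labels")
  if (length(scores_a) != length(labels))
    stop_input("scores and labels differ in length")
  a <- delong_components(scores_a, labels)
  b <- delong_components(scores_b, labels)
  m <- a$n_pos
  n <- a$n_neg
  s10 <- stats::cov(cbind(a$v10, b$v10))
  s01 <- stats::cov(cbind(a$v01, b$v01))
  if (m < 2) s10[] <- 0
  if (n < 2) s01[] <- 0
  s <- s10 / m + s01 / n
  v_diff <- s[1, 1] + s[2, 2] - 2 * s[1, 2]
  d <- a$auc - b$auc
  if (v_diff <= 0 || (abs(d) < 1e-15 && v_diff < 1e-15)) {
    z <- 0
    p <- 1
    v_diff <- max(v_diff, 0)
  } else {
    z <- d / sqrt(v_diff)
    p <- 2 * stats::pnorm(-abs(z))
  }
  list(auc_a = a$auc, auc_b = b$auc, auc_diff = d,
       variance = v_diff, z = z, p_value = p)
}

#' Choose an operating point on the empirical ROC curve
#'
#' Scans all achievable thresholds (each observed score, plus `+Inf` for the
#' "call nothing positive" corner) with the decision rule
#' `positive if score >= threshold`.
#'
#' Rules: `"youden"` maximises Youden's J = sensitivity + specificity − 1;
#' `"prob0.5"` uses the fixed threshold 0.5 (for probability-scale scores).
#' Ties in J are broken toward higher specificity (i.e. the higher
#' threshold), so completely uninformative scores yield (sens 0, spec 1).
#'
#' @param scores,labels as in [roc_auc()].
#' @param rule `"youden"` or `"prob0.5"`.
#' @return list with `threshold`, `sensitivity`, `specificity`.
#' @export
operating_point <- function(scores, labels, rule = c("youden", "prob0.5")) {
  rule <- match.arg(rule)
  labels <- check_binary(labels, "labels")
  if (length(scores) != length(labels))
    stop_input("scores and labels differ in length")
  if (all(labels == 1) || all(labels == 0))
    stop_input("degenerate labels: need at least one case in each class")
  if (rule == "prob0.5") {
    thr <- 0.5
    return(list(threshold = thr,
                sensitivity = mean(scores[labels == 1] >= thr),
                specificity = mean(scores[labels == 0] < thr)))
  }
  thr_grid <- c(sort(unique(scores)), Inf)
  sens <- vapply(thr_grid, function(t) mean(scores[labels == 1] >= t), 0)
  spec <- vapply(thr_grid, function(t) mean(scores[labels == 0] < t), 0)
  j <- sens + spec - 1
  best <- which(j >= max(j) - 1e-12)
  pick <- best[order(spec[best], thr_grid[best], decreasing = TRUE)[1]]
  list(threshold = thr_grid[pick], sensitivity = sens[pick],
       specificity = spec[pick])
}
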