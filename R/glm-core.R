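#' Fit a binomial logit-link GLM by iteratively reweighted least squares
#'
#' `rf_glm()` is the package's central model-fitting function: a logistic
#' regression estimated by maximum likelihood (IRLS), with an honest
#' convergence flag, detection of quasi-complete separation, and an optional
#' ridge fallback for separated or collinear designs. Coefficients are
#' reported on the raw predictor scale (no standardisation), so they are
#' directly comparable across cohorts and to published logit equations.
#'
#' Convergence is declared when the relative change in log-likelihood falls
#' below `tol`. Separation is flagged when any coefficient exceeds
#' `separation_limit` in absolute value or a standard error explodes; in that
#' case the fit is returned with `converged = FALSE` and a warning unless
#' `ridge > 0`, in which case the penalised fit is reported instead (with
#' `ridge_used` recorded). Exactly aliased columns (duplicates of another
#' column, constants) are dropped before fitting, as `stats::glm` does:
#' their coefficient and standard error are `NA`, and fitted scores equal
#' those of the reduced model exactly. A weighted cross-product that still
#' turns out singular receives a minimal ridge of `1e-6` so the fit is
#' always well-posed.
#'
#' @param formula model formula, e.g. `steam_pop ~ rf_power + pct_imp_drop5`.
#' @param data data frame containing the outcome (0/1) and predictors.
#' @param tol convergence tolerance on the relative log-likelihood change.
#' @param max_iter maximum IRLS iterations.
#' @param ridge ridge penalty applied to all coefficients if the design is
#'   separated or singular; `0` disables the separation fallback (a singular
#'   design still receives a minimal ridge of `1e-6`).
#' @param separation_limit absolute coefficient size beyond which
#'   quasi-complete separation is declared.
#' @return an object of class `rf_glm` with components `coefficients`
#'   (intercept first), `se`, `vcov`, `log_likelihood`, `converged`,
#'   `iterations`, `separation`, `ridge_used`, `n_used`, `outcome`,
#'   `predictors` and the matched `call`.
#' @seealso [fit_logistic()] for the column-name interface,
#'   [predict_probability()], [roc_auc()].
#' @examples
#' d <- data.frame(y = rbinom(200, 1, 0.4), x = rnorm(200))
#' fit <- rf_glm(y ~ x, d)
#' coef(fit)
#' head(predict(fit, d, type = "response"))
#' @export
rf_glm <- function(formula, data, tol = 1e-8, max_iter = 100L, ridge = 0,
                   separation_limit = 15) {
  mf <- stats::model.frame(formula, data, na.action = stats::na.fail)
  y <- check_binary(stats::model.response(mf))
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  if (!all(is.finite(X))) stop_input("non-finite values in predictors")
  if (all(y == 1) || all(y == 0))
    stop_input("degenerate outcome: all observations are in one class")

  # exactly aliased columns (duplicates, constants) are dropped from the
  # fit, as in stats::glm: their coefficient is NA and fitted scores equal
  # those of the reduced model exactly
  qrX <- qr(X)
  aliased <- rep(FALSE, ncol(X))
  if (qrX$rank < ncol(X))
    aliased[-qrX$pivot[seq_len(qrX$rank)]] <- TRUE
  Xf <- X[, !aliased, drop = FALSE]

  fit <- irls_logit(Xf, y, tol = tol, max_iter = max_iter, ridge = 0)

  separated <- max(abs(fit$beta)) > separation_limit ||
    any(!is.finite(fit$se)) || max(fit$se) > 1e3
  ridge_used <- fit$ridge_used
  if (separated) {
    if (ridge > 0) {
      fit <- irls_logit(Xf, y, tol = tol, max_iter = max_iter, ridge = ridge)
      ridge_used <- ridge
      warning("separation detected; refit with ridge penalty ", ridge,
              call. = FALSE)
    } else {
      warning("possible complete or quasi-complete separation; ",
              "estimates are unreliable (converged = FALSE). ",
              "Consider ridge > 0.", call. = FALSE)
      fit$converged <- FALSE
    }
  }

  beta <- rep(NA_real_, ncol(X))
  se <- rep(NA_real_, ncol(X))
  beta[!aliased] <- drop(fit$beta)
  se[!aliased] <- fit$se
  names(beta) <- names(se) <- colnames(X)
  V <- matrix(NA_real_, ncol(X), ncol(X),
              dimnames = list(colnames(X), colnames(X)))
  V[!aliased, !aliased] <- fit$vcov
  structure(list(
    coefficients = beta,
    se = se,
    aliased = aliased,
    vcov = V,
    log_likelihood = fit$loglik,
    converged = fit$converged,
    iterations = fit$iter,
    separation = separated,
    ridge_used = ridge_used,
    n_used = length(y),
    outcome = as.character(formula[[2]]),
    predictors = colnames(X)[-1],
    formula = formula,
    call = match.call()
  ), class = "rf_glm")
}

# IRLS core on a numeric design matrix (intercept included in X)
irls_logit <- function(X, y, tol = 1e-8, max_iter = 100L, ridge = 0) {
  p <- ncol(X)
  beta <- matrix(0, p, 1)
  loglik_old <- -Inf
  converged <- FALSE
  ridge_used <- ridge
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    mu <- pmin(pmax(mu, 1e-12), 1 - 1e-12)
    w <- mu * (1 - mu)
    z <- eta + (y - mu) / w
    XtWX <- crossprod(X, X * w)
    XtWz <- crossprod(X, w * z)
    A <- XtWX + diag(ridge_used, p)
    beta_new <- tryCatch(solve(A, XtWz), error = function(e) NULL)
    if (is.null(beta_new)) {
      # singular design (e.g. duplicated columns): minimal ridge keeps the
      # fitted linear predictor well-defined
      ridge_used <- max(ridge_used, 1e-6)
      beta_new <- solve(XtWX + diag(ridge_used, p), XtWz)
    }
    beta <- beta_new
    eta <- drop(X %*% beta)
    loglik <- sum(y * eta - log1pexp(eta))
    if (abs(loglik - loglik_old) < tol * (abs(loglik) + 0.1)) {
      converged <- TRUE
      break
    }
    loglik_old <- loglik
  }
  eta <- drop(X %*% beta)
  mu <- stats::plogis(eta)
  w <- pmin(pmax(mu, 1e-12), 1 - 1e-12)
  w <- w * (1 - w)
  info <- crossprod(X, X * w) + diag(ridge_used, p)
  V <- tryCatch(solve(info), error = function(e) matrix(NA_real_, p, p))
  list(beta = beta, se = sqrt(pmax(diag(V), 0)), vcov = V,
       loglik = sum(y * eta - log1pexp(eta)),
       converged = converged, iter = iter, ridge_used = ridge_used)
}

#' Fit a logistic model by outcome and predictor names
#'
#' Thin wrapper around [rf_glm()] taking the outcome and predictor subset as
#' character vectors — the natural interface for programmatic subset search.
#'
#' @param data data frame of ablation applications (see [generate_cohort()]).
#' @param outcome outcome column name, `"transmural"` or `"steam_pop"` for
#'   the standard cohorts (any 0/1 column is accepted).
#' @param predictors non-empty character vector of predictor column names,
#'   without duplicates.
#' @param ... passed on to [rf_glm()] (`tol`, `max_iter`, `ridge`, ...).
#' @return an `rf_glm` object.
#' @export
fit_logistic <- function(data, outcome, predictors, ...) {
  if (length(predictors) < 1) stop_input("predictors must be non-empty")
  if (anyDuplicated(predictors)) stop_input("duplicate predictors in spec")
  missing_cols <- setdiff(c(outcome, predictors), names(data))
  if (length(missing_cols))
    stop_input("columns not found in data: ", paste(missing_cols, collapse = ", "))
  f <- stats::reformulate(sprintf("`%s`", predictors), response = outcome)
  fit <- rf_glm(f, data, ...)
  fit$call <- match.call()
  fit
}

#' @export
print.rf_glm <- function(x, digits = 4, ...) {
  cat("Binomial logit GLM (IRLS): ", x$outcome, " ~ ",
      paste(x$predictors, collapse = " + "), "\n", sep = "")
  print(round(x$coefficients, digits))
  cat("log-likelihood:", format(x$log_likelihood, digits = 6),
      " n:", x$n_used,
      " converged:", x$converged,
      if (x$separation) " [separation]" else "", "\n")
  invisible(x)
}

#' @export
summary.rf_glm <- function(object, ...) {
  z <- object$coefficients / object$se
  tab <- cbind(Estimate = object$coefficients, `Std. Error` = object$se,
               `z value` = z, `Pr(>|z|)` = 2 * stats::pnorm(-abs(z)))
  structure(list(coefficients = tab, log_likelihood = object$log_likelihood,
                 n_used = object$n_used, converged = object$converged,
                 separation = object$separation, outcome = object$outcome,
                 predictors = object$predictors),
            class = "summary.rf_glm")
}

#' @export
print.summary.rf_glm <- function(x, ...) {
  cat("Binomial logit GLM: ", x$outcome, " ~ ",
      paste(x$predictors, collapse = " + "), "\n\n", sep = "")
  stats::printCoefmat(x$coefficients, P.values = TRUE, has.Pvalue = TRUE)
  cat("\nlog-likelihood ", format(x$log_likelihood, digits = 6),
      " on n = ", x$n_used, if (!x$converged) "  (NOT converged)", "\n",
      sep = "")
  invisible(x)
}

#' @export
coef.rf_glm <- function(object, ...) object$coefficients

#' @export
vcov.rf_glm <- function(object, ...) object$vcov

#' @export
logLik.rf_glm <- function(object, ...) {
  structure(object$log_likelihood, df = length(object$coefficients),
            nobs = object$n_used, class = "logLik")
}

#' @export
predict.rf_glm <- function(object, newdata, type = c("response", "link"), ...) {
  type <- match.arg(type)
  missing_cols <- setdiff(object$predictors, names(newdata))
  if (length(missing_cols))
    stop_input("missing predictor columns: ", paste(missing_cols, collapse = ", "))
  X <- cbind(`(Intercept)` = 1,
             as.matrix(newdata[, object$predictors, drop = FALSE]))
  b <- object$coefficients
  b[is.na(b)] <- 0  # aliased columns contribute nothing
  eta <- drop(X %*% b)
  if (type == "link") eta else stats::plogis(eta)
}

#' Predicted event probabilities with the linear predictor attached
#'
#' Evaluates a fitted logistic model on new rows, returning probabilities in
#' (0, 1) via the logistic sigmoid; the linear predictor (logit scale) is
#' attached as the `"linear_predictor"` attribute.
#'
#' @param model an `rf_glm` object.
#' @param rows data frame containing all model predictors.
#' @return numeric vector of probabilities with attribute `linear_predictor`.
#' @export
predict_probability <- function(model, rows) {
  eta <- predict(model, rows, type = "link")
  structure(stats::plogis(eta), linear_predictor = eta)
}

#' @export
residuals.rf_glm <- function(object, data,
                             type = c("deviance", "pearson", "response"), ...) {
  type <- match.arg(type)
  y <- check_binary(data[[object$outcome]])
  mu <- predict(object, data, type = "response")
  switch(type,
         response = y - mu,
         pearson = (y - mu) / sqrt(mu * (1 - mu)),
         deviance = sign(y - mu) *
           sqrt(-2 * (y * log(mu) + (1 - y) * log(1 - mu))))
}

#' @export
simulate.rf_glm <- function(object, nsim = 1, seed = NULL, newdata, ...) {
  if (!is.null(seed)) set.seed(seed)
  mu <- predict(object, newdata, type = "response")
  out <- as.data.frame(replicate(nsim, stats::rbinom(length(mu), 1, mu)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' Serialise a fitted model to JSON
#'
#' Writes the model specification, intercept, coefficients, standard errors
#' and convergence metadata as a JSON file (or returns the JSON string).
#'
#' @param model an `rf_glm` object.
#' @param path optional file path; if `NULL` the JSON string is returned.
#' @return the JSON string, invisibly when written to file.
#' @export
model_to_json <- function(model, path = NULL) {
  obj <- list(
    outcome = model$outcome,
    predictors = model$predictors,
    intercept = unname(model$coefficients[1]),
    coefficients = as.list(model$coefficients[-1]),
    standard_errors = as.list(model$se),
    converged = model$converged,
    separation = model$separation,
    ridge_used = model$ridge_used,
    n_used = model$n_used,
    log_likelihood = model$log_likelihood
  )
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
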