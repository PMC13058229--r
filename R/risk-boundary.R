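#' The two-predictor steam-pop risk-boundary model
#'
#' A logistic model of steam-pop occurrence in the two experimentally
#' controllable variables — tissue thickness (mm) and RF power (W) — with a
#' boundary statistic
#' \deqn{Z = z\_scale \cdot (1 + e^{L}), \quad
#'       L = intercept + coef_{thickness} t + coef_{power} E.}
#' Because \eqn{1 + e^L = 1/(1 - p)} with \eqn{p = \sigma(L)} the event
#' probability, \eqn{Z = z\_scale / (1 - p)}: Z is strictly increasing in p,
#' and the `Z = 1` isopleth coincides pointwise with the fixed-probability
#' contour \eqn{p = 1 - z\_scale} (0.9257, i.e. 92.6%, at the default
#' scale). The default constants are the published values of record; note
#' their thickness coefficient is positive (higher risk in thicker tissue),
#' which runs against the univariate observation that pops cluster in
#' thinner tissue — `flip_thickness_sign = TRUE` lets you explore the
#' sign-reversed model, but no silent correction is applied.
#'
#' @param intercept,coef_thickness,coef_power logit coefficients
#'   (per mm, per W).
#' @param z_scale scale of the boundary statistic, in (0, 1).
#' @param flip_thickness_sign negate the thickness coefficient.
#' @return a list of class `boundary_model`.
#' @export
boundary_model <- function(intercept = -4.9498, coef_thickness = 1.0729,
                           coef_power = -0.09030, z_scale = 0.0743,
                           flip_thickness_sign = FALSE) {
  if (z_scale <= 0 || z_scale >= 1) stop_input("z_scale must be in (0, 1)")
  if (flip_thickness_sign) coef_thickness <- -coef_thickness
  structure(list(intercept = intercept, coef_thickness = coef_thickness,
                 coef_power = coef_power, z_scale = z_scale),
            class = "boundary_model")
}

#' @export
print.boundary_model <- function(x, ...) {
  cat(sprintf("steam-pop boundary: logit = %.4f %+.4f*thickness %+.5f*power; Z = %.4f*(1+e^logit)\n",
              x$intercept, x$coef_thickness, x$coef_power, x$z_scale))
  cat(sprintf("Z = 1 isopleth marks event probability %.4f\n", 1 - x$z_scale))
  invisible(x)
}

boundary_logit <- function(thickness, power, model) {
  model$intercept + model$coef_thickness * thickness +
    model$coef_power * power
}

#' Boundary statistic Z at given thickness and power
#'
#' `Z = z_scale * (1 + exp(L))` with `L` the model logit; equivalently
#' `Z = z_scale / (1 - p)` where `p` is the steam-pop probability. `Z`
#' approaches `z_scale` from above as the probability vanishes and diverges
#' as it approaches 1; `Z = 1` marks probability `1 - z_scale`.
#'
#' @param thickness tissue thickness (mm); vectorised.
#' @param power RF power (W); vectorised.
#' @param model a [boundary_model()].
#' @return the Z statistic (positive real).
#' @export
z_statistic <- function(thickness, power, model = boundary_model()) {
  model$z_scale * (1 + exp(boundary_logit(thickness, power, model)))
}

#' Power on a Z-isopleth at a given thickness
#'
#' Solves `z_statistic(thickness, E, model) = z` for the power `E` in closed
#' form: the target logit is `L* = log(z / z_scale - 1)` and
#' `E* = (L* - intercept - coef_thickness * thickness) / coef_power`. `E*`
#' is affine in thickness.
#'
#' @param thickness tissue thickness (mm); vectorised.
#' @param model a [boundary_model()].
#' @param z isopleth level; must exceed `z_scale`.
#' @return power in W.
#' @export
boundary_power <- function(thickness, model = boundary_model(), z = 1) {
  if (model$coef_power == 0)
    stop_input("degenerate model: power coefficient is zero")
  if (z <= model$z_scale)
    stop_input("no solution: z must exceed z_scale = ", model$z_scale)
  l_star <- log(z / model$z_scale - 1)
  (l_star - model$intercept - model$coef_thickness * thickness) /
    model$coef_power
}

#' Event-probability surface of a fitted model over a predictor grid
#'
#' Evaluates [predict_probability()] over the Cartesian product of grid
#' ranges, holding the remaining predictors fixed — e.g. pop probability as
#' a function of the 5-s percentage impedance drop for each power level at a
#' fixed baseline impedance of 92 Ω. The output is a long-format table
#' suitable for plotting probability curves.
#'
#' @param model an [rf_glm] fitted model.
#' @param grid named list of numeric vectors to vary.
#' @param fixed named list of scalar values for the remaining predictors.
#' @return data frame: one column per predictor plus `linear_predictor` and
#'   `probability`.
#' @export
probability_surface <- function(model, grid = list(), fixed = list()) {
  covered <- c(names(grid), names(fixed))
  missing_cols <- setdiff(model$predictors, covered)
  if (length(missing_cols))
    stop_input("predictors not covered by grid or fixed: ",
               paste(missing_cols, collapse = ", "))
  if (length(grid)) {
    tab <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE)
  } else {
    tab <- data.frame(row.names = 1)
  }
  for (nm in names(fixed)) tab[[nm]] <- fixed[[nm]]
  p <- predict_probability(model, tab)
  tab$linear_predictor <- attr(p, "linear_predictor")
  tab$probability <- as.numeric(p)
  rownames(tab) <- NULL
  tab
}

#' Export a Z = z boundary curve over thickness
#'
#' @param model a [boundary_model()].
#' @param thickness numeric vector of thicknesses (mm).
#' @param z isopleth level.
#' @return data frame with `thickness`, `power`, `z`, `probability`.
#' @export
boundary_curve <- function(model = boundary_model(),
                           thickness = seq(8, 20, by = 0.5), z = 1) {
  pw <- boundary_power(thickness, model, z = z)
  data.frame(thickness = thickness, power = pw, z = z,
             probability = stats::plogis(boundary_logit(thickness, pw, model)))
}
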