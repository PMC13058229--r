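#' Inversion query for depth prediction
#'
#' Parameters for inverting a fitted transmurality model: the delivery
#' settings, the transmurality probability level that operationally defines
#' "achievable lesion depth", and the thickness bracket searched.
#'
#' @param rf_power RF power (W).
#' @param rf_duration RF duration (s).
#' @param target_probability probability level in (0, 1); default 0.5.
#' @param thickness_bracket search bracket (lo, hi) in mm.
#' @return list of class `inversion_query`.
#' @export
inversion_query <- function(rf_power, rf_duration, target_probability = 0.5,
                            thickness_bracket = c(1, 40)) {
  if (target_probability <= 0 || target_probability >= 1)
    stop_input("target_probability must be strictly inside (0, 1)")
  if (thickness_bracket[1] >= thickness_bracket[2])
    stop_input("thickness_bracket must satisfy lo < hi")
  structure(list(rf_power = rf_power, rf_duration = rf_duration,
                 target_probability = target_probability,
                 thickness_bracket = thickness_bracket),
            class = "inversion_query")
}

# thickness-direction derivative of the logit after substituting the
# impedance-thickness relation
thickness_gradient <- function(model, impedance_slope) {
  b <- coef(model)
  unname(b["thickness"] + b["init_impedance"] * impedance_slope)
}

depth_row <- function(t, query, impedance_intercept, impedance_slope) {
  data.frame(rf_power = query$rf_power, rf_duration = query$rf_duration,
             init_impedance = impedance_intercept + impedance_slope * t,
             thickness = t)
}

#' Predicted achievable lesion depth for a power-duration pair
#'
#' Rearranges a fitted transmurality model over
#' `{rf_power, init_impedance, rf_duration, thickness}` to answer: up to
#' what tissue thickness does this delivery still reach the target
#' transmurality probability? Baseline impedance is tied to thickness
#' through the linear relation `impedance_intercept +
#' impedance_slope * thickness`, so the logit becomes a linear function of
#' thickness alone and the target level is located by bisection (to 1e-6 mm)
#' on the query bracket. The root is interpreted as the predicted lesion
#' depth in mm.
#'
#' Requires the effective thickness gradient of the logit
#' (`coef_thickness + coef_impedance * impedance_slope`) to be negative —
#' transmurality must become less likely in thicker tissue for "depth" to
#' be meaningful.
#'
#' @param model an [rf_glm] transmurality model with predictors
#'   `rf_power`, `init_impedance`, `rf_duration`, `thickness`.
#' @param query an [inversion_query()].
#' @param impedance_intercept,impedance_slope impedance-thickness relation
#'   (Ω, Ω/mm); defaults are the relation used throughout the package.
#' @param tol bisection tolerance (mm).
#' @return predicted depth in mm.
#' @export
predict_depth <- function(model, query,
                          impedance_intercept = 86.213122,
                          impedance_slope = 0.5057449, tol = 1e-6) {
  need <- c("rf_power", "init_impedance", "rf_duration", "thickness")
  missing_cols <- setdiff(need, model$predictors)
  if (length(missing_cols))
    stop_input("model must use predictors: ", paste(need, collapse = ", "))
  grad <- thickness_gradient(model, impedance_slope)
  if (grad >= 0)
    stop_input("invalid model: transmurality probability does not decrease ",
               "with thickness (effective gradient ", signif(grad, 4), ")")
  br <- query$thickness_bracket
  f <- function(t) {
    predict(model, depth_row(t, query, impedance_intercept, impedance_slope),
            type = "link") - stats::qlogis(query$target_probability)
  }
  flo <- f(br[1])
  fhi <- f(br[2])
  if (flo * fhi > 0) {
    side <- if (flo < 0) "below" else "above"
    stop_input("no root in bracket: probability is everywhere ", side,
               " the target on [", br[1], ", ", br[2], "] mm")
  }
  root <- stats::uniroot(f, br, tol = tol)$root
  # the substituted logit is exactly linear in thickness, so one Newton step
  # polishes the bisection root to machine precision
  root - f(root) / grad
}

#' Duration required to reach a target transmurality probability
#'
#' Solves the fitted logit for the duration at which the model reaches
#' `target_probability` for a given power and tissue thickness (closed form
#' — the logit is linear in duration). Durations outside the bench-tested
#' 20-180 s range are flagged as extrapolation; a negative solution means
#' the target is already exceeded at 0 s.
#'
#' @param model as in [predict_depth()].
#' @param rf_power RF power (W).
#' @param thickness tissue thickness (mm).
#' @param target_probability transmurality probability level in (0, 1).
#' @param impedance_intercept,impedance_slope impedance-thickness relation.
#' @param tested_range duration range covered by the bench experiment (s).
#' @return list with `duration` (s), `extrapolation` (logical) and `note`.
#' @export
required_duration <- function(model, rf_power, thickness,
                              target_probability = 0.5,
                              impedance_intercept = 86.213122,
                              impedance_slope = 0.5057449,
                              tested_range = c(20, 180)) {
  if (target_probability <= 0 || target_probability >= 1)
    stop_input("target_probability must be strictly inside (0, 1)")
  b <- coef(model)
  if (!"rf_duration" %in% names(b) || b[["rf_duration"]] == 0)
    stop_input("degenerate model: zero duration coefficient")
  z <- impedance_intercept + impedance_slope * thickness
  base <- b[["(Intercept)"]] + b[["rf_power"]] * rf_power +
    b[["init_impedance"]] * z + b[["thickness"]] * thickness
  d <- (stats::qlogis(target_probability) - base) / b[["rf_duration"]]
  extrap <- d < tested_range[1] || d > tested_range[2]
  note <- if (d < 0) "already exceeded at 0 s"
          else if (extrap) "extrapolation beyond tested durations"
          else ""
  list(duration = unname(d), extrapolation = extrap, note = note)
}

#' Depth look-up curves over duration per power level
#'
#' Tabulates [predict_depth()] over a duration grid for each power level —
#' the data behind depth-versus-duration curves.
#'
#' @param model as in [predict_depth()].
#' @param powers power levels (W).
#' @param durations duration grid (s).
#' @param target_probability probability level defining depth.
#' @param ... passed to [predict_depth()].
#' @return data frame `rf_power`, `rf_duration`, `depth_mm` (NA where the
#'   target level is not reached inside the default bracket).
#' @export
depth_curves <- function(model, powers = c(20, 30, 40, 50),
                         durations = seq(20, 200, by = 20),
                         target_probability = 0.5, ...) {
  grid <- expand.grid(rf_power = powers, rf_duration = durations,
                      KEEP.OUT.ATTRS = FALSE)
  grid$depth_mm <- vapply(seq_len(nrow(grid)), function(i) {
    q <- inversion_query(grid$rf_power[i], grid$rf_duration[i],
                         target_probability)
    tryCatch(predict_depth(model, q, ...), error = function(e) NA_real_)
  }, 0)
  grid
}
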