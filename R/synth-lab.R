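#' Configuration for the synthetic ablation-cohort generator
#'
#' Bundles every constant of the generative model emulating a bench
#' ex vivo bipolar ablation experiment: ventricular myocardium slabs of
#' nominal thickness 10/15/20 mm ablated catheter-to-catheter at 20–50 W for
#' 20–180 s, with baseline bipolar impedance rising linearly with tissue
#' thickness, an early (5-s) impedance drop driven by power, and two latent
#' logistic outcome mechanisms: steam-pop occurrence and lesion
#' transmurality. Steam pops truncate the delivery, so the realised duration
#' can be shorter than planned.
#'
#' The default coefficients are calibrated so that, under the full factorial
#' `grid` design, the marginal transmural rate is close to 49% and the
#' steam-pop rate close to 5.7%, and so that the conditional medians of the
#' 5-s impedance drop are near −9.4 Ω / −10.0% in pop applications versus
#' −5.8 Ω / −6.4% in pop-free ones. Impedance drops are stored signed
#' (negative = drop) throughout.
#'
#' The `boundary_adjacent` design emulates a validation experiment run at
#' conditions deliberately close to the steam-pop risk boundary: thickness
#' is drawn uniformly on `boundary_thickness_range`, the power is set to the
#' boundary power for that thickness (see [boundary_power()]) plus a uniform
#' perturbation of half-width `boundary_band_w`, clipped to the generator's
#' power range, and the planned duration is fixed at 60 s.
#'
#' @param thickness_levels nominal slab thicknesses (mm).
#' @param thickness_jitter_sd SD of Gaussian jitter around each level (mm).
#' @param power_levels generator power settings (W).
#' @param duration_levels planned application durations (s).
#' @param impedance_intercept,impedance_slope linear baseline
#'   impedance–thickness relation (Ω and Ω/mm).
#' @param impedance_noise_sd SD of Gaussian impedance noise (Ω).
#' @param drop5_coefficients named vector `(intercept, per_watt, per_ohm,
#'   noise_sd)` of the linear model for the 5-s impedance drop (Ω).
#' @param pop_coefficients named vector `(intercept, rf_power,
#'   pct_imp_drop5, thickness)` of the steam-pop logit.
#' @param transmural_coefficients named vector `(intercept, rf_power,
#'   rf_duration_actual, init_impedance, thickness)` of the transmurality
#'   logit.
#' @param pop_min_time earliest time (s) at which a pop can truncate the
#'   delivery; actual duration of a popped application is uniform on
#'   (`pop_min_time`, planned).
#' @param design `"grid"` (full factorial) or `"boundary_adjacent"`.
#' @param boundary_model [boundary_model()] used by the
#'   `boundary_adjacent` design.
#' @param boundary_thickness_range,boundary_band_w validation design
#'   parameters (mm range, W half-width).
#' @param seed integer seed recorded in the config and used by
#'   [generate_cohort()] unless overridden.
#' @return a list of class `rf_generator_config`.
#' @export
generator_config <- function(thickness_levels = c(10, 15, 20),
                             thickness_jitter_sd = 0.8,
                             power_levels = c(20, 30, 40, 50),
                             duration_levels = c(20, 60, 180),
                             impedance_intercept = 86.213122,
                             impedance_slope = 0.5057449,
                             impedance_noise_sd = 3.0,
                             drop5_coefficients = c(intercept = -9.35,
                                                    per_watt = -0.12,
                                                    per_ohm = 0.08,
                                                    noise_sd = 2.3),
                             pop_coefficients = c(intercept = -5.15,
                                                  rf_power = 0.08,
                                                  pct_imp_drop5 = -0.55,
                                                  thickness = -0.45),
                             transmural_coefficients = c(intercept = 8.75,
                                                         rf_power = 0.09,
                                                         rf_duration_actual = 0.012,
                                                         init_impedance = -0.05,
                                                         thickness = -0.55),
                             pop_min_time = 5,
                             design = c("grid", "boundary_adjacent"),
                             boundary_model = NULL,
                             boundary_thickness_range = c(8, 12),
                             boundary_band_w = 5,
                             seed = 1L) {
  design <- match.arg(design)
  cfg <- list(thickness_levels = thickness_levels,
              thickness_jitter_sd = thickness_jitter_sd,
              power_levels = power_levels,
              duration_levels = duration_levels,
              impedance_intercept = impedance_intercept,
              impedance_slope = impedance_slope,
              impedance_noise_sd = impedance_noise_sd,
              drop5_coefficients = drop5_coefficients,
              pop_coefficients = pop_coefficients,
              transmural_coefficients = transmural_coefficients,
              pop_min_time = pop_min_time,
              design = design,
              boundary_model = boundary_model,
              boundary_thickness_range = boundary_thickness_range,
              boundary_band_w = boundary_band_w,
              seed = as.integer(seed))
  validate_generator_config(cfg)
  structure(cfg, class = "rf_generator_config")
}

validate_generator_config <- function(cfg) {
  for (nm in c("thickness_levels", "power_levels", "duration_levels"))
    if (length(cfg[[nm]]) < 1 || any(cfg[[nm]] <= 0))
      stop_input(nm, " must be a non-empty vector of positive values")
  for (nm in c("thickness_jitter_sd", "impedance_noise_sd"))
    if (cfg[[nm]] < 0) stop_input(nm, " must be >= 0")
  if (cfg$drop5_coefficients[["noise_sd"]] < 0)
    stop_input("drop5 noise_sd must be >= 0")
  need <- list(drop5_coefficients = c("intercept", "per_watt", "per_ohm", "noise_sd"),
               pop_coefficients = c("intercept", "rf_power", "pct_imp_drop5", "thickness"),
               transmural_coefficients = c("intercept", "rf_power",
                                           "rf_duration_actual",
                                           "init_impedance", "thickness"))
  for (nm in names(need))
    if (!all(need[[nm]] %in% names(cfg[[nm]])))
      stop_input(nm, " must name: ", paste(need[[nm]], collapse = ", "))
  if (!cfg$design %in% c("grid", "boundary_adjacent"))
    stop_input("unknown design: ", cfg$design)
  invisible(cfg)
}

#' Baseline bipolar impedance implied by tissue thickness
#'
#' Linear relation between slab thickness and initial catheter-to-catheter
#' impedance, `intercept + slope * thickness`, optionally with Gaussian
#' measurement noise.
#'
#' @param thickness tissue thickness in mm (> 0; vectorised).
#' @param config a [generator_config()].
#' @param noise if `TRUE`, add `N(0, impedance_noise_sd)` noise.
#' @return impedance in Ω.
#' @export
impedance_from_thickness <- function(thickness, config = generator_config(),
                                     noise = FALSE) {
  if (any(thickness <= 0)) stop_input("thickness must be positive")
  z <- config$impedance_intercept + config$impedance_slope * thickness
  if (noise && config$impedance_noise_sd > 0)
    z <- z + stats::rnorm(length(z), 0, config$impedance_noise_sd)
  z
}

#' Percentage 5-s impedance drop
#'
#' `pct = imp_drop5 * 100 / init_impedance`; signed, so a drop (negative Ω
#' change) gives a negative percentage.
#'
#' @param imp_drop5 5-s impedance change in Ω (negative = drop).
#' @param init_impedance initial impedance in Ω (> 0).
#' @return signed percentage.
#' @export
percent_imp_drop5 <- function(imp_drop5, init_impedance) {
  if (any(init_impedance <= 0)) stop_input("init_impedance must be positive")
  imp_drop5 * 100 / init_impedance
}

#' Generate a synthetic cohort of bipolar RF applications
#'
#' Draws a reproducible cohort from the generative model in
#' [generator_config()]. Each row is one RF application with its settings,
#' impedance kinetics, and binary outcomes.
#'
#' Mechanism, per application: (1) thickness = nominal level + jitter
#' (truncated positive); (2) baseline impedance from
#' [impedance_from_thickness()] plus noise; (3) 5-s impedance drop linear in
#' power and baseline impedance plus noise, percentage drop by
#' [percent_imp_drop5()]; (4) steam pop ~ Bernoulli(logit linear in power,
#' percentage drop, thickness); (5) if a pop occurs the delivery stops early
#' — actual duration uniform on (`pop_min_time`, planned) — otherwise actual
#' = planned; (6) transmurality ~ Bernoulli(logit linear in power, *actual*
#' duration, baseline impedance, thickness).
#'
#' @param config a [generator_config()].
#' @param n_per_cell applications per design cell (`grid` design).
#' @param n_total total applications; for `grid` it overrides `n_per_cell`
#'   by cycling through cells; required for `boundary_adjacent`.
#' @param cohort label stored in the `cohort` column
#'   (`"development"`/`"validation"`; defaults by design).
#' @param seed overrides `config$seed`.
#' @return a data frame with columns `rf_power`, `rf_duration_planned`,
#'   `rf_duration_actual`, `rf_duration` (alias of the *planned* duration —
#'   the operator-chosen setting, known before the outcome, and therefore
#'   the default modelling predictor; the pop-truncated actual duration is
#'   kept separately), `thickness`, `init_impedance`, `imp_drop5`,
#'   `pct_imp_drop5`, `transmural`, `steam_pop`, `cohort`.
#' @export
generate_cohort <- function(config = generator_config(), n_per_cell = NULL,
                            n_total = NULL, cohort = NULL, seed = NULL) {
  validate_generator_config(config)
  seed <- as.integer(seed %||% config$seed)
  if (is.null(cohort))
    cohort <- if (config$design == "grid") "development" else "validation"

  if (config$design == "grid") {
    cells <- expand.grid(thickness_level = config$thickness_levels,
                         rf_power = config$power_levels,
                         rf_duration_planned = config$duration_levels,
                         KEEP.OUT.ATTRS = FALSE)
    if (!is.null(n_total)) {
      if (n_total < 0) stop_input("n_total must be >= 0")
      idx <- rep_len(seq_len(nrow(cells)), n_total)
    } else {
      if (is.null(n_per_cell)) stop_input("give n_per_cell or n_total")
      if (n_per_cell < 0) stop_input("n_per_cell must be >= 0")
      idx <- rep(seq_len(nrow(cells)), each = n_per_cell)
    }
    des <- cells[idx, , drop = FALSE]
  } else {
    if (is.null(n_total)) stop_input("boundary_adjacent design needs n_total")
    if (n_total < 0) stop_input("n_total must be >= 0")
    des <- data.frame(thickness_level = numeric(n_total),
                      rf_power = numeric(n_total),
                      rf_duration_planned = numeric(n_total))
  }
  n <- nrow(des)
  if (n == 0) return(empty_cohort())

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)

  if (config$design == "boundary_adjacent") {
    bm <- config$boundary_model %||% boundary_model()
    rng <- config$boundary_thickness_range
    des$thickness_level <- stats::runif(n, rng[1], rng[2])
    pw <- vapply(des$thickness_level, boundary_power, 0, model = bm) +
      stats::runif(n, -config$boundary_band_w, config$boundary_band_w)
    des$rf_power <- pmin(pmax(pw, min(config$power_levels)),
                         max(config$power_levels))
    des$rf_duration_planned <- 60
    thickness <- pmax(des$thickness_level, 0.5)  # already continuous
  } else {
    thickness <- pmax(des$thickness_level +
                        stats::rnorm(n, 0, config$thickness_jitter_sd), 0.5)
  }

  init_imp <- config$impedance_intercept + config$impedance_slope * thickness +
    stats::rnorm(n, 0, config$impedance_noise_sd)
  init_imp <- pmax(init_imp, 1)

  dc <- config$drop5_coefficients
  drop5 <- dc[["intercept"]] + dc[["per_watt"]] * des$rf_power +
    dc[["per_ohm"]] * init_imp + stats::rnorm(n, 0, dc[["noise_sd"]])
  pct5 <- percent_imp_drop5(drop5, init_imp)

  pc <- config$pop_coefficients
  eta_pop <- pc[["intercept"]] + pc[["rf_power"]] * des$rf_power +
    pc[["pct_imp_drop5"]] * pct5 + pc[["thickness"]] * thickness
  pop <- stats::rbinom(n, 1, stats::plogis(eta_pop))

  dur_actual <- des$rf_duration_planned
  popped <- pop == 1
  if (any(popped))
    dur_actual[popped] <- stats::runif(sum(popped), config$pop_min_time,
                                       des$rf_duration_planned[popped])

  tc <- config$transmural_coefficients
  eta_tm <- tc[["intercept"]] + tc[["rf_power"]] * des$rf_power +
    tc[["rf_duration_actual"]] * dur_actual +
    tc[["init_impedance"]] * init_imp + tc[["thickness"]] * thickness
  tm <- stats::rbinom(n, 1, stats::plogis(eta_tm))

  out <- data.frame(rf_power = des$rf_power,
                    rf_duration_planned = des$rf_duration_planned,
                    rf_duration_actual = dur_actual,
                    rf_duration = des$rf_duration_planned,
                    thickness = thickness,
                    init_impedance = init_imp,
                    imp_drop5 = drop5,
                    pct_imp_drop5 = pct5,
                    transmural = tm,
                    steam_pop = pop,
                    cohort = cohort,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

empty_cohort <- function() {
  data.frame(rf_power = numeric(), rf_duration_planned = numeric(),
             rf_duration_actual = numeric(), rf_duration = numeric(),
             thickness = numeric(), init_impedance = numeric(),
             imp_drop5 = numeric(), pct_imp_drop5 = numeric(),
             transmural = integer(), steam_pop = integer(),
             cohort = character(), stringsAsFactors = FALSE)
}

#' Write / read a cohort as CSV with a seed side-car
#'
#' `write_cohort()` writes the fixed 11-column header CSV (12 significant
#' digits) plus an adjacent `<path>.meta.json` recording the seed and row
#' count; `read_cohort()` reads the same dialect back.
#'
#' @param data cohort data frame from [generate_cohort()].
#' @param path CSV file path.
#' @param seed seed recorded in the metadata side-car.
#' @return `write_cohort()`: the path, invisibly. `read_cohort()`: the
#'   cohort data frame.
#' @export
write_cohort <- function(data, path, seed = NA_integer_) {
  cols <- names(empty_cohort())
  stopifnot(all(cols %in% names(data)))
  out <- data[, cols, drop = FALSE]
  num <- vapply(out, is.numeric, TRUE)
  out[num] <- lapply(out[num], function(x) signif(x, 12))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  meta <- jsonlite::toJSON(list(seed = seed, n = nrow(data)),
                           auto_unbox = TRUE, na = "null")
  writeLines(meta, paste0(path, ".meta.json"))
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(names(empty_cohort()) %in% names(d)))
  d
}
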