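test_that("impedance-thickness relation matches the linear law", {
  cfg <- generator_config()
  expect_equal(cfg$impedance_intercept, 86.213122)
  expect_equal(impedance_from_thickness(10, cfg), 91.270571, tolerance = 1e-9)
  expect_equal(impedance_from_thickness(20, cfg), 96.328020, tolerance = 1e-9)
  # vectorised and deterministic without noise
  expect_equal(impedance_from_thickness(c(10, 20), cfg),
               c(91.270571, 96.328020), tolerance = 1e-9)
  expect_error(impedance_from_thickness(0, cfg), "positive")
  expect_error(impedance_from_thickness(-3, cfg), "positive")
})

test_that("percentage impedance drop is signed arithmetic", {
  expect_equal(percent_imp_drop5(0, 92), 0)
  expect_equal(percent_imp_drop5(-9.2, 92), -10)
  expect_equal(percent_imp_drop5(-5.77, 93), -5.77 * 100 / 93)
  expect_gt(percent_imp_drop5(2, 90), 0)
  expect_error(percent_imp_drop5(-5, 0), "positive")
})

test_that("generated rows satisfy the structural invariants", {
  cfg <- generator_config()
  d <- generate_cohort(cfg, n_per_cell = 20, seed = 7)
  expect_equal(d$pct_imp_drop5, d$imp_drop5 * 100 / d$init_impedance,
               tolerance = 1e-9)
  expect_true(all(d$init_impedance > 0))
  expect_true(all(d$thickness > 0))
  expect_true(all(d$rf_duration_actual <= d$rf_duration_planned))
  early <- d$rf_duration_actual < d$rf_duration_planned
  expect_true(all(d$steam_pop[early] == 1))
  expect_true(all(d$rf_duration_actual[d$steam_pop == 0] ==
                    d$rf_duration_planned[d$steam_pop == 0]))
  expect_true(all(d$rf_duration == d$rf_duration_planned))
})

test_that("cohort generation is reproducible, byte-identical as CSV", {
  cfg <- generator_config()
  f1 <- tempfile(fileext = ".csv")
  f2 <- tempfile(fileext = ".csv")
  write_cohort(generate_cohort(cfg, n_per_cell = 10, seed = 123), f1, seed = 123)
  write_cohort(generate_cohort(cfg, n_per_cell = 10, seed = 123), f2, seed = 123)
  expect_identical(readLines(f1), readLines(f2))
  back <- read_cohort(f1)
  orig <- generate_cohort(cfg, n_per_cell = 10, seed = 123)
  expect_equal(back$init_impedance, orig$init_impedance, tolerance = 1e-11)
  # different seed changes the draw
  d2 <- generate_cohort(cfg, n_per_cell = 10, seed = 124)
  expect_false(identical(orig$init_impedance, d2$init_impedance))
})

test_that("degenerate sizes and the no-pop limit behave", {
  cfg <- generator_config()
  expect_identical(nrow(generate_cohort(cfg, n_total = 0)), 0L)
  expect_error(generate_cohort(cfg, n_total = -1), ">= 0")
  expect_error(generate_cohort(cfg), "n_per_cell or n_total")
  # forcing pop probability to zero leaves every delivery un-truncated
  nopop <- generator_config(pop_coefficients = c(intercept = -1e6, rf_power = 0,
                                                 pct_imp_drop5 = 0, thickness = 0))
  d <- generate_cohort(nopop, n_per_cell = 5, seed = 1)
  expect_true(all(d$steam_pop == 0))
  expect_true(all(d$rf_duration_actual == d$rf_duration_planned))
})

test_that("generator config validation rejects malformed input", {
  expect_error(generator_config(thickness_levels = numeric()), "non-empty")
  expect_error(generator_config(power_levels = c(30, -10)), "positive")
  expect_error(generator_config(impedance_noise_sd = -1), ">= 0")
  expect_error(generator_config(pop_coefficients = c(intercept = 0)),
               "must name")
})

test_that("default calibration reproduces the bench outcome rates", {
  cfg <- generator_config()
  d <- generate_cohort(cfg, n_per_cell = 500, seed = 2024)
  expect_lt(abs(mean(d$transmural) - 0.49), 0.05)
  expect_lt(abs(mean(d$steam_pop) - 0.057), 0.03)
  # pop applications show larger (more negative) early percentage drops
  med_pop <- median(d$pct_imp_drop5[d$steam_pop == 1])
  med_nopop <- median(d$pct_imp_drop5[d$steam_pop == 0])
  expect_lt(med_pop, med_nopop)
  expect_lt(med_pop, 0)
  expect_lt(med_nopop, 0)
})

test_that("boundary-adjacent design fixes duration and hugs the isopleth", {
  cfg <- generator_config(design = "boundary_adjacent")
  d <- generate_cohort(cfg, n_total = 200, seed = 5)
  expect_true(all(d$rf_duration_planned == 60))
  expect_true(all(d$cohort == "validation"))
  rng <- cfg$boundary_thickness_range
  expect_true(all(d$thickness >= rng[1] & d$thickness <= rng[2]))
  # powers sit within the configured band of the boundary (up to clipping)
  ideal <- boundary_power(d$thickness, boundary_model())
  clipped <- pmin(pmax(ideal - cfg$boundary_band_w, 20),
                  50) - 1e-9 <= d$rf_power &
    d$rf_power <= pmin(pmax(ideal + cfg$boundary_band_w, 20), 50) + 1e-9
  expect_true(all(clipped))
  # both outcomes occur at an appreciable rate near the boundary
  expect_gt(mean(d$steam_pop), 0.02)
  expect_gt(mean(d$transmural), 0.5)
})
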