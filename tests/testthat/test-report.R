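fixture_counts <- function(n, n_tm, n_pop) {
  data.frame(transmural = rep(c(1, 0), c(n_tm, n - n_tm)),
             steam_pop = rep(c(1, 0), c(n_pop, n - n_pop)))
}

test_that("outcome summaries reproduce printed rates from printed counts", {
  s <- summarize_outcomes(fixture_counts(194, 95, 11))
  expect_equal(s$rate_transmural, 49)
  expect_equal(s$rate_pop, 5.7)
  s2 <- summarize_outcomes(fixture_counts(111, 102, 25), pop_digits = 0)
  expect_equal(s2$rate_transmural, 92)
  expect_equal(s2$rate_pop, 23)
  expect_equal(summarize_outcomes(fixture_counts(111, 102, 25))$rate_pop, 22.5)
  s3 <- summarize_outcomes(data.frame(transmural = 1, steam_pop = 0))
  expect_equal(s3$rate_transmural, 100)
  expect_equal(s3$n, 1)
  expect_error(summarize_outcomes(fixture_counts(0, 0, 0)), "empty")
})

test_that("summary counts are invariant to row order", {
  co <- make_cohorts(seed = 71)
  d <- co$dev
  s1 <- summarize_outcomes(d)
  s2 <- summarize_outcomes(d[rev(seq_len(nrow(d))), ])
  expect_equal(s1$n_transmural, s2$n_transmural)
  expect_equal(s1$n_pop, s2$n_pop)
  expect_equal(s1$rate_transmural, s2$rate_transmural)
})

test_that("group comparison matches exact permutation enumeration at small n", {
  x1 <- c(3.1, 5.2, 4.4, 6.7, 2.9)
  x0 <- c(1.2, 2.8, 3.3, 0.9, 1.7)
  d <- data.frame(v = c(x1, x0), g = rep(c(1, 0), each = 5))
  tab <- compare_groups(d, by = "g", variables = "v")
  expect_equal(tab$p_value, ranksum_permutation_p(x1, x0), tolerance = 1e-12)
  expect_equal(tab$median_g1, median(x1))
  expect_equal(c(tab$q1_g0, tab$q3_g0),
               unname(quantile(x0, c(0.25, 0.75))))
})

test_that("identical groups give maximal p and zero median difference", {
  d <- data.frame(v = rep(c(1.5, 2.5, 3.5, 4.5), 2),
                  g = rep(c(1, 0), each = 4))
  tab <- compare_groups(d, by = "g", variables = "v")
  expect_equal(tab$median_g1, tab$median_g0)
  expect_gt(tab$p_value, 0.99)
  expect_error(compare_groups(data.frame(v = 1:3, g = c(1, 1, 1)),
                              by = "g", variables = "v"), "degenerate")
})

test_that("with generator defaults, pops occur in thinner tissue with bigger drops", {
  cfg <- generator_config()
  d <- generate_cohort(cfg, n_per_cell = 100, seed = 72)
  tab <- compare_groups(d, by = "steam_pop",
                        variables = c("thickness", "pct_imp_drop5", "rf_power"))
  row <- function(v) tab[tab$variable == v, ]
  expect_lt(row("thickness")$median_g1, row("thickness")$median_g0)
  expect_lt(row("pct_imp_drop5")$median_g1, row("pct_imp_drop5")$median_g0)
  expect_gt(row("rf_power")$median_g1, row("rf_power")$median_g0)
  expect_lt(row("thickness")$p_value, 0.001)
})

test_that("table export round-trips losslessly and keeps the ranking order", {
  co <- make_cohorts(seed = 73)
  ev <- evaluate_all(co$dev, co$val, "steam_pop",
                     predictors = c("rf_power", "pct_imp_drop5", "thickness"))
  at <- attribute_auc(co$dev, co$val, "steam_pop",
                      predictors = c("rf_power", "pct_imp_drop5", "thickness"))
  out <- tempfile()
  files <- export_tables(ev, at, out)
  expect_true(all(file.exists(files)))
  back <- read.csv(files[["models"]], stringsAsFactors = FALSE)
  expect_equal(nrow(back), nrow(ev))
  expect_equal(back$auc_val, ev$auc_val, tolerance = 1e-11)
  expect_equal(back$model, ev$model)
  # descending-AUC order with deterministic tie-break survives the round trip
  expect_equal(back$model, back$model[order(-back$auc_val, back$model)])
  forest <- read.csv(files[["forest"]], stringsAsFactors = FALSE)
  expect_equal(names(forest), c("model", "auc", "lo", "hi"))
  js <- jsonlite::fromJSON(paste(readLines(files[["json"]]), collapse = ""))
  expect_equal(nrow(js$models), nrow(ev))
  expect_equal(js$auc_full, attr(at, "auc_full"))
  expect_error(export_tables(ev[0, ], NULL, out), "empty")
})

test_that("the end-to-end pipeline writes every artefact", {
  out <- tempfile()
  res <- run_rf_analysis(seed = 8, n_dev_per_cell = 4, n_val = 80,
                         out_dir = out)
  expect_s3_class(res$search_pop, "rf_model_ranking")
  expect_equal(nrow(res$search_pop), 62)  # duration-only model excluded a priori
  expect_s3_class(res$attribution_pop, "rf_attribution")
  expect_true(all(file.exists(file.path(out,
    c("development.csv", "validation.csv", "transmural_models.csv",
      "steam_pop_models.csv", "boundary_curve.csv", "depth_curves.csv")))))
})
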