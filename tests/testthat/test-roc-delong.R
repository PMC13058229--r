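test_that("midrank AUC equals brute-force pair counting on random fixtures", {
  set.seed(42)
  for (i in 1:50) {
    n <- sample(4:20, 1)
    labels <- c(0, 1, rbinom(n - 2, 1, 0.5))
    scores <- sample(round(rnorm(n), 1))  # rounding forces ties
    r <- roc_auc(scores, labels)
    expect_equal(r$auc, auc_bruteforce(scores, labels), tolerance = 1e-12)
    expect_true(r$ci95[1] <= r$auc && r$auc <= r$ci95[2])
    expect_true(r$ci95[1] >= 0 && r$ci95[2] <= 1)
  }
})

test_that("AUC hits its degenerate corners", {
  expect_equal(roc_auc(c(3, 4, 1, 2), c(1, 1, 0, 0))$auc, 1)
  expect_equal(roc_auc(rep(1, 6), c(1, 0, 1, 0, 1, 0))$auc, 0.5)
  expect_equal(roc_auc(rep(1, 6), c(1, 0, 1, 0, 1, 0))$delong_variance, 0)
  expect_error(roc_auc(1:4, c(1, 1, 1, 1)), "degenerate")
  expect_error(roc_auc(1:3, c(1, 0)), "length")
  expect_error(roc_auc(c(1, NA, 3), c(1, 0, 1)), "finite")
})

test_that("AUC is rank-based: monotone-transform invariant, complement under negation", {
  set.seed(9)
  scores <- rnorm(30)
  labels <- rbinom(30, 1, 0.4)
  labels[1:2] <- c(0, 1)
  a <- roc_auc(scores, labels)
  b <- roc_auc(exp(2 * scores) + 5, labels)
  expect_equal(a$auc, b$auc)
  expect_equal(a$delong_variance, b$delong_variance)
  expect_equal(roc_auc(-scores, labels)$auc, 1 - a$auc)
})

test_that("DeLong variance and CI agree with the established reference", {
  skip_if_not_installed("pROC")
  set.seed(21)
  scores <- rnorm(60)
  labels <- rbinom(60, 1, plogis(scores))
  labels[1:2] <- c(0, 1)
  r <- roc_auc(scores, labels)
  pr <- pROC::roc(labels, scores, direction = "<", quiet = TRUE)
  expect_equal(r$auc, as.numeric(pROC::auc(pr)), tolerance = 1e-12)
  expect_equal(r$delong_variance, pROC::var(pr, method = "delong"),
               tolerance = 1e-10)
  # paired test
  scores_b <- scores + rnorm(60, sd = 1.2)
  t_ours <- delong_paired_test(scores, scores_b, labels)
  t_ref <- pROC::roc.test(pr, pROC::roc(labels, scores_b, direction = "<",
                                        quiet = TRUE),
                          method = "delong", paired = TRUE)
  expect_equal(t_ours$p_value, as.numeric(t_ref$p.value), tolerance = 1e-8)
})

test_that("paired test returns exact ties for equal or rank-equivalent scores", {
  set.seed(5)
  s <- rnorm(20)
  l <- c(0, 1, rbinom(18, 1, 0.5))
  same <- delong_paired_test(s, s, l)
  expect_equal(same$auc_diff, 0)
  expect_equal(same$p_value, 1)
  mono <- delong_paired_test(s, 3 * atan(s) - 2, l)
  expect_equal(mono$auc_diff, 0)
  expect_equal(mono$p_value, 1)
  expect_error(delong_paired_test(s, s[-1], l), "length")
})

test_that("DeLong variance of an AUC difference matches a case bootstrap at small n", {
  # 12 cases, two informative score vectors sharing signal
  labels <- c(1, 1, 1, 1, 1, 0, 0, 0, 0, 0, 0, 0)
  scores_a <- c(2.1, 1.4, 0.9, 1.8, 0.2, -0.4, 0.3, -1.1, -0.2, -1.6, 0.6, -0.9)
  scores_b <- c(1.6, 0.8, 1.2, 0.1, 0.7, -0.9, 0.5, -0.6, -1.3, -0.8, 1.0, -0.3)
  v_delong <- delong_paired_test(scores_a, scores_b, labels)$variance
  v_boot <- bootstrap_var_auc_diff(scores_a, scores_b, labels, reps = 10000)
  expect_lt(abs(v_delong - v_boot) / v_boot, 0.15)
})

test_that("DeLong variance shrinks with sample size at fixed prevalence", {
  vars <- sapply(c(50, 500, 5000), function(n) {
    set.seed(n)
    s <- rnorm(n)
    l <- rbinom(n, 1, plogis(s))
    l[1:2] <- c(0, 1)
    roc_auc(s, l)$delong_variance
  })
  expect_true(all(diff(vars) < 0))
})

test_that("operating point maximises Youden's J, ties broken to specificity", {
  # perfect separation
  op <- operating_point(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_equal(op$sensitivity, 1)
  expect_equal(op$specificity, 1)
  # uninformative scores: documented degenerate corner (sens 0, spec 1)
  op0 <- operating_point(rep(0.3, 6), c(1, 0, 1, 0, 1, 0))
  expect_equal(c(op0$sensitivity, op0$specificity), c(0, 1))
  # matches an exhaustive threshold scan on a 20-point fixture
  set.seed(14)
  s <- round(runif(20), 2)
  l <- rbinom(20, 1, s)
  l[1:2] <- c(0, 1)
  op2 <- operating_point(s, l)
  grid <- sort(unique(c(s, Inf)))
  j <- vapply(grid, function(t) {
    mean(s[l == 1] >= t) + mean(s[l == 0] < t) - 1
  }, 0)
  expect_equal(op2$sensitivity + op2$specificity - 1, max(j), tolerance = 1e-12)
  # fixed probability rule
  op3 <- operating_point(s, l, rule = "prob0.5")
  expect_equal(op3$threshold, 0.5)
  expect_equal(op3$sensitivity, mean(s[l == 1] >= 0.5))
})
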