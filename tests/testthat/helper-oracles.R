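# Independent oracles, deliberately naive: each re-derives a quantity by
# brute force / enumeration, independently of the package code paths.

# AUC by exhaustive pair counting (concordant + half ties)
auc_bruteforce <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (x in pos) for (y in neg)
    total <- total + (x > y) + 0.5 * (x == y)
  total / (length(pos) * length(neg))
}

# two-sided exact permutation p-value for the rank-sum statistic
ranksum_permutation_p <- function(x1, x0) {
  all_v <- c(x1, x0)
  n1 <- length(x1)
  r <- rank(all_v)
  w_obs <- sum(r[seq_len(n1)])
  combos <- utils::combn(length(all_v), n1)
  w_all <- apply(combos, 2, function(ix) sum(r[ix]))
  mu <- mean(w_all)
  mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-9)
}

# stratified case-resampling bootstrap variance of an AUC difference
bootstrap_var_auc_diff <- function(scores_a, scores_b, labels, reps = 10000,
                                   seed = 99) {
  set.seed(seed)
  ip <- which(labels == 1)
  ineg <- which(labels == 0)
  d <- replicate(reps, {
    ix <- c(sample(ip, replace = TRUE), sample(ineg, replace = TRUE))
    auc_bruteforce(scores_a[ix], labels[ix]) -
      auc_bruteforce(scores_b[ix], labels[ix])
  })
  stats::var(d)
}

# direct Bernoulli log-likelihood maximiser (independent of IRLS)
logit_mle_optim <- function(X, y) {
  nll <- function(b) {
    eta <- drop(X %*% b)
    -sum(y * eta - log(1 + exp(eta)))
  }
  stats::optim(rep(0, ncol(X)), nll, method = "BFGS",
               control = list(maxit = 1000, reltol = 1e-14))$par
}

# small deterministic cohort pair for search/attribution tests
make_cohorts <- function(seed = 11, n_dev_per_cell = 5, n_val = 150) {
  cfg <- generator_config()
  vcfg <- cfg
  vcfg$design <- "boundary_adjacent"
  list(dev = generate_cohort(cfg, n_per_cell = n_dev_per_cell, seed = seed),
       val = generate_cohort(vcfg, n_total = n_val, seed = seed + 1000))
}
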