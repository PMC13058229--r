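# bipolaRF

Predictive modelling of bipolar radiofrequency (RF) ablation outcomes.

Bipolar ablation delivers RF current between two catheter tips placed on
opposite sides of the myocardium. It can create deeper lesions than
conventional unipolar delivery — attractive for thick-walled ventricular
substrate — but carries a higher risk of *steam pops*, intramural vapour
explosions that tear tissue. Planning a delivery therefore means trading off
the efficacy endpoint (a *transmural* lesion, spanning the full wall between
the catheters) against the safety endpoint (avoiding a pop), as a function of
the controllable settings (power in W, duration in s) and the measurable
tissue state (wall thickness in mm, baseline bipolar impedance in Ω, and the
impedance drop over the first 5 s of delivery, in Ω or as a percentage).

`bipolaRF` implements that analysis as a tested pipeline:

* **`generate_cohort()` / `generator_config()`** — a seeded synthetic-cohort
  generator emulating an ex vivo bench experiment (10/15/20 mm porcine
  ventricular slabs, 20–50 W, 20–180 s), with latent logistic mechanisms for
  both outcomes and pop-truncated delivery times.
* **`rf_glm()` / `fit_logistic()`** — binomial logit-link GLMs fitted by
  IRLS maximum likelihood, with honest convergence flags, separation
  detection, aliased-column handling and an optional ridge fallback. The
  linear predictor is `logit P(y = 1) = β₀ + Σ βⱼ xⱼ`.
* **`roc_auc()`, `delong_paired_test()`, `operating_point()`** — AUC by the
  midrank Mann–Whitney statistic with DeLong variance, 95% CIs, the paired
  DeLong test for correlated AUCs, and Youden-index operating points.
* **`enumerate_predictor_subsets()` / `evaluate_all()`** — exhaustive best
  subset search: all 2⁶ − 1 = 63 candidate models over the six predictors
  {power, initial impedance, duration, ImpDrop5, PercentImpDrop5,
  thickness}, fitted on a development cohort and ranked by validation AUC.
* **`attribute_auc()`** — Shapley-value attribution of validation AUC to
  predictors: φᵢ = Σ_S w(S) [AUC(S ∪ {i}) − AUC(S)] with the Shapley kernel
  w(S) = |S|!(p−|S|−1)!/p! and AUC(∅) ≡ 0.5 (uniform weighting available).
* **`boundary_model()`, `z_statistic()`, `boundary_power()`** — the
  two-predictor steam-pop risk boundary in the thickness × power plane:
  Z = 0.0743·(1 + e^L) with L = −4.9498 + 1.0729·thickness − 0.0903·power;
  the isopleth Z = 1 is the contour of pop probability 1 − 0.0743 = 92.6%.
* **`predict_depth()`, `required_duration()`** — inversion of a fitted
  transmurality model: the achievable lesion depth for a power–duration
  pair (the thickness at which transmurality probability crosses a target
  level, default 0.5, with impedance tied to thickness by
  86.213122 + 0.5057449·thickness), and the duration needed for a target
  thickness.
* **`summarize_outcomes()`, `compare_groups()`, `export_tables()`,
  `run_rf_analysis()`** — cohort summaries, rank-sum group comparisons, and
  CSV/JSON export of the full model-ranking, forest-plot and attribution
  tables; `run_rf_analysis()` runs the whole pipeline from one seed.

## Worked example

```r
library(bipolaRF)
res <- run_rf_analysis(seed = 42, n_dev_per_cell = 6, n_val = 120)
print(res$summary_dev)
#> n = 216 applications: transmural 101 (47%), steam pop 12 (5.6%)
#>
#> by steam-pop status (median [q1-q3], rank-sum p):
#>         variable median_g1   q1_g1  q3_g1 median_g0  q1_g0  q3_g0   p_value
#> 1       rf_power    50.000  47.500 50.000    30.000 20.000 40.000 7.080e-05
#> 2 init_impedance    91.510  89.320 92.640    94.070 91.480 96.230 3.113e-02
#> 3      thickness     9.927   9.222 14.370    15.070 10.540 19.630 1.866e-03
#> 4      imp_drop5   -10.300 -12.020 -8.273    -5.928 -7.618 -4.457 5.082e-05
#> 5  pct_imp_drop5   -11.540 -12.410 -9.027    -6.227 -8.027 -4.675 2.463e-05
```

Steam pops concentrate at high power, in thin tissue, with low baseline
impedance and large early impedance drops — and the exhaustive search finds
the early-drop metrics carry most of the validation discrimination:

```r
print(res$attribution_pop)
#> Validation-AUC attribution (shapley weighting), full-model AUC 0.791
#>        predictor contribution
#> 1      imp_drop5       0.1380
#> 2  pct_imp_drop5       0.1337
#> 3       rf_power       0.1042
#> 4    rf_duration      -0.0011
#> 5      thickness      -0.0290
#> 6 init_impedance      -0.0549
```

The risk boundary and the depth inversion give planning numbers directly:

```r
bm <- boundary_model()
boundary_power(10, bm)                                   # 36.07 W
z_statistic(10, 30, bm)                                  # 1.675 (inside the risk zone)
predict_depth(res$transmural_model, inversion_query(50, 180))  # 18.27 mm
```

At 10 mm wall thickness the Z = 1 boundary sits at ≈ 36 W: a 30 W delivery
is already inside the high-risk zone (Z ≈ 1.68), and even a 50 W, 180 s
application is predicted to achieve < 20 mm of lesion depth.

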