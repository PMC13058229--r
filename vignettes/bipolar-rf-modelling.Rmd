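---
title: "Modelling transmurality and steam-pop risk in bipolar RF ablation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling transmurality and steam-pop risk in bipolar RF ablation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bipolaRF)
```

## The problem

Bipolar radiofrequency ablation passes current between two catheter tips on
opposite sides of the myocardial wall. For thick ventricular substrate it
can achieve transmural lesions that unipolar delivery cannot, but it also
raises the risk of steam pops — intramural vapour explosions that disrupt
tissue and force the operator to abort the delivery. This package models
both binary endpoints from per-application records: the power setting (W),
the planned duration (s), the wall thickness (mm), the baseline bipolar
impedance (Ω), and the impedance drop over the first five seconds of
delivery, as an absolute change (Ω) and as a percentage of baseline. All
impedance drops are stored signed: a drop is negative, and
`pct_imp_drop5 = imp_drop5 * 100 / init_impedance` exactly.

Every stage is driven by a synthetic-cohort generator, so the full pipeline
is testable end-to-end without access to bench data.

## The models

Both endpoints are modelled with binomial GLMs with a logit link,

$$\operatorname{logit} P(y = 1 \mid x) = \beta_0 + \sum_j \beta_j x_j,$$

fitted by maximum likelihood (iteratively reweighted least squares).
Candidate predictors are the six variables above. Rather than selecting one
model, `evaluate_all()` fits **every** non-empty predictor subset — $2^6 -
1 = 63$ models per endpoint — on a development cohort and ranks them by
discrimination on an independent validation cohort, measured as the area
under the ROC curve with its DeLong 95% confidence interval. Two fitted
models on the same validation cases are compared with the paired DeLong
test, which accounts for the correlation of the two AUCs through the
covariance of their structural components.

Each predictor's importance is quantified by Shapley-value attribution of
validation AUC: predictor $i$ earns the weighted mean of its marginal gains
$\mathrm{AUC}(S \cup \{i\}) - \mathrm{AUC}(S)$ over all subsets $S$ of the
other predictors, with $\mathrm{AUC}(\varnothing) \equiv 0.5$. The default
weighting is the Shapley kernel $|S|!\,(p-|S|-1)!/p!$, under which the
contributions sum exactly to $\mathrm{AUC}(\text{full}) - 0.5$ (efficiency)
and symmetric predictors earn equal shares. A plain uniform average over
the $2^{p-1}$ subsets is also provided; it is sometimes quoted in applied
work, but it does not satisfy efficiency in general, which is why the
kernel weighting is the default and both modes report their weighting
explicitly.

## The risk boundary

Thickness and power are the two variables an operator can actually choose,
so steam-pop risk is summarised in that plane by a two-predictor logistic
model of record,

$$L = -4.9498 + 1.0729\,t - 0.0903\,E, \qquad Z = 0.0743\,(1 + e^{L}).$$

Because $1 + e^L = 1/(1-p)$ for $p = \sigma(L)$, the statistic is $Z =
0.0743/(1-p)$: strictly increasing in the pop probability, with floor
$0.0743$ and the isopleth $Z = 1$ coinciding pointwise with the
fixed-probability contour $p = 1 - 0.0743 = 0.9257$ (92.6%). The printed
form of this statistic is typographically ambiguous in its source; the
parse adopted here is the unique one under which $Z = 1$ corresponds to the
stated 92.6% probability. `boundary_power()` solves $Z = z$ for power in
closed form, and the boundary is affine in thickness.

One caveat is documented rather than corrected: the positive thickness
coefficient implies *higher* pop risk in thicker tissue, which runs against
the univariate observation (and this package's own generator) that pops
cluster in thin tissue. The constants are kept as published;
`boundary_model(flip_thickness_sign = TRUE)` allows sign-flipped
exploration, and nothing is silently altered.

## Depth inversion

A fitted transmurality model over
$\{E, Z_0, d, t\}$ (power, baseline impedance, duration, thickness) is
rearranged to answer planning questions. "Achievable lesion depth" is
operationalised as the thickness $t^\*$ at which the transmurality
probability crosses a target level — default 0.5, configurable (e.g. 0.9
for a conservative planner) because the choice of level is a modelling
convention, not an estimate. Baseline impedance is tied to thickness by the
linear relation $Z_0 = 86.213122 + 0.5057449\,t$, which makes the logit
affine in $t$; the root is bracketed and located by bisection to $10^{-6}$
mm, then polished with one Newton step (exact for an affine logit). The
dual query — the duration required for a target thickness — has a closed
form; solutions outside the bench-tested 20–180 s range are flagged as
extrapolation, and negative solutions are reported as "already exceeded at
0 s". The inversion demands a negative effective thickness gradient
$\beta_t + 0.5057449\,\beta_{Z_0}$; a model violating it has no meaningful
depth and is rejected.

## The synthetic cohorts

`generator_config()` encodes the bench design: a full factorial grid of
nominal thickness $\{10, 15, 20\}$ mm (Gaussian jitter, SD 0.8 mm), power
$\{20, 30, 40, 50\}$ W and planned duration $\{20, 60, 180\}$ s. Baseline
impedance follows the linear thickness relation above with 3 Ω of Gaussian
noise. The 5-s drop is linear in power and baseline impedance (drops deepen
with power, lighten slightly with baseline impedance) with 2.3 Ω noise.
Steam pops are Bernoulli in a logit linear in power, percentage drop and
thickness; a pop truncates the delivery at a uniform time between 5 s and
the planned end, and transmurality is then Bernoulli in a logit linear in
power, *actual* delivered duration, baseline impedance and thickness.

The default coefficients were calibrated once against the study conditions
the pipeline is meant to emulate — a marginal transmural rate near 49%, a
pop rate near 5.7%, and conditional 5-s-drop medians near −9.4 Ω / −10% in
pop applications versus −5.8 Ω / −6.4% without — and then frozen; they live
in the config object, not in code. The pop-truncation time model is a
modelling convention (only the fact of early termination is observable),
and is configurable.

The `boundary_adjacent` design emulates a validation experiment: thickness
uniform on 8–12 mm, power set to the Z = 1 boundary power for that
thickness plus a uniform ±5 W perturbation (clipped to 20–50 W), duration
fixed at 60 s. Because validation duration is fixed, a duration-only model
is constant there; by convention such constant-score models are reported
with AUC exactly 0.500 and the degenerate CI 0.500–0.500 rather than NaN,
and flagged as excluded.

One deliberate deviation from an obvious alternative: the `rf_duration`
predictor column aliases the **planned** duration, not the pop-truncated
actual one. The actual duration is partly determined by the outcome (pops
stop the clock), so using it as a pop predictor would leak the outcome into
the score; the planned setting is what an operator knows in advance. The
actual duration is retained in `rf_duration_actual` and drives the
transmurality mechanism inside the generator.

What the generator does *not* emulate: thermodynamics (no bioheat model —
outcomes are statistical, not physical), catheter geometry, irrigation or
contact-force variation, inter-slab biological heterogeneity, and any
within-application impedance trajectory beyond the single 5-s summary.
Passing tests therefore demonstrate the *statistical machinery* is correct
and well-calibrated to the stated marginal behaviour; they do not validate
the biophysics of any particular generator or catheter pairing.

## Numerical choices

* IRLS converges on relative log-likelihood change $< 10^{-8}$, at most 100
  iterations; both configurable. The `converged` flag is honest — a
  separated fit is returned with `converged = FALSE` and a warning, or
  refitted with a small ridge (`ridge = 1e-6`) on request, never silently.
* Exactly aliased columns (duplicates, constants) are dropped before
  fitting, as `stats::glm` does, so adding a collinear column leaves fitted
  scores exactly unchanged — this keeps the Shapley dummy and symmetry
  axioms exact rather than approximate.
* AUC uses midranks (ties count ½); DeLong CIs are normal-approximation,
  clipped to [0, 1]; a zero-variance AUC difference is reported as an exact
  tie (p = 1). No multiplicity correction is applied across the 63 models —
  a deliberate mirror of exhaustive-search practice, and a documented
  caveat for interpreting the smallest p-values.
* Operating points use Youden's J by default, ties broken toward higher
  specificity (so uninformative scores give sensitivity 0, specificity 1);
  a fixed 0.5 probability cut is available. Train-set CIs use the same
  DeLong machinery as validation CIs.
* Group comparisons use the Wilcoxon rank-sum test (exact below 10 per
  group without ties, normal approximation with tie correction otherwise)
  with type-7 quantiles; the reported rates round half-up at configurable
  precision (integer transmural, one-decimal pop by default).

## Problem sizes

The test suite and examples run the generator at modest sizes chosen to
make stochastic checks stable: 36-cell grids at 5–15 applications per cell
for pipeline tests, 500 per cell for calibration contracts, a single
50,000-row cohort for parameter recovery (each generating coefficient
recovered within ±3 estimated SEs), and validation cohorts of 150–2,000 for
attribution checks, where a pure-noise predictor must earn |φ| < 0.02.

## Known limitations

* The attribution is exact-enumeration only (p ≤ 12); no sampling
  approximation is provided, none being needed at p = 6.
* The boundary constants are treated as constants of record: the package
  does not refit them, and their thickness-sign tension with the univariate
  pop pattern is surfaced, not resolved.
* Depth inversion reproduces a *procedure*, not published numbers — the
  underlying model coefficients differ with every fitted cohort.
* Validation AUCs computed on boundary-adjacent designs are estimated on a
  deliberately narrow covariate range; they are not comparable to AUCs on a
  factorial design, which is exactly why development and validation cohorts
  are kept distinct.
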