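---
title: "Survival modelling with informative missingness: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Survival modelling with informative missingness: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Electronic health records offer large cohorts for prognostic modelling, but
their covariates are recorded only when clinical practice called for a
measurement. Missingness is therefore both extensive — a heart-rate-like
variable can be absent for over 90% of patients — and *informative*: the
fact that a lipid panel was never ordered, or that creatinine was monitored,
itself carries prognosis (missing not at random, MNAR). Conventional
survival analysis handles this by multiple imputation, which assumes data
are missing at random and, as usually practised, imputes across the
train/test boundary. This package implements and compares the alternative
strategies that treat absence as data:

* **Missingness-indicator Cox regression** — a missing continuous value is
  zero-filled (so it contributes nothing through its own coefficient) and a
  companion 0/1 indicator column carries an independent coefficient
  `beta_missing`. A patient with the value missing contributes exactly
  `beta_missing` to the linear predictor.
* **Quantile-discretised Cox regression** — every continuous variable is
  split into `n` bins assigned in quantiles (10 by default, so deciles) with
  a dedicated extra category for missing cells, giving `n + 1` coefficients
  per variable counting the implicit baseline. Discretisation also lets the
  model express non-monotone risk shapes a linear term cannot.
* **Chained-equations multiple imputation** followed by a conventional Cox
  fit, as the traditional comparator.
* **Random survival forests** with logrank-optimal splits and *adaptive tree
  imputation*: a missing value is routed at random down a branch with
  probability equal to the ratio of non-missing cases sent to each branch.
* **Elastic-net-penalised Cox regression** over the one-hot discretised
  design, which performs variable selection implicitly.

Models are compared by Harrell's concordance index (discrimination) and a
calibration-area score at a five-year horizon, with bootstrap confidence
intervals computed on shared replicates so paired differences are
meaningful.

## The synthetic study cohort

The real cohorts that motivate this design are access-restricted, so the
package ships a generator (`synthetic_spec()`, `generate_cohort()`) whose
default configuration (`caliber_like_spec()`) emulates their published
statistical structure rather than any patient data:

* **Outcome.** Event times are drawn by inverse-transform sampling from a
  Weibull baseline hazard multiplied by `exp(lp)`, where the linear
  predictor sums the declared covariate effects. The default shape 1.2,
  scale 55 years, 10-year administrative horizon and exponential dropout of
  0.03/year were calibrated once so that roughly 23% of patients die within
  follow-up, matching the published cohort summary this generator emulates.
* **Covariates.** A dominant age effect (log-HR 0.75 per SD), sex,
  smoking (categorical, 8% missing), diabetes, and six biomarkers with
  62–92% missingness. Creatinine has a U-shaped effect, parameterised as a
  quadratic in the standardised value — the simplest shape that reproduces
  the published non-monotone creatinine–mortality curve.
* **Informative missingness.** Each patient's *frailty* is their true
  standardised log-hazard, making "missingness carries prognosis" literal
  and controllable. MNAR masking follows a logistic model on the frailty
  with the intercept solved by bisection (to 1e-6) so the marginal missing
  fraction hits its target exactly; published missingness rates are
  marginal rates, which is why the calibration targets the margin.
  Missing cholesterol and HDL mark *higher* risk (sign +), missing
  creatinine marks *lower* risk (sign −), reproducing the published
  two-directional pattern.
* **Extended variables.** 200 zero-effect binary variables emulate the
  coded-diagnosis indicators of a data-driven variable set. Their
  independence is a modelling choice: the joint distribution of real coded
  variables is not characterised in the source material, so no claim is
  made about it.
* **Determinism.** One integer master seed; every stochastic stage derives
  a child seed from it (`child_seed()`), so identical spec + seed gives
  byte-identical cohorts and each stage is independently reproducible.

What passing tests on this cohort do **not** show: real EHR variables are
correlated, repeat over time, and their missingness mechanisms are not
logistic in a scalar frailty. Results here validate the *machinery* and the
qualitative orderings, not clinical performance.

## Model implementations and numerical choices

**Cox fitting** (`fit_cox()`) maximises the log partial likelihood by
damped Newton iterations (step-halving on any likelihood decrease, maximum
100 iterations), with Efron tie handling by default — standard for heavily
tied EHR follow-up times — and Breslow as an option. Convergence is declared
when the score's max-norm falls below 1e-8 (absolute, with a relative guard
for large cohorts). Standard errors come from the inverse observed
information. Exactly collinear columns are an *error*, reported by name:
silent dropping would let encoding bugs through. The derivative kernel is
compiled C++ (one pass over time-sorted data, Efron correction per tied
group).

**Baseline hazard and risk.** `breslow_baseline()` accumulates
`d_k / sum(exp(lp))` over the risk sets; with all coefficients zero it
reduces exactly to the Nelson–Aalen estimator, which is also the test
anchor. Absolute risk at a horizon is `1 - exp(-Lambda0(t) * exp(lp))`;
horizons beyond follow-up clamp with a warning.

**Encodings** (`fit_encoder()`/`encode()`) are fitted on the training split
only — standardisation statistics, quantile edges and the set of
missingness-indicator columns all come from training data, preventing the
train/test leakage that whole-dataset imputation invites. Indicator columns
are emitted only for variables with at least one missing training value, so
no zero-variance columns arise. Values outside the fitted range clamp to
the extreme bins; unseen categorical labels map to the missing category
with a warning (EHR vocabularies drift). Bin membership uses half-open
intervals `[e_k, e_{k+1})` with the last bin closed, so a held-out value
equal to an interior edge goes right.

**Chained imputation** (`chained_imputation()`) cycles per-variable
conditional models from a random-draw initialisation: linear regression on
the log scale for positive continuous variables (exponentiated back),
logistic for binary, multinomial for categorical; 10 cycles by default
(common chained-equations practice), five completions. Predictors are the
expert-set covariates plus the Nelson–Aalen cumulative hazard at the
patient's follow-up time and the event flag. Draws include parameter noise
(normal approximation around the fitted coefficients; scaled
inverse-chi-square residual variance for linear models) and residual noise,
so completions vary as proper imputations should. Unlike the whole-dataset
imputation the comparison literature itself flags as a leakage risk, the
fitted conditional models are stored and *applied* to held-out data
(`apply_imputation()`) without refitting. Sex-stratified imputation is not
built in: synthetic cohorts need not have a sex variable, and stratification
can be expressed by splitting the cohort. How multiple completions should be
pooled for prediction is not settled; the experiment driver evaluates per
completion and averages the predicted risks, reporting that mean.

**Random survival forest** (`fit_forest()`). Each tree sees a bootstrap
sample; at each node `mtry` variables are drawn (default `floor(sqrt(p))`),
and for each continuous candidate `nsplit` thresholds (default 10) are
drawn uniformly *from the node's observed values* — which caps the split
search (and its cost) and makes chosen partitions invariant under monotone
transforms. Categorical candidates are random binary label partitions,
likewise capped at `nsplit`. The candidate with the largest two-group
logrank statistic wins; ties break to the first-drawn candidate for
determinism. Missing values take no part in split scoring; once a split is
chosen they are routed by adaptive tree imputation — at random, weighted by
the non-missing branch ratio — with the draw refreshed over
`n_impute_iterations` passes (routing only; no values are fabricated).
Recursion stops at `min_node_size` members (default 15), zero remaining
events, or no admissible split; leaves store their members' Nelson–Aalen
cumulative hazard. The ensemble cumulative hazard is the mean over trees and
risk is `1 - exp(-CHF(t))`. Tree seeds derive from the forest seed, so the
result is independent of growth order. A C-index-optimising split rule is
deliberately not implemented; the comparison literature found it too
expensive for negligible benefit. Defaults (500 trees, `nsplit` 10,
`min_node_size` 15) are config-exposed, since the source analysis
cross-validated these without printing the chosen values.

**Elastic-net Cox** (`fit_path()`). The objective is
`-(1/n) * loglik + lambda * (alpha * ||b||_1 + (1 - alpha)/2 * ||b||^2)`,
with the absolute-value term weighted by `alpha` — so `alpha = 1` is the
pure lasso and the analysis default `alpha = 0.9` is lasso-dominant,
consistent with the sparse solutions the method is used for. (Published
prose that reverses the mapping is treated as an erratum; the equation
governs.) The loss is the negative Breslow log partial likelihood: the
printed squared-error form cannot produce a Cox model, and the fitted
object plainly is one. The design must be 0/1 (one-hot discretised), in
which setting no normalisation is needed. `lambda_max` is computed from the
null-model gradient as the smallest lambda with an all-zero solution (the
path's first point is that null solution by definition); 100 log-spaced
values run down to `lambda_max * 1e-3`. Each solution is found by proximal
Newton on a working set: the exact observed information over the active and
near-active columns forms the quadratic subproblem, solved by cyclical
coordinate descent with soft-thresholding (compiled), while the full-design
gradient drives a Karush–Kuhn–Tucker check so no violation above 1e-6
escapes. Warm starts run along the path; ten-fold cross-validation selects
lambda by held-out partial-likelihood deviance (fold refits use a looser
stop, since only deviance accuracy is needed there); `grid_alpha()` wraps
the alpha grid search. Per-column penalty factors are uniform.

**Evaluation.** `c_index()` uses Harrell's conventions — a pair is
comparable when the shorter follow-up ends in an event; time-tied
double-event pairs are excluded; risk ties score 1/2 — computed by an
O(n log n) Fenwick-tree sweep that the tests hold to *exact* equality with
O(n^2) pair enumeration. `calibration_score()` regresses observed 5-year
status on predicted risk with a local-linear smoother (`lowess`, window
fraction 0.3, no robustness iterations — the smoother and bandwidth are
config-exposed since the source only specifies "locally smoothed");
patients censored before the horizon are excluded; the area `a` between the
smoothed curve and the identity is integrated by the trapezoid rule over
the *observed* risk range (a model provides no evidence outside it), and
the score `1 - a` is reported clipped to [0.5, 1] with the raw value kept.
Degenerate constant predictions get a horizontal curve at the observed
rate. Bootstrap intervals (percentile, B = 200 by default — enough for
stable 95% intervals on these fixtures) resample test rows; paired
comparisons share replicate indices across models, which is what makes the
quoted difference intervals meaningful. The age-only baseline stratifies
training patients by integer age (strata under 10 patients pool with their
neighbour) and scores test patients by `1 - KM_stratum(horizon)`.

**Variable selection.** Three univariate rankings: completeness; the
within-variable logrank statistic (binary as two groups, categories as k
groups, continuous as quartiles of the non-missing values — with the
missing cells as an extra group whenever at least 1% are missing, since
absence demonstrably carries effect); and permutation importance (mean
C-index drop over shuffles, model-agnostic by construction). Statistics
with different degrees of freedom are compared on the raw chi-square scale
by default — how the source pooled them is unstated — with the caveat that
a p-value scale is the natural alternative. `select_count()` then fits
models to decreasing numbers of top-ranked variables, 3-fold
cross-validates the C-index, keeps the best count, and refits on the full
training set.

**Effects.** `cox_effect()` returns `beta * z` lines with bands
`± 1.96 * se * |z|` (zero width at the baseline `z = 0`) for continuous
terms, per-bin coefficients with the lowest bin as the zero-uncertainty
baseline for discretised terms, and the missing-value coefficient as a
separate point. `partial_dependence()` sweeps one variable over 50
equally-spaced quantiles of its observed support for 1000 randomly drawn
patients, normalises each patient's swept risk curve by its own mean, takes
logs, and reports the median curve (matching how such curves are usually
drawn); risk is normalised before the log — the reverse ordering is a
config switch, as the source's wording is ambiguous.

## The experiment driver

`run_experiment()` executes a (model × encoding × variable-set) grid from
one config: a single train/test split (default 2/3–1/3; the published
fractions are corrupted in the source text, and 2/3 is the conventional
reading) shared by every entry, selection and hyperparameter CV confined to
training data, evaluation on identical bootstrap replicates, per-entry
failures recorded without aborting the grid. A complete-case control entry
is included beyond the published grid so the MNAR comparisons have a
well-defined inferior comparator; since row-wise deletion over variables
that are 60–92% missing would leave essentially no rows, the control first
discards variables more than 50% missing and then deletes incomplete rows —
what a traditional analysis would actually do. At prediction time its
missing cells fall back to the training mean.

## Problem sizes

The shipped analyses and tests run at desk scale, chosen as the smallest
sizes at which each property is statistically clear: the default cohort is
10,000 patients with 200 extended variables (the published cohorts are
~10× larger); MNAR detection uses 20,000; forests use 500 trees where the
ensemble-level contracts are tested and 100–300 elsewhere; the elastic-net
selection study uses 50 replicates of a 205-column design. The acceptance
script reports the problem size alongside every quantity.

## Known limitations

* Imputation's multinomial draws take the fitted class probabilities
  without parameter noise, a mild understatement of imputation variance.
* The forest's admissibility check (both children at least `min_node_size`)
  is applied after missing-value routing; a borderline split can therefore
  collapse to a leaf that a different routing draw would have kept.
* `lowess` smoothing of a binary outcome can overshoot [0, 1]; values are
  clipped before integration.
* No time-varying covariates, stratified baselines, frailty terms,
  proportionality diagnostics, interaction partial dependence, or repeated
  measurements per patient.
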