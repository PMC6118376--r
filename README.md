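# survmiss

Survival modelling when missingness itself carries prognosis.

In electronic health records, covariates are measured only when clinical
practice called for them: biomarkers can be absent for 60–92% of patients,
and *which* patients lack a value is informative — patients with no lipid
panel tend to fare worse, patients with no creatinine measurement tend to
fare better. `survmiss` implements, end to end, the modelling strategies
that treat absence as data and the machinery to compare them fairly on one
cohort:

* **Cox proportional hazards** `lambda(t) = lambda0(t) * exp(beta' x)`,
  fitted by damped Newton–Raphson on the Efron/Breslow partial likelihood,
  with three missingness-aware encodings:
  * *missingness indicators*: a missing value `x1` is set to 0 and a paired
    dummy `x_missing` carries its own coefficient, so the linear predictor
    is `beta1 * x1 + beta_missing * x_missing`;
  * *quantile discretisation*: each continuous variable becomes
    `n` equal-occupancy bins plus a dedicated missing category
    (`n + 1` coefficients counting the baseline bin);
  * *chained-equations multiple imputation* (the conventional comparator),
    with the fitted conditional models applied — not refitted — to held-out
    data.
* **Random survival forests** with logrank-optimal splits, `nsplit`-capped
  candidate thresholds, adaptive tree imputation (missing values routed at
  random by the non-missing branch ratio) and Nelson–Aalen leaf hazards.
* **Elastic-net penalised Cox regression** over the one-hot discretised
  design: objective `-(1/n) loglik + lambda (alpha ||b||_1 +
  (1-alpha)/2 ||b||_2^2)`, proximal-Newton coordinate descent with exact
  KKT verification, ten-fold cross-validated `lambda`, grid-searched
  `alpha`.
* **Evaluation**: Harrell's C-index (O(n log n), provably identical to pair
  enumeration), a calibration-area score `1 - a` at a 5-year horizon,
  percentile bootstrap intervals on shared replicates, paired model
  differences, and an age-stratified Kaplan–Meier baseline as the floor.
* **Variable selection**: completeness, within-variable logrank and
  permutation-importance rankings with cross-validated count selection.
* A seeded **synthetic cohort generator** with known ground truth —
  Weibull baseline, nonlinear (U-shaped) biomarker effects, and calibrated
  MCAR/MNAR missingness driven by the patient's latent frailty — so every
  claim above is testable without access-restricted patient data.

## Worked example

The scripted analysis lives under `analysis/` (run the stages in order;
outputs land under `results/`). Stage 1 generates the default cohort —
10,000 patients, 23% deaths over 10 years, biomarkers 62–92% missing, MNAR
in both directions, 200 zero-effect binary "extended" variables:

```
$ Rscript analysis/01_simulate_cohort.R
<cohort> 10000 patients, 210 variables (202 binary, 1 categorical, 7 continuous); 2292 events (22.9%)
event fraction: 0.229 (emulation target ~0.23)
    smoking  heart_rate  total_chol         hdl  creatinine         wbc  haemoglobin
      0.078       0.923       0.632       0.779       0.640       0.748        0.771
hdl: missing group fares worse (logrank 180.9)
creatinine: missing group fares better (logrank 380.2)
```

Stage 2 runs the model grid on one shared train/test split, scoring every
model on identical bootstrap replicates (C = Harrell's C-index on the
held-out third; cal = calibration score `1 - a` at 5 years):

```
$ Rscript analysis/02_fit_models.R
  cox-indicator            C=0.720 (0.702-0.736)  cal=0.949
  cox-discrete             C=0.732 (0.713-0.746)  cal=0.967
  cox-imputed              C=0.769 (0.753-0.782)  cal=0.872
  rsf                      C=0.723 (0.706-0.740)  cal=0.939
  coxnet                   C=0.733 (0.715-0.747)  cal=0.959
  complete-case            C=0.688 (0.669-0.709)  cal=0.981
  age-baseline             C=0.673 (0.653-0.690)  cal=0.978

paired bootstrap C-index differences vs the complete-case control:
               a             b median_diff   lower  upper
   cox-indicator complete-case      0.0313 0.01383 0.0463
    cox-discrete complete-case      0.0444 0.02675 0.0578
     cox-imputed complete-case      0.0800 0.06713 0.0936
             rsf complete-case      0.0342 0.02325 0.0456
          coxnet complete-case      0.0441 0.02812 0.0579
```

Under informative missingness every missingness-aware model beats the
traditional complete-case analysis by a paired ΔC whose 95% interval
excludes zero, and the age-only baseline is the floor. Stage 3 extracts
variable effects — the discretised Cox model exposes the U-shaped
creatinine–hazard relationship a linear term cannot (first bin +0.00,
middle −0.45, last +1.61 on the log-risk scale) and recovers the
missing-value risks with the generator's signs (`beta_missing` = +0.32 for
HDL, −0.32 for creatinine). Stage 4 ranks the extended variable set by
within-variable logrank tests (the five real risk factors head the list of
205) and cross-validates how many top-ranked variables to keep.

The methods vignette (`vignettes/survmiss-methods.Rmd`) documents the
models, the generator's assumptions, every numerical choice and the known
limitations.

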