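---
title: "Methods: voxel-based brain age, bias correction, and the BAG association suite"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: voxel-based brain age, bias correction, and the BAG association suite}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`braingap` implements a complete brain-age-gap (BAG) analysis: a voxel-wise
elastic-net model of chronological age trained on gray-matter (GM)
probability maps, transfer of that model to a target cohort, linear age-bias
correction, and the downstream epidemiological association suite (mortality,
cognitive status, phenotypes, proteomics). Because real multi-site MRI,
mortality, and aptamer proteomics data cannot ship with a package, a
synthetic-cohort generator with full ground truth is a first-class module:
every statistical claim the test suite makes is a parameter-recovery or
calibration statement about data whose generating mechanism is known.

## The brain age model

Each subject contributes a registered GM probability volume on a common
template grid. Voxels inside a brain mask (template value > 0.1 by default;
the threshold is stored in the model metadata) are unrolled into a row of the
design matrix $X$ (`vectorize()`), using R's native column-major ascending
linear index — the order is fixed and recorded so serialized weight maps
remain portable. With chronological age $y$ as outcome, the model solves

$$
\hat\beta = \arg\min_\beta \frac{1}{2n}\lVert y - \beta_0 - X\beta\rVert^2
 + \lambda\Big(\alpha\lVert\beta\rVert_1 +
   \tfrac{1-\alpha}{2}\lVert\beta\rVert_2^2\Big),
$$

with the mixing parameter fixed at $\alpha = 0.5$. The fit is delegated to
glmnet; because glmnet internally rescales a gaussian response by its
standard deviation (which silently changes the ridge/lasso balance of the
penalty above), `braingap` passes a translated pair
$\lambda_g = \lambda(\alpha + s(1-\alpha))$, $\alpha_g = \alpha/(\alpha +
s(1-\alpha))$, where $s$ is the $1/n$ standard deviation of $y$. This makes
the returned solution minimize exactly the objective printed above;
`enet_objective()` evaluates it and the model stores the maximal violation
of the stationarity conditions (checked against $10^{-5}$). An independent
coordinate-descent minimizer in the test suite confirms objective agreement
to $10^{-6}$ relative on random instances.

### Penalty selection

The penalty $\lambda$ is chosen by repeated cross-validation:

1. draw a random `n_folds`-fold partition (default 10);
2. compute the CV error curve over a grid of 100 log-spaced $\lambda$
   values from the data-driven $\lambda_{\max} = \max_j |x_j^\top
   \tilde y| / (n\alpha)$ down to $10^{-3}\lambda_{\max}$;
3. apply the one-standard-error rule (`select_lambda_1se()`): the largest
   $\lambda$ whose mean CV error is within one standard error of the
   minimum;
4. repeat steps 1–3 five times with fresh partitions (this is what the
   repeats average over: fold-assignment noise) and refit once on all
   subjects at the arithmetic mean of the five selected $\lambda$ values.
   A geometric-mean variant is available via `fit_config(lambda_average =
   "log")`.

Voxels are standardized to mean 0 / SD 1 before fitting (penalty fairness
across voxels; constant voxels are dropped and counted in the model object),
and coefficients are returned on the original GM-probability scale. The
intercept is never penalized. The refit is warm-started along the
$\lambda$ path so the solution at the averaged $\lambda$ is exact rather
than interpolated.

## Bias correction and the BAG

Raw predictions from any regularized age model are compressed toward the
training mean (regression dilution / regression to the mean): the young are
over-predicted, the old under-predicted, so the raw gap correlates
negatively with age. `fit_bias_correction()` regresses the uncorrected gap
$\hat y - y$ on age in the *training* cohort by OLS and
`apply_bias_correction()` subtracts the fitted trend:

$$
\mathrm{BAG} = (\hat y - y) - (\hat a\, y + \hat b), \qquad
\hat y_{\text{corr}} = y + \mathrm{BAG}.
$$

Two properties pin the implementation down. On training data the corrected
BAG is exactly orthogonal to age (OLS residual identity, asserted at
$10^{-8}$), and a deterministic shrinkage line $\hat y = 0.5y + 40$ is
corrected to BAG $\equiv 0$. Whether the correction line should be fitted
on training-cohort or target-cohort predictions is genuinely ambiguous in
the brain-age literature; the package fits on training predictions (the
target cohort then inherits a fixed, externally estimated correction) —
refitting within the target is possible by calling `fit_bias_correction()`
on target predictions, and the choice is recorded in the BAG-fit object.

Target subjects are ranked into BAG tertiles with closed outer intervals
($t_1 \le q_{1/3}$, $t_3 \ge q_{2/3}$): a value lying exactly on the lower
boundary belongs to the lowest tertile, one on the upper boundary to the
highest, matching the convention used when such boundaries are reported to
readers. The *highest* tertile (oldest-looking brains) is the survival
reference, so protective hazard ratios are expected below 1.

## Association suite

**Mortality.** `fit_cox()` fits a partial-likelihood Cox model on tertile
indicators plus covariates, Efron tie handling, Wald 95% intervals,
complete-case with the exclusion count recorded. The competing-risk variant
is a *cause-specific* hazard model: deaths from the competing cause are
censored at their event time, with event/competing tallies reported. The
cause-specific form (rather than a Fine–Gray subdistribution model) was
chosen because it reduces exactly to the plain model when no competing
events exist — a reduction the tests assert bit-for-bit — and because
reporting "competing events" alongside an otherwise unchanged model is how
the analysis it mirrors is tabulated. Relabelling the reference tertile
reproduces reciprocal hazard ratios to $10^{-8}$.

**Cognitive status.** `lsmeans_by_group()` fits `bag ~ group + covariates`
and reports least-squares means via emmeans: predictions at covariate
sample means with categorical covariates at observed proportions, plus
pairwise contrasts with unadjusted p-values. With no covariates LS means
equal raw group means exactly; a normal-equations oracle in the tests
checks the adjusted case at $10^{-10}$. The adjustment set for the
cognitive-status contrast is configurable and defaults to unadjusted.

**Phenotypes.** `phenotype_assoc()` fits one OLS model per phenotype with
BAG as outcome, adjusted by default for age, sex, and center-race.

**Proteomics.** `run_pwas()` regresses BAG on each analyte (plus the full
covariate set) one at a time. All analytes share the covariate projection,
so it is computed once and applied by Frisch–Waugh–Lovell residualization;
the tests verify numerical identity with per-analyte `lm()` fits. Analytes
are standardized per analyte before regression, so effects are in BAG-years
per SD of analyte; a log2 and a rank-based inverse-normal transform are
available (`transform=`), since aptamer platforms differ in the scale they
deliver and coefficient magnitudes — though not signs — depend on it.
Multiplicity control is Bonferroni at $\alpha/m$ and Benjamini–Hochberg
step-up at $\alpha$, with $m$ the number of analytes actually tested after
QC filtering and per-analyte skips. Bonferroni significance implies BH
significance on every input, and the BH flags are checked against an
independent step-up implementation.

## The synthetic cohort

`simulate_cohort()` generates everything downstream stages consume:

* **Template and signal.** A smooth ellipsoidal pseudo-brain in $[0,1]$
  (roughly 30–70% of voxels above 0.1) and `n_signal_clusters` spherical
  atrophy clusters with cosine-tapered negative per-year effects of peak
  size `effect_scale` (default 0.004 GM-probability units per year — about
  a 10% GM loss over 25 years at cluster centers, a plausible atrophy
  magnitude).
* **Volumes.** `volume = clip(template + W (age + BAG_true - age_ref) +
  noise, 0, 1)` with i.i.d. voxel Gaussian noise (SD 0.05) smoothed to
  FWHM 2 voxels for spatial autocorrelation. The per-subject
  `BAG_true ~ N(0, 3^2)` years shifts *effective* age, planting the ground
  truth the model should recover. Training ages are uniform on 55–95,
  target ages uniform on 67–90, so transfer interpolates; the target range
  mirrors an older community cohort. The BAG SD is a free parameter of the
  generator (real BAG dispersion is not identifiable from published
  summaries), set to 3 years to be consistent with published tertile
  cut-points a couple of years on either side of zero.
* **Phenotypes.** Covariates (sex, 5-level center-race, smoking, education,
  hypertension, diabetes, BMI, intracranial volume) are drawn independently
  of BAG with marginals near the cohort tables the simulator emulates;
  cognitive status comes from an ordinal-logit model on true BAG with
  thresholds placed to yield roughly a 63/32/5% CN/MCI/dementia mix;
  4-m walk time and disease/physical-function indicators increase in true
  BAG. Survival is exponential with tertile-of-true-BAG hazard ratios
  (defaults 0.4/0.6 vs the highest tertile, baseline hazard 0.035/year,
  about 19% mortality over follow-up), administratively censored at
  site-specific dates (2017-12-31 for the Jackson site, 2019-12-31
  elsewhere); death causes are CNS with probability 0.14. Because
  covariates carry no hazard effect, the covariate-conditional hazard
  ratios the Cox model estimates equal the generating ones — deliberate,
  since Cox non-collapsibility would otherwise make "truth" ambiguous in
  recovery tests.
* **Proteins.** Analyte $j$ is $\gamma_j \cdot \mathrm{BAG}_{true}$ plus
  small age/sex effects and unit Gaussian noise on an additive
  (log-analyte-like) scale, with $\gamma_j \ne 0$ for a designated subset;
  a fixed fraction of analytes (407/5284 by default) is flagged as failing
  QC, so a 5,284-analyte panel filters to 4,877.

What the generator does *not* emulate: scanner/site effects in the images,
registration or segmentation error, non-Gaussian or spatially structured
BAG heterogeneity, aptamer cross-reactivity, covariate-outcome confounding.
Passing recovery tests therefore demonstrates correctness of the estimation
machinery under the stated generating model, not robustness to the
artifacts real multi-site data add on top.

## Numerical choices and degenerate inputs

* glmnet convergence threshold $10^{-16}$ (with $10^6$ iteration cap) for
  the final refit, $10^{-10}$ within CV; the stationarity check stored on
  the model is the ultimate arbiter.
* Single-voxel designs are padded with a zero column (glmnet requires two)
  whose coefficient is discarded.
* Constant ages, degenerate age variance, empty masks, empty QC panels,
  rank-deficient LS-mean designs, misaligned subject IDs, and mismatched
  grids/affines (tolerance $10^{-4}$) are rejected with informative errors
  rather than propagated.
* Tertile boundary ties that empty a group raise an error naming the
  collision; `evaluate_predictions()` flags an undefined Pearson
  correlation (`pearson_defined = FALSE`) instead of inventing a value.
* Seeds: every stage derives its seed deterministically from the global
  config seed, so `run_full()` is byte-identical across reruns and stages
  can be reproduced in isolation.

## Problem sizes used in validation

The validation suite runs, among others: an end-to-end study at a
$32^3$ grid with 300 training and 500 target subjects (about 16,000 masked
voxels); solver-oracle comparisons on 25 random instances with $n \le 50$,
$p \le 20$; proteome-scan null calibration with 100 analytes, 300 subjects,
500 replicates; and survival recovery at $n = 5000$ (point estimates) plus
200 replicates at $n = 1000$ (interval coverage). These sizes were chosen
so each statistical tolerance is comfortably inside the Monte Carlo
precision the replicate counts afford while the whole suite stays
desk-scale. At the single-dataset size the tertile hazard-ratio band of
$\pm 0.06$ corresponds to roughly one standard error of the middle-tertile
estimate, which is why the suite pins that comparison to a fixed seed and
relies on the replicated coverage check for calibration.

## Known limitations

* The elastic-net model is linear and voxel-wise; nonlinear estimators
  (kernel methods, CNNs) are out of scope, as are sex-stratified models.
* The bias-correction variant (train-fitted, BAG-corrected) is one of
  several defensible choices; alternatives change BAG location/scale but
  not its rank ordering.
* Cause-specific competing-risk modelling answers an etiological question;
  cumulative-incidence (Fine–Gray) modelling would be needed for absolute
  risk prediction.
* The PWAS assumes analytes are exchangeable after per-analyte
  standardization; no normalization chemistry is modelled.
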