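---
title: "Methods: cross-platform assay calibration, concordance, and cutpoint transfer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-platform assay calibration, concordance, and cutpoint transfer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(markercal)
```

`markercal` validates agreement between two continuous-score biomarker
quantification platforms and transfers prognostic cutpoints between them.
This vignette is the package's account of the statistical methods: the
models, the tunable parameters and why their defaults are what they are,
the numerical choices, and what the synthetic cohorts do and do not
establish about real data.

## The measurement model and calibration

Each platform is assumed to report an affine transformation of a latent
true log-intensity plus independent noise:

$$x_i = \alpha_x + \beta_x \mu_i + e_{xi}, \qquad
  y_i = \alpha_y + \beta_y \mu_i + e_{yi},$$

with $e_{xi}, e_{yi}$ independent mean-zero normals. Working on the log
scale is essential: fluorescence intensities are positive, span about two
orders of magnitude across a cohort, and platform differences are
multiplicative, so the platforms' relationship is linear in the logs.
The package uses the natural log throughout. The choice of base is
immaterial to the structure of the conversion — an affine map in one base
is affine in any other — and the conversion coefficients a practitioner
reports are base-invariant in form; the natural log is simply declared
so that `log_score` values are reproducible.

Under this model the difference $D = y - x$ is linear in the average
$A = (x+y)/2$. `ba_regression()` fits $D = a + bA$ by ordinary least
squares, and `conversion_from_ba()` inverts the algebra to the
conversion equation $y = \alpha + \beta x$ with

$$\alpha = \frac{a}{1 - b/2}, \qquad \beta = \frac{1 + b/2}{1 - b/2}.$$

The residual standard deviation is propagated by the same
$1/(1-b/2)$ factor into `pred_sd`, the half-width basis of a prediction
band on the target scale. `limits_of_agreement()` draws the band at the
fitted difference $\pm z_{(1+\gamma)/2}\, s$ in difference-vs-mean
coordinates. Standard-normal quantiles are used rather than $t$
quantiles: at the cohort sizes this method is used for (hundreds of
pairs) the two differ in the third decimal, and the normal form matches
the classical limits-of-agreement definition. The full variance-component
machinery of replicate-based method comparison (MethComp-style) is
deliberately out of scope: with one score per case per platform a single
residual standard deviation is all the data support.

Two deliberate asymmetries are worth noting. `invert_calibration()` is
the exact algebraic inverse ($\alpha' = -\alpha/\beta$,
$\beta' = 1/\beta$); refitting the regression in the opposite direction
on noisy data gives a slightly different equation, the two agreeing to
$O(s^2)$. The pipeline reports the refitted equation in each direction,
as a practitioner would, while tests verify the exact-inverse property
on noise-free data. And cases with nonpositive raw scores are rejected
with their identifiers rather than offset-corrected, because an additive
offset before the log silently bends the very linearity the model
assumes.

## Concordance statistics

`ccc()` implements the concordance correlation coefficient
$\rho_c = 2 s_{xy} / (s_x^2 + s_y^2 + (\bar x - \bar y)^2)$ with
*n*-denominator (population) moments — the original estimator
definition. The variant with $n-1$ denominators shifts the third decimal
at $n \approx 200$, which matters when judging agreement against
thresholds like 0.98, so the choice is fixed and documented. The
confidence interval is computed on the Fisher $z$ scale with the
estimator's standard asymptotic variance and back-transformed, the
conventional interval for this statistic.

`cohens_kappa()` reports $\kappa = (p_o - p_e)/(1 - p_e)$ with the
large-sample standard error
$\sqrt{p_o(1-p_o)/(n(1-p_e)^2)}$ for the confidence interval and the
Fleiss null-hypothesis standard error for the $p$-value — the
conventional pairing of "SE under the alternative for the CI, SE under
the null for the test". Degenerate tables (a marginal of zero, or
$p_e = 1$) are flagged rather than silently producing intervals the
asymptotics do not cover.

`coefficient_of_variation()` computes each case's replicate CV
(sd over mean, $n-1$ denominator) and aggregates across cases as the
root mean square, reported in percent. RMS aggregation is chosen because
the per-case CVs estimate a common relative noise scale, whose natural
pooling is on the variance scale; the operation is isolated so a
different aggregation is a one-line change.

## Survival analysis

Recurrence-free survival runs from diagnosis to first recurrence, with
death without recurrence treated as censoring, not as an event — the
reading consistent with defining follow-up as "date of last contact or
death in the absence of recurrence". `km_fit()`, `logrank_test()` and
`cox_fit()` delegate to the `survival` package (product-limit estimate,
hypergeometric-variance log-rank, partial-likelihood Cox fit); the
package's tests pin these against hand-computed oracles on small
instances. Cox fits use Efron tie handling: follow-up is recorded in
months, ties are common at that granularity, and Efron's approximation
is less biased than Breslow's there. Intervals are Wald, two-sided, 95%.
Monotone partial likelihoods (a marker class completely separated from
events) raise a `separation` flag instead of reporting a spuriously
finite hazard ratio.

## Data-driven cutpoints and transfer

`datadriven_cutpoint()` scans every admissible split of the marker:
candidate thresholds are midpoints between consecutive distinct values
with at least `min_frac` of the cohort on each side, and the threshold
maximizing the two-group log-rank chi-square is selected — the standard
first-split criterion of survival recursive partitioning, used here for
a single dichotomization rather than full tree growth. The scan is
implemented as an incremental sweep over the event-time grid, costing
O(candidates × distinct event times), so cohorts of a few thousand cases
scan in seconds. Ties in the statistic resolve to the smallest
threshold, making the search deterministic.

`min_frac` defaults to 0.10 so that a discovered "low" group is
clinically non-trivial; it is explicit and configurable because the
underlying recursive-partitioning defaults that shaped published
cutpoints are typically unreported. The low class includes the threshold
value (`low` $\iff x \le$ threshold), a convention that must be fixed
somewhere and is documented here. `percentile_cutpoint()` returns the
$\lceil p n \rceil$-th order statistic so that at least $p$ of the
cohort falls at or below it, the right convention for transferring a
percentile-defined published threshold.

Cross-validation (default 10 folds, seeded assignment) re-derives the
threshold within each training fold, fits a one-covariate Cox model, and
evaluates the held-out partial-likelihood deviance against the null.
The split is `cv_supported` when the total held-out deviance reduction
exceeds one standard error of the per-fold reductions — the 1-SE
convention of recursive-partitioning pruning. A plain
"any reduction at all" rule endorses a noise split far too often,
because the summed fold reductions are nearly symmetric around zero
under the null; with the 1-SE margin, null cohorts are endorsed only a
few percent of the time while strong splits (hazard ratios near 3–4)
are endorsed essentially always. Cross-validation is a support check
only; the reported threshold always comes from the full-cohort scan,
never from averaging fold thresholds.

`transfer_cutpoint()` maps a threshold through the fitted conversion
equation and refuses a model whose source platform does not match the
cutpoint's platform label. Classification agreement between a native and
a transferred cutpoint approaches 100% as platform noise vanishes; at
realistic noise the discordant cases cluster around the threshold, which
is exactly the behavior the 2×2 agreement statistics quantify.

## Time-dependent ROC

`td_roc()` implements the cumulative-case/dynamic-control estimator
under independent censoring: at horizon $t$, cases are subjects with an
observed event by $t$, controls are subjects event-free beyond $t$, and
subjects censored before $t$ drop out while the remainder are reweighted
by the inverse probability of censoring, estimated by reverse
Kaplan–Meier on the pooled cohort (cases weighted by $1/\hat G(T_i^-)$,
controls by $1/\hat G(t)$). This variant is chosen over
incident/dynamic alternatives because it is consistent under independent
censoring and reduces *exactly* to the empirical rank AUC when no one is
censored — which makes it testable against a brute-force pairwise count.
Marker ties contribute 0.5 to concordance. Low marker is the default
risk direction (the marker this pipeline was built around is
protective), with `direction = "high"` available. Because the estimator
depends on the marker only through ranks, affine calibration between
platforms provably cannot change the AUC — the formal counterpart of
comparing platforms' ROC curves on raw values.

`auc_series()` evaluates a grid of horizons and reports inestimable
horizons (no events yet; no subjects remaining) as `NA` rows with the
reason, so a series over years 1–12 degrades gracefully at the ends of
follow-up.

## The synthetic cohort generator

The generator exists so that every downstream stage has inputs with the
statistical structure the analysis assumes, at the scale of the
motivating study. Its defaults are the study conditions, fixed once:

* **Latent marker**: $\mu_i \sim N(2, 0.5^2)$ on the log scale, i.e.
  lognormal raw intensities spanning roughly two orders of magnitude.
  No distributional form for true marker levels is published; the
  lognormal is the simplest choice consistent with a linear log–log
  scatter between platforms, and it is a modeling decision, not an
  empirical claim.
* **Platforms**: an identity reference platform and a second platform
  with $(\alpha, \beta) = (0.43, 0.95)$ — the published conversion
  between two real fluorescence immunohistochemistry platforms — each
  with noise sd 0.05 log-units, which places the post-calibration
  concordance correlation near 0.98–0.99, the published regime.
* **Outcome**: exponential event times with hazard
  `baseline_rate` × `hr_low` for the lowest `cut_quantile` fraction of
  latent values (defaults 0.2 and 3.7, the published low-fraction and
  hazard-ratio regime), censored uniformly over 1–205 months, the
  published follow-up window. The exponential is the simplest
  proportional-hazards-consistent generator; `baseline_rate` defaults to
  0.002 events/month, which makes recurrences relatively rare over the
  window, as in the motivating cohort. An independent
  progesterone-receptor-style covariate (16% negative, hazard ratio 3)
  is included so parsimonious two-covariate Cox models are exercisable.
* **Chromogen scores**: the lowest `floor_quantile` fraction of latent
  values (default 0.875) report 0 — the pathologist's detection floor —
  and the rest map monotonically onto integers 1–95, the reported
  scoring range.
* **Replicates**: each operator replicate is the raw score times
  $(1 + \delta)$, $\delta \sim N(0, \text{cv}/100)$ drawn independently
  per replicate. With independent draws the RMS-aggregated CV estimator
  converges to the nominal `cv_percent`; perturbing only one member of
  each pair would converge to $\text{cv}/\sqrt 2$ and could not emulate
  a reported 1.0% interoperator CV with a 1.0% setting, which is why
  the independent-draw reading is implemented.

Every generator is a pure function of its inputs and seed; identical
seeds reproduce output bit-for-bit.

What passing tests on these cohorts establishes: that the pipeline's
algebra, estimators and decision rules recover the parameters that
generated the data, at the right cohort sizes and noise levels. What
they do not establish: anything about image segmentation, core-to-case
aggregation, staining batch effects, non-affine platform relationships,
informative censoring, or non-proportional hazards — none of which the
generator emulates. Results on real cohorts depend on those assumptions
holding approximately.

## Numerical choices and degenerate inputs

* Test-suite and acceptance problem sizes are chosen to make sampling
  noise negligible relative to the asserted tolerances: 323 pairs for
  calibration recovery (200 replicates), 2000 cases for cutpoint
  recovery, 336 cases for operator-variability summaries, and small
  hand-checkable instances (n = 3–6) wherever an exact oracle exists.
* `ba_regression()` refuses fewer than 3 complete pairs and a constant
  pair-average; `conversion_from_ba()` refuses $b = 2$, where the
  conversion is undefined.
* `ccc()` refuses zero-variance inputs; its CI collapses to a point when
  $|\rho_c| = 1$, where the Fisher-z variance is undefined.
* The cutpoint scan refuses constant markers, all-censored cohorts, and
  `min_frac` constraints that admit no candidate.
* `td_roc()` refuses horizons beyond follow-up, horizons before the
  first event, and censoring distributions that reach zero before the
  horizon (undefined weights).
* Report rounding (coefficients 2 dp, concordance/kappa 3 dp,
  percentages 1 dp, hazard ratios 2 dp) happens only in the report
  layer; every object carries full precision, and every number in a
  report is recomputable by calling the corresponding operation
  directly.

## Known limitations

* Calibration assumes a single affine relationship across the whole
  intensity range; range-dependent (non-linear) platform differences are
  not modeled.
* The prediction band uses one residual standard deviation; no
  variance-component decomposition or replicate-based error partition.
* The cutpoint search performs a single split with no multiplicity
  correction of its in-sample log-rank statistic; cross-validation
  support is the guard against overfitting, and the in-sample statistic
  should not be read as a calibrated test.
* No weighted or multi-category kappa; no AUC confidence bands or
  formal between-platform AUC tests; no competing risks or time-varying
  covariates.
* One score per case per platform is required; aggregation over
  multiple tissue cores per tumor happens upstream of this package.
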