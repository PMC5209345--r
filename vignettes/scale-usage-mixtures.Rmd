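---
title: "Mixture partial credit models for diagnosing rating-scale usage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mixture partial credit models for diagnosing rating-scale usage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement problem

Long rating scales (eleven response options are common in large panel
surveys) presume that respondents can and do distinguish eleven ordered
states of the trait being rated. Often they cannot: people collapse the
scale into a handful of subjectively meaningful categories, gravitate to the
extremes, or skip particular options altogether. Such content-unrelated
response behaviour — inappropriate scale usage — contaminates observed
scores, inflates internal-consistency estimates, and differs between
respondents.

`mixpcm` treats this as a mixture measurement problem: the population is a
finite mixture of latent classes, each using the same items with its own
category thresholds. Fitting the mixture, inspecting class-specific
parameters, and relating class membership to covariates together form a
complete workflow for judging whether a response format is being used as
intended.

## The model family

For an item $i$ with categories $x \in \{0, \dots, m_i\}$, the generalized
partial credit model (GPCM) gives the category probability

$$
P(X_{vi} = x \mid \theta_v) =
  \frac{\exp \sum_{s=0}^{x} \delta_i (\theta_v - \tau_{is})}
       {\sum_{c=0}^{m_i} \exp \sum_{s=0}^{c} \delta_i (\theta_v - \tau_{is})},
$$

with the $s = 0$ term identically zero. The thresholds $\tau_{is}$ are the
latent-trait locations where the characteristic curves of categories
$x - 1$ and $x$ cross; the discrimination $\delta_i > 0$ controls how
sharply probabilities change in $\theta$. The partial credit model (PCM) is
the special case $\delta_i \equiv 1$.

The mixture extensions index parameters by a latent class $g$ with weights
$\pi_g$ and class-specific trait distributions $N(0, \sigma_g^2)$:

* **mPCM** — class-specific thresholds, all discriminations equal;
* **rmGPCM** — class-specific thresholds, item-specific discriminations
  *shared across classes* (the "restricted" model);
* **mGPCM** — thresholds and discriminations both class-specific.

### Identification

Class means are fixed at zero and one latent variance is free per class.
For the GPCM/rmGPCM the first item's discrimination is fixed at 1; for the
mGPCM a single overall reference (item 1, class 1) is fixed. With
$m_i = 10$ and five items this accounting yields 55, 107, 159, 211 and 263
free parameters for one to five classes of the rmGPCM, and 155/169 for the
three-class mPCM/mGPCM — `count_free_parameters()` implements exactly this
scheme.

A caveat worth knowing: under the single-reference mGPCM convention, any
class without a fixed discrimination retains a scaling ridge (rescaling
$\delta_{\cdot g}$, $\sigma_g$, $\tau_{\cdot g}$ jointly leaves the
likelihood unchanged). The likelihood value and all probability statements
are unaffected, but individual mGPCM parameters from such classes should
not be over-interpreted, and their information matrix is singular by
construction (`standard_errors()` then falls back to a pseudo-inverse and
flags it). This mirrors the instability practitioners report for
fully class-specific discrimination structures.

## Estimation

`fit_mixgpcm()` maximizes the marginal likelihood, integrating the trait
out class-by-class with Gauss–Hermite quadrature rescaled by $\sigma_g$.
The schedule is the conventional one for mixture IRT:

1. **Short EM from many random starts.** Thresholds are drawn
   uniform$(-2, 2)$, sorted within item and jittered; discriminations
   log-uniform on $(0.5, 2)$; mixing weights from a flat simplex;
   variances start at 1. One user seed deterministically spawns one
   sub-seed per start, so runs are exactly reproducible and the best start
   is recorded.
2. **Full EM** from the best start until the relative log-likelihood change
   drops below `em_tolerance` (default $10^{-8}$) or the cap (default
   8000). The M-step maximizes each item's expected complete-data
   likelihood with a bounded quasi-Newton update (shared-discrimination
   structures couple classes within an item but items stay separable),
   updates mixing weights in closed form, and updates each
   $\log \sigma_g^2$ by line search over $[\log 10^{-3}, \log 25]$. Every
   sub-step is accept-only (a halving line search falls back to the current
   value), so the observed log-likelihood is monotone — a property the test
   suite asserts on every fit it runs.
3. **Quasi-Newton refinement** (L-BFGS-B, analytic score) on unconstrained
   transforms — free thresholds, $\log \delta$, $\log \sigma^2$, mixing
   logits — inside the same box the EM respects (default cap 600
   iterations). The box matters: without it, degenerate ridges
   ($\sigma^2 \to \infty$ straddling well-separated clumps, or
   $\delta \to 0$ with $\tau \to \infty$ at fixed product) can swallow the
   optimizer. The bounds ($|\tau| \le 30$, $\delta \in [10^{-3}, 10^3]$,
   $\sigma^2 \in [10^{-3}, 25]$) are far outside any interpretable
   estimate, and estimates beyond the flag levels ($\pi < 10^{-4}$,
   $\delta > 50$, $\sigma^2 < 10^{-4}$, $|\tau| > 10$) are reported as
   extreme/boundary in the fit's `flags`.

Classes are always returned in descending order of $\pi_g$, and posterior
columns follow, which keeps label switching out of downstream code.

### Quadrature resolution

The default grid has 21 nodes, which is adequate for short scales and
moderate slopes. Five 11-category items with discriminations up to about
2.6 concentrate each person's posterior into an interval narrower than the
central node spacing, and a 21-node grid then biases variance estimates
noticeably downward. The node-doubling check (pattern probabilities stable
to $10^{-6}$ under doubling) is the package's criterion: for this item
regime it is met from about 60 nodes, so the recovery experiments and the
acceptance script use `quadrature_nodes = 61`. Costs grow linearly in the
node count; the compiled E-step makes 61 nodes cheap even at $n = 4000$.

### Standard errors

`standard_errors()` differentiates the analytic score numerically to get
the observed information; the default SEs are the square roots of the
inverse-information diagonal, with a sandwich variant (per-person score
outer products) available as `type = "sandwich"`. Discrimination and
variance SEs are delta-method transforms from the log scale. Non-finite or
implausibly large SEs are counted as "extreme", and a singular information
matrix (the mGPCM ridge, or genuinely flat directions from near-empty
categories) switches to a pseudo-inverse with a flag rather than failing.

## Choosing the number of classes

`enumerate_classes()` fits a range of class counts and tabulates AIC, BIC
and CAIC $= -2\,\mathrm{LL} + p(\ln n + 1)$; the smallest CAIC wins, with
ties resolved toward fewer classes. Alongside the random starts, each
G-class fit is seeded incrementally from the (G−1)-class solution with its
largest class split and jittered: random starts alone occasionally miss
the G-class basin, which would bias the comparison against the larger
model, and the incremental start closes that gap at the cost of some slow
plateau iterations. Absolute fit uses
`parametric_bootstrap_gof()`: Pearson or Cressie–Read ($\lambda = 2/3$)
statistics over the observed-pattern cells plus one pooled remainder cell —
the full $11^5$ outcome space is far too sparse to use directly, and the
remainder cell restores the total so both statistics are well defined. The
limit cases $\lambda \in \{0, -1\}$ of the power-divergence family are
deliberately rejected rather than silently substituted. Bootstrap refits
default to 10 starts rather than the full complement, a documented
tractability concession; p-values use the add-one convention
$(1 + \#\{T_b \ge T_{\text{obs}}\}) / (B + 1)$ and are reproducible given
the seed. Nested variants are compared with `bootstrap_lr_test()`, which
seeds each replicate's general fit from the restricted replicate solution
(embedding the parameters) so replicate differences cannot go negative.

## Reading the diagnostics

* **Threshold order** (`threshold_order_report()`): inverted adjacent
  thresholds ($\tau_s > \tau_{s+1}$; ties count as ordered) mean some
  category's curve is covered by its neighbours.
* **Avoided categories** (`modal_category_set()`): a category that is never
  the strict argmax of the characteristic curves anywhere on
  $[-6, 6]$ (step 0.01; near-ties within $10^{-9}$ count as attained) is
  avoided — respondents in that class effectively do not use it. The
  default range guarantees both extreme categories register as modal for
  any $\sigma \le 2$. Avoidance depends only on the thresholds, not on the
  discrimination, and the report never labels classes as response-style
  types: it provides the evidence (an extreme-response class shows up as
  wide end categories and many covered middle ones), the labelling is the
  analyst's.
* **Latent category widths** (`latent_category_widths()`): adjacent
  threshold differences; the class summary reports the min/max over
  positive (ordered) widths across all items, since the corresponding
  published "range" statistic does not specify its exact cell set — treat
  it as descriptive, not comparable.
* **Expected category frequencies** (`expected_category_frequencies()`):
  quadrature average of the curves over each class's trait distribution,
  averaged over items — the model-implied response profile per class.
* **Reliability**: `marginal_reliability()` is EAP-based —
  $\mathrm{var}(\widehat{\mathrm{EAP}})$ over
  $(\mathrm{var}(\widehat{\mathrm{EAP}}) + \overline{\mathrm{postvar}})$ —
  computed within the mixture, against `cronbach_alpha()` on raw scores.
  Controlling class-specific scale usage typically *lowers* the
  coefficient: part of what alpha counts as signal is stylistic. Which
  exact estimator the motivating application used is not stated, so only
  the qualitative comparison is meaningful.

## Relating membership to covariates

The three-step route (classify, quantify error, regress) is implemented in
`classification_error_matrix()` and `three_step_multinomial()`. The
correction is the ML variant: the observed modal label $s_v$ enters the
likelihood through $\sum_t P(t \mid x_v; B)\, D[s_v, t]$, where $D$ is the
estimated misclassification matrix, so coefficients refer to the *true*
class. With $D = I$ this is an ordinary multinomial logit (the test suite
checks the reduction against an independent implementation), and as
classification entropy vanishes the adjusted and unadjusted estimates
coincide, while under real misclassification the unadjusted slope is
attenuated. Wald CIs $\exp(B \pm 1.96\,\mathrm{SE})$ match the reporting
format of applied three-step tables; the pseudo-$R^2$ is McFadden's on the
corrected likelihood — a deliberate, documented choice since published
values of "pseudo-$R^2$" rarely state their variant, and it should not be
compared across studies. Missing covariates are rejected outright:
imputation is a pre-processing concern outside this package's scope.

## The synthetic-data generator

`generate_responses()` draws class, trait and responses exactly in the
model's generative order, and `scenario_preset()` bundles the conditions
the package is designed around:

* `"hilda_like"` — five 11-category satisfaction items, three classes with
  proportions 0.40/0.33/0.27, shared discriminations
  (1, 0.71, 1.27, 2.58, 1.76) and published class-specific thresholds
  transcribed verbatim. Latent variances are not published and are set to
  1 — the natural latent scale — once and for all. Data from this preset
  are left-skewed (more mass in the upper than the lower half of the
  scale), though less sharply than the original survey distribution, whose
  latent spread is unknown.
* `"hilda_like_stable"` — same with thresholds clipped to $|\tau| \le 4$.
  The verbatim set contains a few extreme printed values (e.g. $-5.71$)
  whose own standard errors are huge; for parameter-recovery experiments
  the clipped truth is the appropriate one.
* `"ordered_11"`, `"avoided_mid"`, `"ers_dichotomous"` — single-class
  archetypes: ordinary equidistant usage, a covered middle category
  (thresholds 7/8 swapped), and a fully reversed threshold sequence where
  only the end categories are ever modal.

`generate_covariates()` draws covariates class-conditionally so that the
implied membership model is an *exact* multinomial logit with the requested
coefficients: a normal covariate with variance $\sigma^2$ and class shift
$\beta_g \sigma^2$ contributes log-odds $\beta_g$; a categorical covariate
tilted by $e^{\beta_{gl}}$ contributes dummy coefficients $\beta_{gl}$.
That makes end-to-end coefficient-recovery tests sharp. The default
battery mirrors a typical employment-survey predictor set with effect
magnitudes echoing applied findings.

What the generator does **not** emulate: household clustering, sampling
weights, item-level missingness patterns, or covariate missingness (and
hence multiple imputation). Tests passing on these data therefore certify
the estimator and diagnostics under clean mixture sampling, not robustness
to survey complexities.

## Problem sizes used by the test suite

The suite exercises recovery at $n = 4000$ with 10 starts and 61 nodes
(median over 5 seeds), class enumeration over $G \in 1..4$ at $n = 4000$
with 21 nodes across 10 seeds, bootstrap calibration with $B = 99$ over 20
replications at $n = 150$, and bootstrap-SD cross-checks of the standard
errors at $n = 600$, $B = 60$. These sizes were chosen so the full suite
runs on a single CPU in well under half an hour while keeping every check
statistically meaningful.

## Known limitations

* **Weakly identified thresholds.** When a class–item–category cell has
  near-zero expected frequency (exactly the situation long scales
  produce), its thresholds are weakly identified; ML estimates drift
  toward the box bounds and are flagged as extreme. Aggregate recovery
  metrics that include such thresholds are dominated by them — an intrinsic
  information limit, not an optimizer defect (random-start and
  truth-seeded fits reach the same likelihood). Interpret flagged
  thresholds only through the diagnostics (avoidance, ordering), which are
  stable.
* **CAIC is conservative at moderate samples.** CAIC's per-parameter
  penalty $\ln n + 1$ is the steepest of the three criteria; detecting a
  third class that adds 52 parameters requires the log-likelihood gain to
  exceed roughly $26(\ln n + 1)$. Under the three-class preset the true
  per-person separation sits just below that bar at $n = 4000$ (CAIC then
  prefers two classes) and above it at the survey-scale $n \approx 7000$
  (three classes selected with a clear margin). When class separation is
  modest, treat CAIC class counts as sample-size dependent and corroborate
  with BIC and the bootstrap difference test.
* **mGPCM scaling ridge** under the single-reference identification, as
  described above.
* Bootstrap refits with reduced starts can occasionally land in local
  optima, which conservatively inflates bootstrap statistics; replicates
  that fail outright are dropped and counted, with a warning beyond 10%.
* The latent trait is unidimensional within class; multidimensional or
  graded-response formulations are out of scope.
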