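---
title: "Modeling labor progression with sparse multi-output Gaussian processes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling labor progression with sparse multi-output Gaussian processes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The prediction problem

During the first stage of labor, clinicians track progress through
periodic pelvic examinations recording cervical dilation (0-10 cm),
cervical effacement (0-100%) and fetal station (integer scores -3..+3
relative to the ischial spines), alongside cardiotocography and
intervention events (induction, epidural, rupture of membranes).
`laborgp` frames labor monitoring as a *causal one-step regression*: at
each exam, predict the current dilation and station from information
available strictly beforehand — the previous exam's dilation, station
and effacement, the cumulative contraction count since the reference
time t0, and the epidural and induction indicators. Unlike classical
time-based labor curves (Friedman, Zhang), every predictor is available
in real time, so the model can run at the bedside, and it returns a
predictive distribution rather than a point estimate.

## Preprocessing

Raw exam tables are cleaned per delivery in a fixed order:

1. restrict to the final 20 h before delivery (window closed on both
   ends) and shift times so the first retained exam sits at t0 = 0;
2. drop exams whose dilation is strictly below the last retained
   exam's (a single left-to-right pass; clinically these are
   measurement disagreements, since true dilation does not regress);
3. drop any exam within 5 minutes of the previously retained one;
4. linearly interpolate a missing dilation/effacement/station value
   when both a preceding and a following exam observed that field;
   remove exams that remain incomplete.

Deliveries with fewer than two clean exams are excluded with an
explicit signal (condition class `laborgp_excluded`), never silently.
Cumulative contraction counts and intervention flags are evaluated at
the *target* exam's time — they accrue continuously and are known
before the exam's outcome, so causality is preserved. Interval
boundaries are inclusive throughout (onset at exactly t counts;
epidural at exactly the exam time flags 1). Station is coded on the
integer -3..+3 convention.

## The model

Stacking the two outputs with an output index $i \in \{0, 1\}$
(dilation, station), observations follow

$$y(x, i) = f(x, i) + \varepsilon_i, \qquad
  f \sim \mathcal{GP}\!\left(\mu_\phi(x, i),\;
  k_\theta(x, x')\, B_{ij}\right), \qquad
  \varepsilon_i \sim \mathcal{N}(0, \sigma_i^2).$$

**Kernel.** $k_\theta$ is the *sum* of a squared-exponential, a Matern
($\nu = 5/2$ by default; 3/2 and 1/2 available) and a linear kernel,
each with per-dimension (ARD) scales. The three terms play distinct
roles: smooth progression, abrupt changes (precipitous dilation,
arrest release), and the long-run non-decreasing trend. Summing — rather
than multiplying — the components keeps those roles additive and keeps
per-kernel ARD readouts interpretable as predictor importances.

**Output covariance.** The intrinsic-coregionalization matrix
$B = WW^\top + \mathrm{diag}(\kappa)$ (rank 1 by default) scales the
base kernel across outputs, letting station data inform the dilation
surface and vice versa. The implied output correlation is
$B_{01}/\sqrt{B_{00}B_{11}}$.

**Mean.** A small feed-forward network (default two tanh layers of 32
units) maps standardized predictors to the mean. The output index
enters twice: a learned additive embedding on the first hidden layer,
and an output-specific affine readout (the last layer has one row per
output). The readout prevents the two outputs' different surfaces from
interfering through a shared scalar head. Because a ~1300-parameter
mean can interpolate a few hundred pooled transitions outright —
driving the likelihood's noise variance toward zero and destroying
generalization — the network weights carry a zero-mean Gaussian MAP
prior (`net_prior_sd`, default 0.2 on the standardized scale). This is
the single most important regularization choice in the package at
moderate cohort sizes.

**Noise.** Observation noise is per-output by default for two-output
models. The two outputs have different residual scales even after
per-output standardization, and forcing one shared variance measurably
degraded both outputs in development experiments; per-output noise is
the common choice in the coregionalization literature. A scalar
`sigma2` is still accepted everywhere for the shared-noise variant.

**Normalization.** Predictors are z-scored and targets z-scored per
output on the training pool; every reported quantity is
back-transformed.

## Sparse approximation and training

The exact posterior costs $O(n^3)$. `laborgp` uses the collapsed
variational bound for sparse GP regression with $m$ inducing inputs
$Z$ (default 64, k-means-initialized on the training inputs and held
fixed; with the inducing set fixed the bound is still a valid lower
bound, and freezing Z keeps the trainable parameter set small enough
for exact analytic gradients):

$$\mathcal{L} = \log \mathcal{N}\!\left(y \mid \mu_\phi,\;
  Q_{nn} + \Lambda\right) - \tfrac{1}{2}\,
  \mathrm{tr}\!\left[\Lambda^{-1}(K_{nn} - Q_{nn})\right],
  \qquad Q_{nn} = K_{nf}^\top K_{mm}^{-1} K_{mf}.$$

With $Z$ equal to the training inputs the bound equals the exact log
marginal likelihood and the sparse predictor reproduces the exact
posterior — both identities are verified to $10^{-6}$ in the test
suite, against independently coded dense-matrix oracles.

All gradients (kernel hyperparameters, coregionalization factors,
noise, and the full network by backpropagation through
$\partial\mathcal{L}/\partial\mu = (Q_{nn}+\Lambda)^{-1}(y-\mu)$) are
analytic and verified against central finite differences to $10^{-6}$.
Positivity is enforced by softplus reparameterization; Cholesky
factorizations first try the raw matrix and then add escalating jitter
($10^{-8}$ to $10^{-4}$ relative to the mean diagonal). Optimization is
the two-stage hybrid: Adam (default 100-150 steps, learning rate 0.02),
then bounded L-BFGS-B refinement. With analytic gradients this budget
reaches the same optima that a much longer first-order schedule would;
ELBO values at the stage boundaries are recorded in the fitted model
(`milestones`) and are non-decreasing.

## Meta-learning view and per-delivery adaptation

Each delivery is a meta-task; the shared prior is trained by
maximizing the collapsed bound over the pooled transitions of all
training deliveries. Two prediction modes follow:

- **5p (no adaptation).** The standard sparse posterior given the
  pooled training data.
- **5b (test adaptation).** Before predicting exam $k$ of a test
  delivery, the unfrozen parameter groups are fine-tuned on that
  delivery's transitions $1..k-1$ by maximizing their exact marginal
  likelihood, and those transitions join the conditioning set. With no
  past exams, or with every group frozen, 5b coincides with 5p.

By default adaptation unfreezes the mean network's output layer, the
kernel signal variances and the noise, and anchors all unfrozen raw
parameters at their trained values through a Gaussian trust-region
penalty (`adapt_config(prior_sd = 0.5)`). Per-delivery samples are
tiny (often 1-5 exams), and unregularized full unfreezing occasionally
produces grossly wrong adapted models; the anchored restricted default
trades a little adaptivity for robustness. `unfreeze = "all"` with
`prior_sd = Inf` reproduces the unregularized behavior — the
acceptance suite demonstrates that this mode fattens the extreme tail
of the error distribution while the restricted default lowers MAE.

Elapsed time since the previous exam is carried in every transition
sample but excluded from the default predictor set; cumulative
contraction count acts as the physiologic clock. Setting
`train_config(include_elapsed = TRUE)` adds it as a kernel input, and
predictive uncertainty then widens as the hypothetical gap grows — the
behavior a bedside user expects — whereas the mixed-effects baseline's
predictive sd is constant by construction.

## Baselines

- **Time-only GP** (`flavor = "time_only"`): same machinery, single
  predictor (time since t0), dilation output — the stand-in for
  classical labor-curve models.
- **Mixed-effects model** (`fit_me()`): dilation on the five
  fixed effects (previous dilation/station/effacement, cumulative
  contractions, epidural — induction deliberately excluded, matching
  the reference formulation; a flag adds it) plus a per-delivery random
  intercept. Estimated by profiling the variance ratio
  $\lambda = \tau^2/\sigma^2$ with closed-form per-group GLS solves
  (REML by default, ML optional), Wald z p-values, and a numerically
  differentiated observed information for the variance-component
  standard error. The fit agrees with `lme4::lmer` to $10^{-6}$ in the
  test suite while remaining independent of it. Test deliveries are
  predicted at the population level (their random effects are
  unknowable), with predictive variance $\sigma^2 + \tau^2$.

## The synthetic cohorts

The study data are unavailable, so the package ships two generators
with known ground truth.

**Mechanistic simulator (regime A).** Latent dilation follows the
self-accelerating law $\dot d = c\,e^{\alpha (d - 10)}$ (default
$\alpha = 0.35$ per cm): a slow latent phase and an abrupt active-phase
acceleration, the qualitative shape of clinical labor curves. The base
speed $c$ is calibrated so the unimpeded curve lasts 6-14 h; delivery
occurs at 10 cm. Epidural (triggered at a random dilation threshold,
mean 4.5 cm) multiplies the rate by 0.7 thereafter; induction (30% of
deliveries) multiplies it by 0.85; 15% of deliveries insert a 1-3 h
arrest plateau at 4-7 cm. Station is an affine-monotone transform of a
weighted mix (default weight 0.85) of the dilation progress and an
independent monotone latent, giving a tunable dilation-station
coupling; effacement is a concave transform of a similar mix.
Contractions form an inhomogeneous Poisson process (6/h rising by 14/h
toward delivery, simulated by thinning). Observations add Gaussian
noise (0.2 cm, 0.25 station units, 4% effacement), a per-delivery
examiner bias on dilation (sd 0.3 cm — the delivery-level heterogeneity
that the random intercept and the 5b adaptation both target), clinical
rounding (integer cm, integer station, 5% effacement steps), and a 4%
missingness rate on interior exams. Exam times follow gamma gaps (mean
1.6 h) over the labor span; absolute times get a random origin and an
occasional pre-window exam so the windowing code is exercised. All
randomness flows from per-delivery substreams derived from
`(seed, delivery index)`, so delivery $i$ is reproducible regardless of
cohort size.

What regime A does *not* emulate: fetal heart rate, cesarean
exits (every simulated labor completes), correlated missingness,
hospital-level effects, or real inter-observer error structure. Passing
patterns on it demonstrate internal consistency of the pipeline, not
clinical performance.

**Prior sampler (regime B).** Exact multivariate-normal draws from the
model's own prior at arbitrary designs, with the generative
hyperparameters recorded. Used where the generative process must match
the model class exactly: interval calibration (coverage of the nominal
90% interval is 0.90 within Monte-Carlo error over >= 2000 held-out
points) and parameter recovery (ARD lengthscales of the Gaussian
component within 30%, output correlation within 0.15 at 2000 stacked
points — the kernel variance itself is not assessed: it trades off
against the scale of $B$, and even the identifiable amplitude product
is only weakly determined by a single function realization).

## Evaluation harness

`run_evaluation()` implements grouped k-fold cross-validation: whole
deliveries are assigned to folds (so no delivery leaks across
partitions — the defensible unit given per-delivery adaptation); fold
$f$ tests fold $f$, the next fold cyclically is validation, the rest
train (80/10/10 by delivery at $k = 10$). It reports RMSE and MAE per
fold, model and output; two-sided paired t-tests (Wilcoxon optional)
on per-exam squared and absolute errors, plus a fold-level pairing as
a secondary readout (fold-level $n = k$ alone could never yield the
very small p-values exam-level pairing can); elapsed-time-binned error
and predictive-sd tables on closed-open integer-hour bins (0-8 h and
an open tail); and empirical interval coverage. No multiplicity
correction is applied across the handful of pre-planned contrasts, and
the printed report says so.

## Problem sizes and numerical defaults

The shipped experiments use cohorts of 80-250 deliveries, $m = 48$-$64$
inducing points, 100-150 Adam steps and 50-80 L-BFGS-B iterations —
sizes at which one harness fold trains in tens of seconds on a single
core and the full 10-fold comparison completes in minutes. Jitter
escalates $10^{-8} \to 10^{-4}$; softplus keeps variances and
lengthscales positive; ties in the descending-dilation filter keep the
earlier exam; equal-dilation consecutive exams are retained (only
strict descents are pathological).

## Known limitations

- The ICM transfer gain between dilation and station is small when both
  outputs are observed at every exam with comparable relative noise —
  exactly the regime the simulator produces — so the dual-output model's
  advantage over the single-output model is parity-level there, even
  though the output correlation itself is recovered almost perfectly.
  Larger gains require asymmetric observation designs or noise.
- Adaptation is sequential per exam and dominates harness cost for the
  5b mode; the harness therefore allows running a subset of folds.
- Multi-step forecasting is deliberately out of scope: the model
  predicts the next exam only.
- Non-Gaussian likelihoods and more than two outputs are not supported.
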