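---
title: "Gaussian process growth-curve analysis: models, choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gaussian process growth-curve analysis: models, choices, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(gpgrowth)
```

This vignette is the package's own account of its statistical machinery:
the models and their assumptions, the parameters that matter, the
numerical choices, and what the synthetic-data tests do and do not
establish about real plate-reader data.

## Data model and preprocessing

The unit of data is a long-format table: one row per (time, well)
observation with OD, a replicate (well) label, and categorical
covariates (strain, condition, batch). `log_baseline_normalize()`
prepares raw OD for modeling in two steps:

1. log2-transform the OD values;
2. per (strain, condition) group, fit an ordinary least-squares
   polynomial of degree 5 to all raw observations at the group's first
   10 distinct time points (all replicates pooled), and subtract the
   polynomial's value at time zero from every log2-OD in the group.

After normalization every group starts at approximately zero, so
curves are comparable across strains and conditions and a zero-mean GP
prior is sensible. Two choices here were genuinely open and are fixed
as follows: the baseline polynomial is fit on the *pooled raw points*
of the head window rather than on replicate means (pooling weights
wells by their observation count, which is what least squares does
naturally and is robust to a missing well), and the baseline is
*subtracted after* the log transform, which is what "normalize starting
growth levels to zero" means on the log scale.

Subsampling to a coarser grid (`subsample_timepoints`) keeps
observations whose time stamp is a multiple of the interval within an
absolute tolerance of 1e-6 h; plate readers emit near-exact grids, so
the tolerance only has to absorb floating-point representation error.
A 48-h experiment at 30-min resolution yields 12 points per replicate
at a 4-h interval and 8 at 6 h.

## The GP regression model

Observations are modeled as a zero-mean multivariate Gaussian
`y ~ N(0, K + sigma2_nugget I)`. The prior mean is identically zero —
normalized log2-OD starts at zero, and deviations from zero are what
the kernel explains. Four kernel families are implemented, with the
conventions:

- `rbf`: `sigma2 * exp(-||dx||^2 / l^2)`. Note there is *no* factor of
  1/2 and the denominator is `l^2`; this is a pure reparameterization of
  the textbook form, and the derivative formulas below are derived from
  this exact expression.
- `ard_rbf`: `sigma2 * exp(-sum_k dx_k^2 / l_k^2)`, one lengthscale per
  input dimension. A large `l_k` makes dimension k irrelevant — this is
  how nested model comparisons stay meaningful (see below).
- `matern32`: `sigma2 (1 + sqrt(3) r) exp(-sqrt(3) r)` with
  `r = ||dx|| / l`, the standard Matérn-3/2 scaled distance. This
  process is only once differentiable, so derivative-based metrics
  refuse it.
- `linear`: `sum_k w_k x_k x'_k`.

The nugget is independent observation noise: it is added once per
*observation* on the diagonal of the training covariance. Two wells
measured at the same time therefore share the latent growth value but
not the noise term. (The scalar kernel functions `rbf_kernel()` etc.
keep the indicator form `delta(x_i = x_j)` of the covariance function
itself; the distinction only matters when duplicate design rows exist,
and the matrix builder `kernel_matrix()` is the authority for training
covariances.)

Covariates enter the kernel unscaled: hours for time, {0, 1} for
strain, stress, and the strain-by-stress interaction. The binary
covariates' lengthscales are then directly interpretable — `l_strain`
around 1 means the two strains' curves are substantially decorrelated,
`l_strain` of hundreds means the strain label is ignored.

### Hyperparameter optimization

All hyperparameters are log-parameterized and fit by L-BFGS-B with
analytic gradients, best of several seeded restarts (default 5).
Lengthscales are bounded to [0.01, 1000] input units and variances to
[1e-8, 1e4]; the nugget floor of 1e-8 also guarantees the training
covariance is invertible. Cholesky failures escalate jitter from 1e-10
to 1e-4 of the mean diagonal before giving up.

One numerical device deserves a note because it shapes everything
downstream: replicated designs make the training covariance low-rank
plus diagonal. With `U` distinct (time, covariate) rows among `n`
observations, the Woodbury identity and the matrix determinant lemma
give the *exact* marginal likelihood and its gradient in `O(U^3)`
rather than `O(n^3)`. A 288-observation strain test has only 24
distinct rows, so a likelihood evaluation costs microseconds — which is
what makes 100-permutation Bayes-factor calibration routine. The
grouped path is checked against the dense Cholesky computation in the
unit tests; it is a factorization, not an approximation.

## Growth parameters

- `mu_max`: the squared-exponential kernel is smooth, so d/dt of the
  latent function is itself a GP whose cross- and auto-covariances are
  the analytic partial derivatives of the implemented kernel
  (`d k / d t* = -2 dt / l^2 k`;
  `d2 k / dt dt' = (2/l^2 - 4 dt^2/l^4) k`). The point estimate is the
  maximum of the derivative posterior mean over a grid of 100 evenly
  spaced times. The derivative formulas are validated against
  finite-difference and Monte-Carlo oracles in the tests rather than
  transcribed from any secondary source, because an inconsistent
  derivative kernel would not define a valid joint process.
- Carrying capacity `A`: maximum of the noiseless posterior mean over
  the same grid.
- Credible intervals for both are the 2.5/97.5 percentiles of the
  grid maximum across 10,000 joint posterior draws (seeded). A
  pointwise alternative (normal interval of the derivative marginal at
  the argmax) is available via `ci_method = "pointwise"`; the
  max-over-samples construction is the default because the maximum of
  a posterior sample path is the quantity the point estimate
  approximates.
- AUC: the noiseless posterior on 50 evenly spaced points, contracted
  with the left-Riemann weight vector `a = (dt, ..., dt)`. The result
  is exactly Gaussian, `N(a mu, a Sigma a')`. No trapezoid correction
  is applied — the estimator is the stated linear functional, and its
  discretization bias (well under 2% on smooth fits) is part of the
  definition.

## Differential growth testing

Each test compares two nested covariate designs fitted with ARD
kernels:

| test | null design | alternative design |
|---|---|---|
| strain | {time} | {time, strain} |
| stress | {time, strain, stress} | {time, strain, stress, strain x stress} |

`log BF` is the difference of the maximized log marginal likelihoods —
an approximate Bayes factor with hyperparameters point-estimated rather
than integrated over. Because the ARD kernel can disable the added
column (lengthscale at its upper bound reproduces the null fit
exactly), the alternative's optimized marginal should never fall
meaningfully below the null's. The optimizer is therefore always given
structured starts derived from the fitted null — added column switched
off, and switched on at a lengthscale of 0.5 — alongside the heuristic
and random restarts. Without these starts the log BF is occasionally
dominated by local-optimum noise; with them the nesting holds in
practice and permuted and real scores are computed with the same
thoroughness (permuted refits additionally warm-start from the real
fit's optimum).

Calibration is by permutation: within each time point (and within each
stress arm for the stress test, preserving the stress distribution),
strain labels are shuffled across observations, the interaction column
is recomputed from the permuted labels, and the BF is recomputed; 100
permutations by default, and fewer than 5 is refused as uninformative.
The significance threshold is the empirical 80th percentile of the
permuted scores (the k-th order statistic with `k = ceiling(0.8 n)`),
and a real score must *strictly exceed* it. The reported FDR at the
real score is `#{permuted > real} / n_perm`, i.e. the permutation FDR
at a threshold just below the real score with the single real test
count scaled to the permutation count; `permutation_fdr()` exposes the
general formula at any threshold.

`od_delta()` answers the follow-up question — *when* do the strains
differ. For each time `t_k` it forms the joint noiseless posterior over
`(f_m(t_k), f_m(t_0), f_p(t_k), f_p(t_0))` and applies the contrast
`a = (1, -1, -1, 1)`, which subtracts the strains' difference at the
experiment start; the result is exactly Gaussian and the t0 value is
identically zero with zero variance. In interaction mode the contrast
is instead between the stressed mutant's growth with the interaction
column set to 1 and to 0 — the stress response beyond what strain and
stress explain additively. Time points whose central 95% interval
excludes zero are flagged.

## Hierarchical cross-study modeling

Batches (studies) share a latent growth function `g` with per-batch GP
deviations `f_b`; marginally,
`Cov(y_b(x), y_b'(x')) = K_g(x,x') + 1[b=b'] K_f(x,x') + nugget`.
Both levels are ARD kernels over the full stress-test design, and all
2D+3 hyperparameters are fit jointly by maximum likelihood — the exact
finite-batch form of the hierarchical construction, with no iterative
mean-function passing.

With only two batches the variance split between the levels is weakly
identified: the likelihood is nearly indifferent between carrying the
growth trend in `K_g` and duplicating it per batch in `K_f`, and the
optimizer regularly prefers the latter. Conditioning through `K_g`
alone then returns a posterior that has reverted toward the prior, even
though the fit itself is excellent. The package therefore defines the
batch-corrected growth estimate as the *across-batch mean function*
`g + (1/B) sum_b d_b`, obtained exactly by conditioning through
`K_g + K_f / B`. This estimand is invariant to the variance-split
ambiguity, reduces to the pooled fit when batch effects vanish, and
deviations with zero cross-batch mean — such as equal-and-opposite
study offsets — cancel from it by construction.
`predict_shared(..., estimand = "latent")` still exposes the pure
`K_g` conditioning. The optimizer also receives a structured "split"
start (arm structure in the shared kernel, smooth trend plus offsets in
the batch kernel), which resolves most of the remaining local-optimum
failures of the joint fit.

`hierarchical_bf()` repeats the stress test with both designs fitted
hierarchically and permutes strain labels within (batch, stress arm,
time point) cells. The regime it is built for: a modest interaction
effect present in every study, swamped in a pooled analysis by large
smooth between-study offsets (which inflate the pooled model's
effective noise), but cleanly separated from the signal by the
batch-level kernel.

## Primary growth models

The four classical sigmoids are implemented in the
carrying-capacity/`mu_max`/lag reparameterization; the Richards shape
exponent uses `(1+v)^(1+1/v)`, under which `v = 1` reduces exactly to
the logistic. Fitting is Levenberg–Marquardt damped least squares
(`minpack.lm::nls.lm`) with heuristic initialization (`A = max y`,
`mu_max` = steepest finite-difference slope, `lam` = time of that
slope) and box constraints. Non-convergence sets a flag instead of
raising, so benchmark sweeps can score every curve and report failure
counts; a failed fit is scored as missing, never as infinite error.

The Schnute family needs special care. Its bracket
`(1 - b exp(a lam + 1 - b - a t)) / (1 - b)` turns negative at early
times unless `b` is small, and its `b -> 0` limit is the Gompertz curve
with `a = mu_max e / A`. The default initialization therefore starts at
that limit (`b = 1e-3`, `a = mu0 e / A0`), two further starts probe
`b = 0.2` and `b = 0.5`, and a candidate is only accepted if its curve
is finite on a fine grid over the fitted range. Even so the fitted
curve can be undefined just outside the training support (for example
at a held-out time-zero point), which the benchmark records as a
missing score.

The held-out benchmark splits each curve's records 80/20 at random
(split seed derived from the curve's content, so results are
independent of processing order and duplicated curves score
identically), fits the GP and all four primary models on the training
portion, and compares held-out MSE distributions with one-sided Welch
t-tests. Welch's form is used because nothing guarantees equal
variances between a nonparametric and a parametric model's errors.
Classical parameter tests between strains (`parameter_ttest`) are also
Welch, with Bonferroni adjustment (`fwer_adjust`) at a family-wise
budget of 0.25 across per-strain tests.

## The synthetic generator, and what passing tests mean

`synthetic_spec()` encodes the study conditions used throughout the
tests: a 48-h experiment sampled every 30 min, 12 replicates per
(strain, condition) arm, baseline Gompertz parameters `A = 2` log2
units, `mu_max = 0.3`/h, `lam = 5` h, and IID Gaussian noise with
`sd = 0.05` log2 units. Effects enter as multiplicative factors on
`A` or `mu_max`, additive post-inoculation offsets, or a linear
post-peak decline (onset 24 h by default) — the simplest shape with
the rise-then-fall signature of chronic oxidative stress. Batch
offsets are smooth GP draws (lengthscale 12 h, amplitude 0.3 log2
units) applied per batch or per arm, or deterministic functions when a
controlled scenario (equal-and-opposite study effects) is needed.

What the generator does *not* emulate: heteroskedastic or
time-correlated noise, non-Gaussian measurement error, plate position
effects, evaporation artifacts, continuous stress doses, or more than
two levels per covariate. Passing the suite therefore demonstrates
that the estimators and tests are correct and calibrated *under the
stated generative model* — IID Gaussian noise around smooth
strain-condition means — not that real plate-reader data satisfy those
assumptions. The preprocessing and test machinery run unchanged on real
tables, but calibration claims transfer only to the extent the noise
model does.

Problem sizes in the test suite and acceptance script are chosen to
exercise the study conditions at meaningful scale: 50-dataset
calibration and power sweeps at 100 permutations for the strain test,
20-curve benchmarks, and 6-repeat cross-study comparisons at 30
permutations; the masking scenario uses noise sd 0.03 and study offsets
of amplitude 0.8 so that study effects dominate the weak (late-decline,
0.01/h) interaction in a pooled analysis.

## Known limitations

- Strain comparisons are pairwise (parent vs one mutant); multi-strain
  panels are looped over mutants, not modeled jointly.
- The Bayes factor uses point-estimated hyperparameters; it is a
  likelihood-ratio-style approximation, and its absolute scale is not
  an evidence measure — only its rank against the permutation null is
  interpreted.
- The permutation null of the pooled test collapses toward zero when
  permuted labels carry no exploitable smooth structure, making the
  pooled test sensitive to very small real effects; conclusions should
  rest on the calibrated decision, not on the raw BF magnitude.
- Exact GP inference scales with the number of *distinct* design rows;
  dense prediction still scales cubically with observations, which is
  immaterial at plate-reader sizes but rules out very long time series
  without thinning.
- Lag time is not extracted from the GP fit (only from the primary
  models); the GP metrics are `mu_max`, carrying capacity, and AUC.
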