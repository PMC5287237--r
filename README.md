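# gpgrowth

Nonparametric analysis of microbial population growth curves with
Gaussian process (GP) regression.

Plate readers produce optical-density (OD) time series for dozens of
strains and conditions at once. The classical way to summarize such
curves — fitting a sigmoid "primary model" (Gompertz, logistic, Schnute,
Richards) — breaks down whenever growth is not sigmoid: under chronic
stress many microbes rise, peak, and then decline, and a sigmoid fit is
simply wrong. `gpgrowth` instead models log-OD nonparametrically, so the
curve shape is learned from the data, and builds the downstream
statistics (growth parameters, differential-growth tests, cross-study
meta-analysis) directly on the GP posterior. It is intended for
microbiologists and statisticians analyzing strain-by-condition growth
panels.

## The model

Log2-transformed, baseline-normalized OD observations are modeled as a
zero-mean GP:

    y(x) ~ N(0, K + sigma2_nugget * I),
    k(x, x') = sigma2 * exp(-||x - x'||^2 / l^2)

where `x` is time, optionally extended with covariates (strain, stress
condition, strain x stress interaction). With covariates, each dimension
gets its own lengthscale `l_k` (automatic relevance determination, ARD):
a covariate with a very long lengthscale is effectively pruned from the
model. Kernel hyperparameters are point-estimated by maximizing the
marginal likelihood.

On top of the fitted GP, the package provides:

- **Growth parameters.** The maximum specific growth rate `mu_max` is
  the maximum of the posterior mean of d/dt log2-OD (the derivative of a
  squared-exponential GP is again a GP, with analytic cross-covariances);
  the carrying capacity `A` is the maximum of the noiseless posterior
  mean; the area under the curve is the exact Gaussian
  `AUC ~ N(a mu, a Sigma a')` for the Riemann weight vector `a` on a
  50-point grid. Credible intervals for the max-type statistics come
  from joint posterior samples.
- **Approximate Bayes-factor tests.** Differential growth between
  strains (or a strain-by-stress interaction) is scored by
  `log BF = log p(Y | alt design) - log p(Y | null design)`, with
  maximized marginal likelihoods on nested ARD designs. Significance is
  calibrated by permuting strain labels within each time point (100
  permutations; a real score above the 80th percentile of permuted
  scores corresponds to an empirical FDR of at most 20%).
- **Per-time-point contrasts (`od_delta`).** The posterior difference
  between mutant and parent latent growth at each time, baseline-
  corrected at t0 via the contrast `a = (1, -1, -1, 1)` on the joint
  4-point posterior — exactly Gaussian, flagged significant where the
  95% interval excludes zero.
- **Hierarchical cross-study model.** Batches share a growth function g
  with per-batch GP deviations:
  `Cov(y_b(x), y_b'(x')) = K_g + 1[b = b'] K_f + nugget`. The batch-
  corrected growth estimate conditions through `K_g + K_f / B`, and the
  interaction test (`hierarchical_bf`) runs on the two-level marginal
  likelihoods with within-batch permutations.
- **Primary-model baselines.** The four classical sigmoid models with
  Levenberg–Marquardt fitting, and a held-out MSE benchmark comparing
  them against the GP with one-sided Welch t-tests.
- **A synthetic-data generator** (`synthetic_spec`, `simulate_dataset`)
  with known ground truth: Gompertz-shaped log2-OD curves, strain /
  stress / interaction effects, post-peak stress declines, smooth batch
  offsets, IID noise. Every statistical claim in the test suite is
  exercised against it.

## Worked example

Simulate a parent/mutant pair at the default study conditions (48-h
experiment, 30-min sampling thinned to a 4-h grid, 12 replicates per
arm, the mutant growing at half the parent's `mu_max`), extract growth
parameters, and test for differential growth:

```r
library(gpgrowth)

sp  <- synthetic_spec(timegrid = seq(0, 47.5, by = 0.5), n_replicates = 12,
                      strain_effect = list(mu_factor = 0.5), noise_sd = 0.05)
tab <- subsample_timepoints(simulate_dataset(sp, seed = 42), 4)
tab
#> growth_table: 288 observations, 24 curve(s), log2 (baseline-normalized) scale
#>   strain: mutant, parent
#>   time: 0 to 44 h (12 distinct points)

growth_parameter_table(tab, restarts = 3, seed = 1)
#>   strain mu_max mu_max_lo mu_max_hi capacity capacity_lo capacity_hi auc_mean
#> 1 parent  0.255     0.246     0.265     2.01        2.00        2.04     70.9
#> 2 mutant  0.147     0.141     0.153     2.00        1.99        2.03     63.5
```

The parent's estimated `mu_max` is 0.255/h against a generative truth of
0.3/h (the 4-h grid smooths the steepest part of the exponential phase);
the mutant's 0.147/h recovers the programmed 50% reduction, while both
strains plateau at the same carrying capacity of about 2 log2 units.

```r
res <- permutation_test(tab, "strain_test", n_perm = 100, seed = 1)
res
#> strain_test: log BF = 277.079, permutation threshold (80%) = 0.141
#>   estimated FDR at real score: 0.000 -> SIGNIFICANT
```

The real log Bayes factor (277) dwarfs the permutation null (80th
percentile 0.14): modeling the two strains separately is overwhelmingly
better supported. Where and how the strains differ comes from the
posterior contrast:

```r
head(as.data.frame(od_delta(res$fit_alt, seq(0, 44, by = 4))), 5)
#>   time   mean variance ci_low ci_high significant
#> 1    0  0.000  0.00000  0.000   0.000       FALSE
#> 2    4  0.022  0.00075 -0.031   0.076       FALSE
#> 3    8 -0.496  0.00077 -0.551  -0.442        TRUE
#> 4   12 -0.714  0.00069 -0.765  -0.663        TRUE
#> 5   16 -0.473  0.00072 -0.525  -0.420        TRUE
```

The mutant falls significantly below the parent during exponential phase
(down 0.71 log2 units at 12 h) and converges again as both reach
stationary phase — exactly the signature of a reduced growth rate with
an unchanged carrying capacity.

A command-line workflow (`simulate`, `fit`, `benchmark`, `test-strain`,
`test-stress`, `test-batch`) is installed at
`system.file("cli", "gpgrowth", package = "gpgrowth")`; it is a thin
wrapper over the functions above, driven by a YAML config.

## The methods vignette

`vignettes/gp-growth-methods.Rmd` documents the model and its
assumptions, every tunable parameter with units and defaults, the
numerical choices (likelihood factorization, optimizer starts, jitter
policy), what the synthetic generator does and does not emulate, and the
package's known limitations.
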