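test_that("primary model curves match their closed-form anchor points", {
  # asymptotes
  expect_equal(gompertz(1e6, 2, 0.3, 5), 2)
  expect_equal(logistic_growth(1e6, 2, 0.3, 5), 2)
  expect_equal(richards(1e6, 2, 0.3, 5, 2.5), 2, tolerance = 1e-9)

  # value at the lag time: the exponent collapses to a constant
  expect_equal(gompertz(5, 3, 0.4, 5), 3 * exp(-exp(1)), tolerance = 1e-12)
  expect_equal(logistic_growth(5, 3, 0.4, 5), 3 / (1 + exp(2)), tolerance = 1e-12)

  # fixed-point evaluation used as the regression fixture
  expect_equal(gompertz(20, 2, 0.3, 5),
               2 * exp(-exp(0.3 * exp(1) / 2 * (5 - 20) + 1)), tolerance = 1e-12)

  # logistic midpoint slope equals mu_max (finite-difference oracle)
  tmid <- optimize(function(t) logistic_growth(t + 1e-4, 1, 0.25, 4) -
                     logistic_growth(t - 1e-4, 1, 0.25, 4),
                   c(0, 20), maximum = TRUE)$maximum
  slope <- (logistic_growth(tmid + 1e-4, 1, 0.25, 4) -
            logistic_growth(tmid - 1e-4, 1, 0.25, 4)) / 2e-4
  expect_equal(slope, 0.25, tolerance = 1e-3)

  # bounded by the asymptote
  tt <- seq(-5, 100, by = 0.5)
  expect_true(all(gompertz(tt, 2, 0.3, 5) <= 2 + 1e-12))
  expect_true(all(logistic_growth(tt, 2, 0.3, 5) <= 2 + 1e-12))
  expect_true(all(richards(tt, 2, 0.3, 5, 0.7) <= 2 + 1e-12))
})

test_that("the Schnute family behaves at its anchor points and limits", {
  # base-one case: t chosen so the exponential term makes the bracket 1,
  # i.e. exp(a*lam + 1 - b - a*t) = 1  =>  t = lam + (1 - b)/a
  a <- 0.3; b <- 0.4; mu <- 0.5; lam <- 4
  t1 <- lam + (1 - b) / a
  expect_equal(schnute(t1, mu, lam, a, b), mu * (1 - b) / a, tolerance = 1e-12)

  # direct evaluation on a grid against an independently coded expression
  tg <- c(8, 12, 20, 30, 45)
  indep <- mu * (1 - b) / a *
    ((1 - b * exp(a * lam + 1 - b - a * tg)) / (1 - b))^(1 / b)
  expect_equal(schnute(tg, mu, lam, a, b), indep, tolerance = 1e-12)

  # b -> 0 limit approaches the Gompertz shape with A = mu*e/a
  A <- 2; mu2 <- 0.3; lam2 <- 5
  a2 <- mu2 * exp(1) / A
  tg2 <- seq(0, 47.5, by = 0.5)
  expect_lt(max(abs(schnute(tg2, mu2, lam2, a2, 1e-6) -
                    gompertz(tg2, A, mu2, lam2))), 1e-3)

  expect_error(schnute(1, 0.3, 5, 0, 0.5), "Gompertz")
  expect_error(schnute(1, 0.3, 5, 0.3, 0), "Gompertz")
  expect_error(schnute(0, 0.3, 5, 0.5, 0.7), "negative")
})

test_that("the Richards family is monotone and nests the logistic at v = 1", {
  tt <- seq(0, 60, by = 0.5)
  for (v in c(0.3, 1, 3, 10)) {
    y <- richards(tt, 2, 0.3, 5, v)
    expect_true(all(diff(y) >= -1e-12), label = paste("v =", v))
  }
  expect_equal(richards(tt, 2, 0.3, 5, 1), logistic_growth(tt, 2, 0.3, 5),
               tolerance = 1e-12)
  expect_error(richards(1, 2, 0.3, 5, -1), "v > 0")
})

test_that("damped least squares recovers parameters and degrades gracefully", {
  tt <- seq(0, 47.5, by = 0.5)
  ctab <- growth_table(data.frame(time = tt, od = gompertz(tt, 2, 0.3, 5),
                                  replicate = "r1"), is_log = TRUE)
  f <- fit_primary("gompertz", ctab)
  expect_true(f$converged)
  expect_lt(max(abs(f$parameters - c(2, 0.3, 5)) / c(2, 0.3, 5)), 0.01)

  # cross-model robustness: gompertz on logistic data converges with
  # small but nonzero error
  ltab <- growth_table(data.frame(time = tt, od = logistic_growth(tt, 2, 0.3, 5),
                                  replicate = "r1"), is_log = TRUE)
  fx <- fit_primary("gompertz", ltab)
  expect_true(fx$converged)
  expect_gt(fx$mse_train, 0)
  expect_lt(fx$mse_train, 0.05)

  # all four families self-recover their own curves closely
  # (Schnute parameters chosen so the bracket stays positive over the grid)
  scurve <- schnute(tt, 0.3, 5, 0.1, 0.2)
  stab <- growth_table(data.frame(time = tt, od = scurve, replicate = "r"),
                       is_log = TRUE)
  fs <- fit_primary("schnute", stab)
  expect_true(fs$converged)
  expect_lt(fs$mse_train / diff(range(scurve))^2, 1e-4)
  rtab <- growth_table(data.frame(time = tt, od = richards(tt, 2, 0.3, 5, 2),
                                  replicate = "r"), is_log = TRUE)
  fr <- fit_primary("richards", rtab)
  expect_true(fr$converged)
  expect_lt(fr$mse_train, 1e-6)

  # a monotone decreasing curve defeats the sigmoid assumption
  dtab <- growth_table(data.frame(time = tt, od = 2 - 0.04 * tt,
                                  replicate = "r"), is_log = TRUE)
  fd <- fit_primary("gompertz", dtab)
  expect_true(!fd$converged || fd$mse_train > 0.05)
})

test_that("mse is plain mean squared error", {
  expect_equal(mse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(mse(c(1, 2), c(1, 2) + 0.5), 0.25)
  expect_equal(mse(c(0, 1, 2), c(0, 0, 0)), 5 / 3)
  expect_error(mse(1:3, 1:2), "length")
})

test_that("held-out benchmark separates regimes and handles degenerate input", {
  # stress-shaped curves: the GP wins against every primary model
  curves <- lapply(1:10, stress_curve)
  bm <- benchmark_models(curves, seed = 7)
  gp_mean <- bm$summary$mean_mse[bm$summary$model == "gp"]
  for (m in c("gompertz", "logistic", "schnute", "richards")) {
    expect_lt(gp_mean, bm$summary$mean_mse[bm$summary$model == m])
  }
  expect_true(all(bm$tests$p_value < 0.05))

  # Gompertz-shaped curves: every model is in the same small-error regime.
  # The Schnute curve is undefined where its bracket goes negative, so an
  # occasional held-out split (e.g. with time 0 held out) is scored as
  # missing rather than infinite; everything that fits scores well.
  gcurves <- lapply(1:6, function(s) single_curve(noise_sd = 0.03,
                                                  seed = 100 + s))
  bm2 <- benchmark_models(gcurves, seed = 7)
  expect_true(all(bm2$summary$n_failed <= 1))
  expect_true(all(bm2$summary$mean_mse < 0.01))
  expect_lt(max(bm2$summary$mean_mse) / min(bm2$summary$mean_mse), 10)

  # reproducibility given the seed
  bm3 <- benchmark_models(curves, seed = 7)
  expect_identical(bm$per_curve$mse_test, bm3$per_curve$mse_test)

  # one curve duplicated: zero between-curve variance, t-test undefined
  dup <- list(curves[[1]], curves[[1]])
  bmd <- benchmark_models(dup, seed = 7)
  expect_true(all(is.na(bmd$tests$p_value)))
})

test_that("Welch tests on parameter estimates behave like t-tests should", {
  g <- c(1.1, 0.9, 1.0, 1.05)
  r <- parameter_ttest(g, g)
  expect_equal(r$t, 0)
  expect_equal(r$p_value, 1)

  # power: clearly separated groups are detected essentially always
  hits <- 0
  for (s in 1:25) {
    set.seed(s)
    a <- rnorm(12, 0, 1); b <- rnorm(12, 3, 1)
    if (parameter_ttest(a, b)$p_value < 0.001) hits <- hits + 1
  }
  expect_gte(hits, 24)

  # antisymmetry
  set.seed(2)
  a <- rnorm(10); b <- rnorm(10, 1)
  expect_equal(parameter_ttest(a, b)$t, -parameter_ttest(b, a)$t)

  expect_error(parameter_ttest(1, c(1, 2)), "at least 2")

  # Bonferroni family-wise control at the 0.25 budget
  adj <- fwer_adjust(c(0.01, 0.04, 0.2), alpha = 0.25)
  expect_equal(adj$p_adjusted, c(0.03, 0.12, 0.6))
  expect_equal(adj$significant, c(TRUE, TRUE, FALSE))
})
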