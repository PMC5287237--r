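test_that("derivative posterior tracks analytic slopes", {
  # linear data: derivative mean equals the slope on the interior
  m <- 0.08
  tt <- seq(0, 40, by = 1)
  tab <- growth_table(data.frame(time = tt, od = m * tt, replicate = "r"),
                      is_log = TRUE)
  fit <- fit_gp(tab, "time", family = "rbf", restarts = 3, seed = 1)
  dp <- derivative_posterior(fit, seq(5, 35, by = 1))
  expect_true(all(abs(dp$mean - m) < 0.05 * m))

  # constant data: derivative mean is zero everywhere
  tabc <- growth_table(data.frame(time = tt, od = rep(1.5, length(tt)),
                                  replicate = "r"), is_log = TRUE)
  fitc <- fit_gp(tabc, "time", family = "rbf", restarts = 3, seed = 1)
  dpc <- derivative_posterior(fitc, seq(0, 40, by = 2))
  expect_true(all(abs(dpc$mean) < 1e-3))

  # unsupported kernel families refuse
  fitl <- fit_gp(tab, "time", family = "matern32", restarts = 2, seed = 1)
  expect_error(derivative_posterior(fitl, tt), "rbf")
})

test_that("derivative posterior matches finite-difference and Monte-Carlo oracles", {
  tab <- single_curve(noise_sd = 0.02, times = seq(0, 47.5, by = 1.5), seed = 5)
  fit <- fit_gp(tab, "time", family = "rbf", restarts = 3, seed = 1)
  tg <- c(4, 10, 16, 24, 36)
  dp <- derivative_posterior(fit, tg)

  # oracle: sample the joint latent posterior at tg +- h, differentiate
  # each sample by central differences
  h <- 0.05
  Xs <- matrix(c(tg - h, tg + h), ncol = 1)
  post <- predict_posterior(fit, Xs)
  n_draw <- 10000
  draws <- sample_posterior(post, n_draw, seed = 99)
  fd <- (draws[, 6:10] - draws[, 1:5]) / (2 * h)
  mc_mean <- colMeans(fd)
  mc_cov <- cov(fd)
  se_mean <- apply(fd, 2, sd) / sqrt(n_draw)
  expect_true(all(abs(dp$mean - mc_mean) <= 3 * se_mean))
  # central-difference check on the posterior mean itself
  pm <- predict_posterior(fit, Xs)$mean
  expect_equal(dp$mean, (pm[6:10] - pm[1:5]) / (2 * h), tolerance = 1e-3)
  # covariance entries within 3 MC standard errors
  se_cov <- sqrt((outer(diag(mc_cov), diag(mc_cov)) + mc_cov^2) / n_draw)
  expect_true(all(abs(dp$cov - mc_cov) <= 3 * se_cov + 1e-12))
})

test_that("maximum growth rate estimates recover the generative truth", {
  tab <- single_curve(A = 2, mu_max = 0.3, lam = 5, noise_sd = 0,
                      times = seq(0, 47.5, by = 0.5), seed = 2)
  fit <- fit_gp(tab, "time", family = "rbf", restarts = 3, seed = 1)
  mu <- estimate_mu_max(fit, n_samples = 2000, seed = 3)
  expect_lt(abs(mu$point - 0.3) / 0.3, 0.10)
  expect_lte(mu$ci[1], mu$point)
  expect_gte(mu$ci[2], mu$point)
  # the pointwise variant agrees on the point estimate
  mu_pw <- estimate_mu_max(fit, ci_method = "pointwise")
  expect_equal(mu_pw$point, mu$point)

  # monotone decreasing curve: the max derivative stays below 0.05
  tt <- seq(0, 40, by = 1)
  tabd <- growth_table(data.frame(time = tt, od = 2 - 0.04 * tt,
                                  replicate = "r"), is_log = TRUE)
  fitd <- fit_gp(tabd, "time", family = "rbf", restarts = 3, seed = 1)
  mud <- estimate_mu_max(fitd, n_samples = 500, seed = 1)
  expect_lt(mud$point, 0.05)

  # flat curve: the estimate is within noise of zero
  set.seed(4)
  tabf <- growth_table(data.frame(time = tt, od = rnorm(length(tt), 0, 0.01),
                                  replicate = "r"), is_log = TRUE)
  fitf <- fit_gp(tabf, "time", family = "rbf", restarts = 3, seed = 1)
  dpf <- derivative_posterior(fitf, seq(0, 40, length.out = 100))
  muf <- estimate_mu_max(fitf, n_samples = 500, seed = 1)
  expect_lt(abs(muf$point), 2 * max(sqrt(pmax(diag(dpf$cov), 0))))
})

test_that("carrying capacity estimates plateau at the right level", {
  tab <- single_curve(A = 2, mu_max = 0.3, lam = 5, noise_sd = 0.02,
                      times = seq(0, 47.5, by = 0.5), seed = 6)
  fit <- fit_gp(tab, "time", family = "rbf", restarts = 3, seed = 1)
  A <- estimate_carrying_capacity(fit, n_samples = 2000, seed = 3)
  expect_gte(A$point, 1.9)
  expect_lte(A$point, 2.1)

  # grid refinement does not move the estimate on smooth fits
  A50 <- estimate_carrying_capacity(fit, tgrid = seq(0, 47.5, length.out = 50),
                                    n_samples = 200, seed = 1)
  A500 <- estimate_carrying_capacity(fit, tgrid = seq(0, 47.5, length.out = 500),
                                     n_samples = 200, seed = 1)
  expect_lt(abs(A50$point - A500$point), 1e-3)

  # all-zero data: estimate within noise of zero
  tt <- seq(0, 40, by = 1)
  tab0 <- growth_table(data.frame(time = tt, od = rep(0, length(tt)),
                                  replicate = "r"), is_log = TRUE)
  fit0 <- fit_gp(tab0, "time", family = "rbf", restarts = 2, seed = 1)
  A0 <- estimate_carrying_capacity(fit0, n_samples = 500, seed = 1)
  expect_lt(abs(A0$point), 0.05)
})

test_that("AUC is an exact Gaussian functional of the posterior", {
  tab <- single_curve(A = 2, mu_max = 0.3, lam = 5, noise_sd = 0.02, seed = 9)
  fit <- fit_gp(tab, "time", family = "rbf", restarts = 3, seed = 1)
  auc <- estimate_auc(fit)
  expect_gt(auc$variance, 0)
  # quadrature oracle: trapezoidal integration of the posterior mean
  grid <- seq(min(tab$time), max(tab$time), length.out = 400)
  pm <- predict_posterior(fit, matrix(grid, ncol = 1))$mean
  trap <- sum(diff(grid) * (head(pm, -1) + tail(pm, -1)) / 2)
  expect_lt(abs(auc$mean - trap) / abs(trap), 0.02)

  # constant posterior mean c over [0, T] integrates to ~ c*T
  tt <- seq(0, 40, by = 1)
  tabc <- growth_table(data.frame(time = tt, od = rep(1.5, length(tt)),
                                  replicate = "r"), is_log = TRUE)
  fitc <- fit_gp(tabc, "time", family = "rbf", restarts = 2, seed = 1)
  aucc <- estimate_auc(fitc, 0, 40)
  expect_equal(aucc$mean, 1.5 * 40, tolerance = 0.05 * 60)

  # zero data: AUC mean near zero, variance still positive
  tab0 <- growth_table(data.frame(time = tt, od = rep(0, length(tt)),
                                  replicate = "r"), is_log = TRUE)
  fit0 <- fit_gp(tab0, "time", family = "rbf", restarts = 2, seed = 1)
  auc0 <- estimate_auc(fit0)
  expect_lt(abs(auc0$mean), 0.5)
  expect_gt(auc0$variance, 0)

  # the variance a' Sigma a is invariant to permuting grid-point order
  post <- predict_posterior(fit, matrix(auc$grid, ncol = 1))
  a <- rep(diff(auc$grid)[1], length(auc$grid))
  set.seed(1)
  o <- sample(length(a))
  expect_equal(as.numeric(a %*% post$cov %*% a),
               as.numeric(a[o] %*% post$cov[o, o] %*% a[o]), tolerance = 1e-10)

  expect_error(estimate_auc(fit, n_points = 1), "at least 2")
})

test_that("growth parameter tables cover every strain-condition group", {
  sp <- synthetic_spec(timegrid = seq(0, 44, by = 4), n_replicates = 3,
                       conditions = c("standard", "stress"),
                       stress_effect = list(mu_factor = 0.7))
  tab <- simulate_dataset(sp, seed = 3)
  params <- growth_parameter_table(tab, restarts = 2, seed = 1, n_samples = 300)
  expect_equal(nrow(params), 4)
  expect_true(all(c("strain", "condition", "mu_max", "capacity",
                    "auc_mean") %in% names(params)))
  expect_true(all(params$mu_max_lo <= params$mu_max &
                  params$mu_max <= params$mu_max_hi))
})
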