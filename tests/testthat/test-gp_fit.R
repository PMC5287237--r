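test_that("log marginal likelihood matches the scalar Gaussian closed form", {
  # n = 1, y = 0, K11 = 1: log N(0; 0, 1) = -log(2*pi)/2
  spc <- kernel_spec("rbf", variance = 1 - 0.1, lengthscales = 1, nugget = 0.1)
  expect_equal(log_marginal_likelihood(matrix(0), 0, spc),
               -0.5 * log(2 * pi), tolerance = 1e-12)
  # all-zero targets: the quadratic form vanishes, leaving -log|2 pi K|/2
  X <- matrix(c(0, 2, 5), ncol = 1)
  spc2 <- kernel_spec("rbf", variance = 1.2, lengthscales = 3, nugget = 0.2)
  K <- kernel_matrix(spc2, X)
  expect_equal(log_marginal_likelihood(X, rep(0, 3), spc2),
               -0.5 * as.numeric(determinant(K)$modulus) - 1.5 * log(2 * pi),
               tolerance = 1e-10)
})

test_that("grouped-replicate likelihood factorization equals the dense computation", {
  set.seed(5)
  for (fam in c("rbf", "ard_rbf", "matern32", "linear")) {
    X <- cbind(rep(c(0, 4, 8, 12), each = 3), rep(c(0, 1, 1), 4))
    y <- rnorm(12)
    obj <- gpgrowth:::make_nll(X, y, fam)
    p <- rnorm(obj$n_par, 0, 0.4)
    spc <- gpgrowth:::params_to_spec(p, fam, 2)
    expect_equal(-obj$nll(p), log_marginal_likelihood(X, y, spc),
                 tolerance = 1e-8, label = fam)
  }
})

test_that("analytic likelihood gradients match finite differences", {
  set.seed(9)
  X <- cbind(rep(c(0, 6, 12, 18), each = 2), rep(c(0, 1), 4))
  y <- rnorm(8)
  for (fam in c("rbf", "ard_rbf", "matern32", "linear")) {
    obj <- gpgrowth:::make_nll(X, y, fam)
    p <- rnorm(obj$n_par, 0, 0.5)
    gn <- vapply(seq_along(p), function(j) {
      e <- replace(rep(0, length(p)), j, 1e-6)
      (obj$nll(p + e) - obj$nll(p - e)) / 2e-6
    }, numeric(1))
    expect_equal(obj$gr(p), gn, tolerance = 1e-5, label = fam)
  }
})

test_that("maximum-likelihood fits recover generative hyperparameters", {
  # noiseless draw from a GP with lengthscale 5 h
  set.seed(13)
  tt <- seq(0, 49, by = 1)
  spc <- kernel_spec("rbf", variance = 1, lengthscales = 5, nugget = 0)
  K <- kernel_matrix(spc, matrix(tt, ncol = 1)) + diag(1e-10, 50)
  y <- as.numeric(crossprod(chol(K), rnorm(50)))
  tab <- growth_table(data.frame(time = tt, od = y, replicate = "r"),
                      is_log = TRUE)
  fit <- fit_gp(tab, "time", family = "rbf", restarts = 5, seed = 1)
  expect_gte(fit$kernel$lengthscales, 2.5)
  expect_lte(fit$kernel$lengthscales, 10)

  # pure IID noise: the nugget absorbs at least 80% of the variance
  # (200 points, so chance autocorrelation cannot masquerade as signal)
  set.seed(14)
  ttn <- seq(0, 199, by = 1)
  tabn <- growth_table(data.frame(time = ttn, od = rnorm(200, 0, 0.5),
                                  replicate = "r"), is_log = TRUE)
  fitn <- fit_gp(tabn, "time", family = "rbf", restarts = 5, seed = 1)
  # on a unit-spaced grid an RBF with sub-spacing lengthscale is
  # observationally identical to white noise, so count it as noise too
  noise_equiv <- fitn$kernel$nugget + fitn$kernel$variance *
    (exp(-1 / fitn$kernel$lengthscales^2) < 0.01)
  expect_gte(noise_equiv / var(tabn$od), 0.8)

  # zero-mean GP fits are scale-equivariant: doubling y doubles the
  # posterior mean at the training inputs after refitting
  tab1 <- single_curve(noise_sd = 0.03, seed = 3)
  fit1 <- fit_gp(tab1, "time", family = "rbf", restarts = 3, seed = 2)
  tab2 <- tab1; tab2$od <- 2 * tab2$od
  fit2 <- fit_gp(tab2, "time", family = "rbf", restarts = 3, seed = 2)
  m1 <- predict_posterior(fit1, matrix(tab1$time, ncol = 1))$mean
  m2 <- predict_posterior(fit2, matrix(tab1$time, ncol = 1))$mean
  expect_equal(m2, 2 * m1, tolerance = 0.02)

  # determinism given the seed
  fit1b <- fit_gp(tab1, "time", family = "rbf", restarts = 3, seed = 2)
  expect_identical(fit1$optim_par, fit1b$optim_par)
})

test_that("posterior conditioning interpolates, reverts to the prior, and matches partitioned-MVN algebra", {
  # near-zero nugget: the posterior mean interpolates the data
  tt <- c(0, 5, 10, 20, 35)
  y <- c(0, 0.3, 1.2, 1.9, 2.0)
  spc <- kernel_spec("rbf", variance = 2, lengthscales = 8, nugget = 1e-9)
  fit <- structure(list(X = matrix(tt, ncol = 1), y = y, design = "time",
                        family = "rbf", kernel = spc,
                        chol = gpgrowth:::chol_jitter(
                          kernel_matrix(spc, matrix(tt, ncol = 1))),
                        log_marginal = 0), class = "gp_fit")
  fit$alpha <- backsolve(fit$chol, forwardsolve(t(fit$chol), y))
  post <- predict_posterior(fit, matrix(tt, ncol = 1))
  expect_equal(post$mean, y, tolerance = 1e-6)

  # far from the data the posterior reverts to the zero-mean prior
  far <- predict_posterior(fit, matrix(500, ncol = 1))
  expect_lt(abs(far$mean), 1e-6)
  expect_equal(far$cov[1, 1], 2, tolerance = 1e-6)

  # brute-force partitioned-MVN conditioning oracle at n <= 6
  set.seed(31)
  X <- matrix(sort(runif(5, 0, 40)), ncol = 1)
  yy <- rnorm(5)
  spc2 <- kernel_spec("rbf", variance = 1.3, lengthscales = 6, nugget = 0.1)
  fit2 <- structure(list(X = X, y = yy, design = "time", family = "rbf",
                         kernel = spc2,
                         chol = gpgrowth:::chol_jitter(kernel_matrix(spc2, X)),
                         log_marginal = 0), class = "gp_fit")
  fit2$alpha <- backsolve(fit2$chol, forwardsolve(t(fit2$chol), yy))
  Xs <- matrix(c(3, 17, 29), ncol = 1)
  post2 <- predict_posterior(fit2, Xs)
  Kxx <- kernel_matrix(spc2, X)
  Ksx <- kernel_matrix(spc2, Xs, X)
  Kss <- kernel_matrix(spc2, Xs, nugget = FALSE)
  expect_equal(post2$mean, as.numeric(Ksx %*% solve(Kxx, yy)), tolerance = 1e-8)
  expect_equal(post2$cov, Kss - Ksx %*% solve(Kxx, t(Ksx)), tolerance = 1e-8)

  # information never hurts: posterior variance <= prior variance
  grid <- matrix(seq(0, 40, by = 1), ncol = 1)
  pv <- diag(predict_posterior(fit2, grid)$cov)
  expect_true(all(pv <= spc2$variance + 1e-8))

  # with noise included the diagonal gains exactly the nugget
  pn <- predict_posterior(fit2, grid, include_noise = TRUE)
  expect_equal(diag(pn$cov) - pv, rep(spc2$nugget, nrow(grid)),
               tolerance = 1e-10)
})

test_that("BIC arithmetic and kernel-complexity ordering are correct", {
  fake <- function(logL, fam, D) {
    structure(list(log_marginal = logL,
                   kernel = kernel_spec(fam,
                     lengthscales = rep(1, if (fam == "ard_rbf") D else 1),
                     linear_variances = if (fam == "linear") rep(1, D)),
                   X = matrix(0, 288, D), y = rep(0, 288)),
              class = "gp_fit")
  }
  expect_equal(bic(fake(-100, "rbf", 1)), 200 + 3 * log(288), tolerance = 1e-9)
  # more hyperparameters at equal likelihood always scores worse
  expect_gt(bic(fake(-100, "ard_rbf", 4)), bic(fake(-100, "rbf", 1)))

  # on growth-curve data, smooth kernels beat the linear kernel
  tab <- single_curve(noise_sd = 0.05, seed = 8)
  b_rbf <- bic(fit_gp(tab, family = "rbf", restarts = 3, seed = 1))
  b_mat <- bic(fit_gp(tab, family = "matern32", restarts = 3, seed = 1))
  b_lin <- bic(fit_gp(tab, family = "linear", restarts = 3, seed = 1))
  expect_lt(b_rbf, b_lin)
  expect_lt(b_mat, b_lin)
})

test_that("fitted models survive a serialization round trip", {
  tab <- single_curve(noise_sd = 0.03, seed = 12)
  fit <- fit_gp(tab, "time", family = "rbf", restarts = 2, seed = 1)
  path <- withr::local_tempfile(fileext = ".json")
  write_gp_fit(fit, path)
  back <- read_gp_fit(path)
  grid <- matrix(seq(0, 47, by = 5), ncol = 1)
  expect_equal(predict_posterior(back, grid)$mean,
               predict_posterior(fit, grid)$mean, tolerance = 1e-8)
  expect_equal(back$log_marginal, fit$log_marginal)
})
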