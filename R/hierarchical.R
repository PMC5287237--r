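#' Hierarchical GP over batches of growth experiments
#'
#' Cross-study (batch) variation is modeled with a two-level GP: a shared
#' growth function \eqn{g \sim GP(0, K_g)} and per-batch deviations
#' \eqn{f_b \sim GP(g, K_f)}.  Marginalizing g and the deviations, the
#' observations are jointly Gaussian with covariance
#' \deqn{Cov(y_b(x), y_{b'}(x')) = K_g(x, x') + 1[b = b'] K_f(x, x') +
#'   \sigma^2_{nugget} 1[\mathrm{same\ obs}],}
#' an exact finite-batch formulation of the hierarchical model.  Both
#' levels use ARD squared-exponential kernels over the same covariate
#' design; all hyperparameters (shared variance and lengthscales, batch
#' variance and lengthscales, nugget) are set by maximizing the joint
#' marginal likelihood.
#'
#' @param table a log-transformed growth table with a \code{batch}
#'   column.  With a single batch the model falls back to a plain
#'   \code{\link{fit_gp}} with a warning.
#' @param design design columns, see \code{\link{encode_design}}.
#' @param restarts,seed,maxit optimizer settings.
#' @param parent,control reference levels.
#' @return object of class \code{hgp_fit}: training arrays, batch index,
#'   shared/batch \code{kernel_spec}s, nugget, log marginal likelihood
#'   and the cached decomposition.
#' @export
hierarchical_fit <- function(table, design = c("time", "strain", "stress",
                                               "interaction"),
                             restarts = 5, seed = 1L, maxit = 300,
                             parent = NULL, control = NULL) {
  stopifnot(inherits(table, "growth_table"))
  if (!is_log(table)) stop("hierarchical_fit expects log-transformed data",
                           call. = FALSE)
  if (!"batch" %in% names(table) || length(unique(table$batch)) < 2) {
    warning("fewer than 2 batches; falling back to a plain GP fit")
    return(fit_gp(table, design, family = "ard_rbf", restarts = restarts,
                  seed = seed, parent = parent, control = control))
  }
  X <- encode_design(table, design, parent, control)
  y <- as.numeric(table$od)
  b <- match(table$batch, sort(unique(table$batch)))
  fit <- fit_hgp_xy(X, y, b, restarts = restarts, seed = seed, maxit = maxit)
  fit$design <- colnames(X)
  fit$batch_levels <- sort(unique(table$batch))
  fit
}

# Negative joint marginal likelihood of the two-level kernel, using the
# same grouped (unique-row) factorization as the flat GP; a "row" here is
# the pair (design row, batch).  Parameters:
# log sg2, log lg (D), log sf2, log lf (D), log nugget.
make_nll_hier <- function(X, y, b) {
  X <- as_row(X)
  n <- nrow(X); D <- ncol(X)
  key <- paste(apply(X, 1, paste, collapse = "\r"), b, sep = "\r")
  uk <- !duplicated(key)
  Xu <- X[uk, , drop = FALSE]
  bu <- b[uk]
  idx <- match(key, key[uk])
  U <- nrow(Xu)
  d <- as.numeric(tabulate(idx, U))
  s <- as.numeric(rowsum(y, idx))
  yty <- sum(y^2)
  D2 <- lapply(seq_len(D), function(k) outer(Xu[, k], Xu[, k], "-")^2)
  same_batch <- outer(bu, bu, "==") * 1

  parts <- function(p) {
    Eg <- matrix(0, U, U); Ef <- matrix(0, U, U)
    for (k in seq_len(D)) {
      Eg <- Eg + D2[[k]] / exp(2 * p[1 + k])
      Ef <- Ef + D2[[k]] / exp(2 * p[D + 2 + k])
    }
    Kg <- exp(p[1]) * exp(-Eg)
    Kf <- same_batch * (exp(p[D + 2]) * exp(-Ef))
    list(Kg = Kg, Kf = Kf)
  }
  cache <- new.env(parent = emptyenv())
  compute <- function(p) {
    if (!is.null(cache$p) && identical(cache$p, p)) return(cache$res)
    s2 <- exp(p[length(p)])
    pr <- parts(p)
    Ku <- pr$Kg + pr$Kf
    aux <- lml_grouped(Ku, s2, n, d, s, yty, aux = TRUE)
    res <- if (!is.list(aux)) NULL else
      list(Ku = Ku, Kg = pr$Kg, Kf = pr$Kf, s2 = s2, aux = aux)
    cache$p <- p; cache$res <- res
    res
  }
  list(
    D = D, n = n, n_par = 2L * D + 3L,
    ku_fun = function(p) { pr <- parts(p); pr$Kg + pr$Kf },
    nll = function(p) {
      res <- compute(p)
      if (is.null(res) || !is.finite(res$aux$value)) 1e10 else -res$aux$value
    },
    gr = function(p) {
      res <- compute(p)
      if (is.null(res) || !is.finite(res$aux$value)) return(rep(0, length(p)))
      g <- numeric(length(p))
      g[1] <- grad_kernel_term(res$aux, res$Kg)
      for (k in seq_len(D)) {
        g[1 + k] <- grad_kernel_term(res$aux,
                                     res$Kg * (2 * D2[[k]] / exp(2 * p[1 + k])))
        g[D + 2 + k] <- grad_kernel_term(res$aux,
                                         res$Kf * (2 * D2[[k]] / exp(2 * p[D + 2 + k])))
      }
      g[D + 2] <- grad_kernel_term(res$aux, res$Kf)
      g[length(p)] <- grad_nugget_term(res$aux, res$Ku, res$s2, n, d, s, yty) *
        res$s2
      -g
    })
}

fit_hgp_xy <- function(X, y, b, restarts = 5, seed = 1L, maxit = 300,
                       start = NULL) {
  X <- as_row(X)
  obj <- make_nll_hier(X, y, b)
  D <- obj$D
  vy <- max(stats::var(y), 1e-4)
  l0 <- apply(X, 2, function(col) {
    span <- diff(range(col)); if (span <= 0) 1 else max(span / 4, 0.05)
  })
  p0 <- log(c(vy, l0, 0.25 * vy, 2 * l0, 0.1 * vy))
  # "split" start: covariate (arm) structure in the shared kernel with
  # short lengthscales, smooth trend + study offsets in the batch kernel
  # with the covariates switched off -- the decomposition a hierarchical
  # growth model is meant to find
  spans <- apply(X, 2, function(col) diff(range(col)))
  lg <- ifelse(spans > 2, spans / 4, 0.7)
  lf <- ifelse(spans > 2, spans / 2, 999)
  p_split <- log(c(0.25 * vy, lg, vy, lf, 0.01 * vy))
  lb <- log(c(1e-8, rep(1e-2, D), 1e-8, rep(1e-2, D), 1e-8))
  ub <- log(c(1e4, rep(1e3, D), 1e4, rep(1e3, D), 1e2))
  clamp <- function(p) pmin(pmax(p, lb + 1e-9), ub - 1e-9)
  explicit <- if (is.null(start)) list() else
    if (is.list(start)) start else list(start)
  starts <- c(list(clamp(p0), clamp(p_split)), lapply(explicit, clamp))
  if (restarts > 1) {
    with_seed(seed, for (i in seq_len(restarts - 1)) {
      starts[[length(starts) + 1]] <-
        clamp(p0 + stats::runif(length(p0), -1.5, 1.5))
    })
  }
  best <- NULL
  for (p in starts) {
    res <- tryCatch(
      stats::optim(p, obj$nll, gr = obj$gr, method = "L-BFGS-B",
                   lower = lb, upper = ub,
                   control = list(maxit = maxit, factr = 1e7)),
      error = function(e) NULL)
    if (!is.null(res) && is.finite(res$value) &&
        (is.null(best) || res$value < best$value)) best <- res
  }
  if (is.null(best))
    stop("hierarchical GP optimization failed on all restarts", call. = FALSE)
  p <- best$par
  spec_g <- kernel_spec("ard_rbf", variance = exp(p[1]),
                        lengthscales = exp(p[2:(D + 1)]), nugget = 0)
  spec_f <- kernel_spec("ard_rbf", variance = exp(p[D + 2]),
                        lengthscales = exp(p[(D + 3):(2 * D + 2)]), nugget = 0)
  nug <- exp(p[length(p)])
  Kg <- kernel_matrix(spec_g, X, nugget = FALSE)
  Kf <- kernel_matrix(spec_f, X, nugget = FALSE)
  SB <- outer(b, b, "==") * 1
  K <- Kg + SB * Kf + diag(nug, length(y))
  R <- chol_jitter(K)
  alpha <- backsolve(R, forwardsolve(t(R), y))
  structure(list(
    X = X, y = y, batch = b, design = colnames(X),
    kernel_shared = spec_g, kernel_batch = spec_f, nugget = nug,
    log_marginal = -best$value, chol = R, alpha = alpha,
    optim_par = p, convergence = best$convergence
  ), class = "hgp_fit")
}

#' @export
print.hgp_fit <- function(x, ...) {
  cat(sprintf("hgp_fit: %d observations in %d batches, design {%s}\n",
              length(x$y), length(unique(x$batch)),
              paste(x$design, collapse = ", ")))
  cat(sprintf("  log marginal likelihood: %.4f\n", x$log_marginal))
  cat("shared kernel:\n"); print(x$kernel_shared)
  cat("batch-deviation kernel:\n"); print(x$kernel_batch)
  invisible(x)
}

#' Posterior of the shared (batch-corrected) growth function
#'
#' Returns the posterior of the study-effect-corrected growth function.
#' With a finite number of observed batches the natural batch-corrected
#' estimand is the across-batch mean function \eqn{g + B^{-1}\sum_b d_b}
#' (shared function plus the average of the batch deviations), obtained
#' exactly by conditioning through the covariance \eqn{K_g + K_f/B}.
#' Unlike conditioning through \eqn{K_g} alone, this estimand is
#' invariant to the well-known non-identifiability of the two-level
#' variance split when only a few batches are observed (the marginal
#' likelihood cannot distinguish signal carried by g from signal
#' duplicated in every \eqn{f_b}); deviations with zero cross-batch mean
#' -- such as opposite study offsets -- cancel from it.  Set
#' \code{estimand = "latent"} for the pure \eqn{K_g} conditioning on the
#' latent g itself.
#'
#' @param model an \code{hgp_fit}.
#' @param Xstar query design matrix.
#' @param estimand \code{"consensus"} (across-batch mean function,
#'   default) or \code{"latent"} (conditioning through K_g only).
#' @return a \code{posterior_mvn} over the corrected growth function at
#'   \code{Xstar}.
#' @export
predict_shared <- function(model, Xstar, estimand = c("consensus", "latent")) {
  estimand <- match.arg(estimand)
  stopifnot(inherits(model, "hgp_fit"))
  if (!is.matrix(Xstar)) Xstar <- matrix(as.numeric(Xstar), ncol = 1)
  B <- length(unique(model$batch))
  wf <- if (estimand == "consensus") 1 / B else 0
  Ks <- kernel_matrix(model$kernel_shared, Xstar, model$X) +
    wf * kernel_matrix(model$kernel_batch, Xstar, model$X)
  Kss <- kernel_matrix(model$kernel_shared, Xstar, nugget = FALSE) +
    wf * kernel_matrix(model$kernel_batch, Xstar, nugget = FALSE)
  mu <- as.numeric(Ks %*% model$alpha)
  V <- forwardsolve(t(model$chol), t(Ks))
  S <- Kss - crossprod(V); S <- (S + t(S)) / 2
  structure(list(locations = Xstar, mean = mu, cov = S,
                 includes_noise = FALSE), class = "posterior_mvn")
}

#' Posterior of one batch's growth function (shared + deviation)
#'
#' @param model an \code{hgp_fit}.
#' @param Xstar query design matrix.
#' @param batch batch label or index.
#' @return a \code{posterior_mvn} over \eqn{f_b = g + } deviation.
#' @export
predict_batch <- function(model, Xstar, batch) {
  stopifnot(inherits(model, "hgp_fit"))
  if (!is.matrix(Xstar)) Xstar <- matrix(as.numeric(Xstar), ncol = 1)
  bidx <- if (is.numeric(batch)) batch else match(batch, model$batch_levels)
  if (is.na(bidx)) stop("unknown batch '", batch, "'", call. = FALSE)
  same <- matrix(as.numeric(model$batch == bidx), nrow(Xstar),
                 length(model$batch), byrow = TRUE)
  Ks <- kernel_matrix(model$kernel_shared, Xstar, model$X) +
    same * kernel_matrix(model$kernel_batch, Xstar, model$X)
  Kss <- kernel_matrix(model$kernel_shared, Xstar, nugget = FALSE) +
    kernel_matrix(model$kernel_batch, Xstar, nugget = FALSE)
  mu <- as.numeric(Ks %*% model$alpha)
  V <- forwardsolve(t(model$chol), t(Ks))
  S <- Kss - crossprod(V); S <- (S + t(S)) / 2
  structure(list(locations = Xstar, mean = mu, cov = S,
                 includes_noise = FALSE), class = "posterior_mvn")
}

#' Hierarchical Bayes-factor test for a stress interaction across batches
#'
#' The cross-study analogue of the stress test: both the null
#' \{time, strain, stress\} and alternative \{time, strain, stress,
#' interaction\} designs are fitted with the hierarchical two-level
#' kernel, and the permutation null shuffles strain labels within each
#' (batch, stress arm, time point) cell.
#'
#' @inheritParams permutation_test
#' @return a \code{bf_test} (with the two \code{hgp_fit}s attached).
#' @export
hierarchical_bf <- function(table, n_perm = 100, seed = 1L, restarts = 5,
                            maxit = 300, fdr_percentile = 0.80,
                            parent = NULL, control = NULL) {
  stopifnot(inherits(table, "growth_table"))
  if (n_perm < 5)
    stop("n_perm < 5 gives an uninformative permutation null; refusing",
         call. = FALSE)
  if (!"batch" %in% names(table) || length(unique(table$batch)) < 2) {
    warning("fewer than 2 batches; using the plain (pooled) stress test")
    return(permutation_test(table, "stress_test", n_perm = n_perm, seed = seed,
                            restarts = restarts, maxit = maxit,
                            fdr_percentile = fdr_percentile,
                            parent = parent, control = control))
  }
  des <- build_design(table, "stress_test", parent, control)
  y <- as.numeric(table$od)
  b <- match(table$batch, sort(unique(table$batch)))
  fit0 <- fit_hgp_xy(encode_design(table, des$null, parent, control), y, b,
                     restarts = restarts, seed = seed, maxit = maxit)
  fit1 <- fit_hgp_xy(encode_design(table, des$alt, parent, control), y, b,
                     restarts = restarts, seed = seed, maxit = maxit,
                     start = hier_alt_start(fit0$optim_par, length(des$null)))
  real <- fit1$log_marginal - fit0$log_marginal
  tb <- table
  tb$.arm <- paste(table$batch, table$condition)
  perm_seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L, n_perm))
  perm <- vapply(seq_len(n_perm), function(i) {
    ptab <- permute_strain_labels(tb, "strain", seed = perm_seeds[i],
                                  within = ".arm")
    p0 <- fit_hgp_warm(ptab, des$null, y, b, fit0$optim_par, maxit,
                       parent, control)
    p1 <- fit_hgp_warm(ptab, des$alt, y, b,
                       c(list(fit1$optim_par),
                         hier_alt_start(p0$par, length(des$null))),
                       maxit, parent, control)
    p1$lml - p0$lml
  }, numeric(1))
  thr <- sort(perm)[ceiling(fdr_percentile * n_perm)]
  structure(list(
    which = "batch_test", log_bf = real, perm_log_bfs = perm, threshold = thr,
    fdr = sum(perm > real) / n_perm, significant = real > thr,
    n_perm = n_perm, fdr_percentile = fdr_percentile, seed = seed,
    fit_alt = fit1, fit_null = fit0
  ), class = "bf_test")
}

# Warm-started hierarchical refit(s); returns the best log marginal and
# the parameters achieving it.  `start`: vector or list of vectors.
fit_hgp_warm <- function(ptab, design, y, b, start, maxit, parent, control) {
  X <- encode_design(ptab, design, parent, control)
  obj <- make_nll_hier(X, y, b)
  D <- obj$D
  lb <- log(c(1e-8, rep(1e-2, D), 1e-8, rep(1e-2, D), 1e-8))
  ub <- log(c(1e4, rep(1e3, D), 1e4, rep(1e3, D), 1e2))
  starts <- if (is.list(start)) start else list(start)
  best <- NULL
  for (p in starts) {
    p <- pmin(pmax(p, lb + 1e-9), ub - 1e-9)
    res <- tryCatch(
      stats::optim(p, obj$nll, gr = obj$gr, method = "L-BFGS-B",
                   lower = lb, upper = ub,
                   control = list(maxit = maxit, factr = 1e7)),
      error = function(e) list(value = obj$nll(p), par = p))
    if (is.null(best) || res$value < best$value) best <- res
  }
  list(lml = -best$value, par = best$par)
}

# Alternative-design start derived from a fitted null: the added
# covariate's lengthscale enters at (near) its upper bound in both the
# shared and the batch kernel, reproducing the null fit.
hier_alt_start <- function(null_par, D0, n_add = 1L) {
  mk <- function(lg, lf) {
    c(null_par[1:(1 + D0)], rep(log(lg), n_add),
      null_par[(D0 + 2):(2 * D0 + 2)], rep(log(lf), n_add),
      null_par[length(null_par)])
  }
  # the added covariate switched off, active at both levels, active in the
  # shared kernel only, and active in the batch kernel only
  list(off = mk(999, 999), on = mk(0.5, 0.5),
       on_g = mk(0.5, 999), on_f = mk(999, 0.5))
}
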