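#' Encode growth-table covariates as a GP input matrix
#'
#' Builds the numeric design matrix fed to the kernel.  Columns are taken
#' in the requested order from:
#' \describe{
#'   \item{time}{hours, unscaled.}
#'   \item{strain}{0 = parent/reference strain, 1 = mutant.  Requires
#'     exactly two strain levels.}
#'   \item{stress}{0 = control condition, 1 = stress, from the
#'     \code{condition} column.}
#'   \item{interaction}{elementwise product strain * stress; always
#'     recomputed, never read from the input.}
#' }
#'
#' @param table a growth table.
#' @param design character vector of column names from
#'   \code{c("time","strain","stress","interaction")}; time must come
#'   first.
#' @param parent strain label encoded as 0; defaults to \code{"parent"}
#'   when present, otherwise the alphabetically first level.
#' @param control condition label encoded as 0; defaults to
#'   \code{"standard"} when present, otherwise the alphabetically first
#'   level.
#' @return numeric matrix with one row per observation and named columns.
#' @export
encode_design <- function(table, design = "time", parent = NULL, control = NULL) {
  design <- match.arg(design, c("time", "strain", "stress", "interaction"),
                      several.ok = TRUE)
  if (design[1] != "time") stop("'time' must be the first design column", call. = FALSE)
  n <- nrow(table)
  cols <- list(time = as.numeric(table$time))
  if (any(c("strain", "interaction") %in% design)) {
    if (!"strain" %in% names(table))
      stop("design needs a 'strain' column in the table", call. = FALSE)
    lev <- sort(unique(table$strain))
    if (length(lev) != 2)
      stop(sprintf("strain must have exactly 2 levels for pairwise tests (found %d)",
                   length(lev)), call. = FALSE)
    if (is.null(parent)) parent <- if ("parent" %in% lev) "parent" else lev[1]
    if (!parent %in% lev) stop("parent level '", parent, "' not found", call. = FALSE)
    cols$strain <- as.numeric(table$strain != parent)
  }
  if (any(c("stress", "interaction") %in% design)) {
    if (!"condition" %in% names(table))
      stop("design needs a 'condition' column in the table", call. = FALSE)
    lev <- sort(unique(table$condition))
    if (length(lev) > 2)
      stop("condition must have at most 2 levels", call. = FALSE)
    if (is.null(control)) control <- if ("standard" %in% lev) "standard" else lev[1]
    cols$stress <- as.numeric(table$condition != control)
  }
  if ("interaction" %in% design) cols$interaction <- cols$strain * cols$stress
  X <- do.call(cbind, cols[design])
  colnames(X) <- design
  X
}

# ---------------------------------------------------------------------------
# Marginal likelihood

chol_jitter <- function(K, jitters = c(0, 1e-10, 1e-8, 1e-6, 1e-4)) {
  scale <- mean(diag(K))
  if (!is.finite(scale) || scale <= 0) scale <- 1
  for (j in jitters) {
    R <- tryCatch(chol(K + diag(j * scale, nrow(K))), error = function(e) NULL)
    if (!is.null(R)) return(R)
  }
  ev <- min(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  stop(sprintf(
    "covariance matrix not positive definite after jitter escalation (min eigenvalue %.3e)",
    ev), call. = FALSE)
}

# Dense log N(y; 0, K(X,X) + nugget I).
lml_dense <- function(X, y, spec) {
  K <- kernel_matrix(spec, X, nugget = TRUE)
  R <- chol_jitter(K)
  a <- backsolve(R, forwardsolve(t(R), y))
  -0.5 * sum(y * a) - sum(log(diag(R))) - 0.5 * length(y) * log(2 * pi)
}

# Exact log marginal likelihood exploiting replicated design rows.
# With A the n x U indicator of unique rows, K = A K_u A' + s2 I, and
# (matrix determinant lemma / Woodbury):
#   log|K|   = (n-U) log s2 + log|s2 I + D^{1/2} K_u D^{1/2}|,  D = A'A
#   y'K^{-1}y = (y'y - s' K_u D^{1/2} B^{-1} D^{-1/2} s)/s2,     s = A'y,
# with B = s2 I + D^{1/2} K_u D^{1/2}.  Exact for nugget s2 > 0.
lml_grouped <- function(Ku, s2, n, d, s, yty, aux = FALSE) {
  U <- nrow(Ku)
  sq <- sqrt(d)
  B <- s2 * diag(U) + Ku * tcrossprod(sq)
  R <- tryCatch(chol((B + t(B)) / 2), error = function(e) NULL)
  if (is.null(R)) return(NA_real_)
  w <- backsolve(R, forwardsolve(t(R), s / sq))
  quad <- (yty - sum(s * (Ku %*% (sq * w)))) / s2
  logdet <- (n - U) * log(s2) + 2 * sum(log(diag(R)))
  val <- -0.5 * (quad + logdet + n * log(2 * pi))
  if (!aux) return(val)
  # quantities for the analytic gradient:
  #   a_u = A' K^{-1} y = D^{1/2} B^{-1} D^{-1/2} s
  #   W   = A' K^{-1} A = D^{1/2} B^{-1} D^{1/2}
  Binv <- chol2inv(R)
  a_u <- sq * (Binv %*% (s / sq))
  W <- Binv * tcrossprod(sq)
  list(value = val, a_u = as.numeric(a_u), W = W, sq = sq)
}

# Gradient of lml_grouped w.r.t. a kernel parameter with dK = A dKu A':
#   d lml = 1/2 a_u' dKu a_u - 1/2 tr(W dKu)
grad_kernel_term <- function(aux, dKu) {
  0.5 * sum(aux$a_u * (dKu %*% aux$a_u)) - 0.5 * sum(aux$W * dKu)
}

# Gradient w.r.t. the nugget s2 (dK = I):
#   d lml = 1/2 alpha'alpha - 1/2 tr(K^{-1}),
# expressed through grouped quantities.
grad_nugget_term <- function(aux, Ku, s2, n, d, s, yty) {
  h <- as.numeric(Ku %*% aux$a_u)
  aa <- (yty - 2 * sum(s * h) + sum(d * h^2)) / s2^2
  trKinv <- (n - sum(Ku * t(aux$W))) / s2
  0.5 * aa - 0.5 * trKinv
}

#' Log marginal likelihood of growth observations under a GP prior
#'
#' Computes \eqn{\log N(y; 0, K(X,X) + \sigma^2_{nugget} I)}, the
#' probability of the data with the latent growth function integrated out;
#' the zero prior mean is a fixed modeling choice.
#'
#' @param X input matrix (rows = observations).
#' @param y numeric vector of log2-OD values.
#' @param spec a \code{kernel_spec}.
#' @return scalar log marginal likelihood.
#' @export
log_marginal_likelihood <- function(X, y, spec) {
  X <- as_row(X)
  stopifnot(length(y) == nrow(X), length(y) >= 1)
  lml_dense(X, y, spec)
}

# ---------------------------------------------------------------------------
# Hyperparameter optimization

# Precompute sufficient statistics and return function(log-params) -> -lml.
# The grouped path makes each evaluation O(U^3) in the number of distinct
# input rows, so 100-permutation Bayes-factor tests stay cheap.
make_nll <- function(X, y, family) {
  X <- as_row(X)
  n <- nrow(X); D <- ncol(X)
  key <- apply(X, 1, paste, collapse = "\r")
  uk <- !duplicated(key)
  Xu <- X[uk, , drop = FALSE]
  idx <- match(key, key[uk])
  U <- nrow(Xu)
  d <- as.numeric(tabulate(idx, U))
  s <- as.numeric(rowsum(y, idx))
  yty <- sum(y^2)
  # per-dimension squared distances between unique rows
  D2 <- lapply(seq_len(D), function(k) outer(Xu[, k], Xu[, k], "-")^2)
  D2tot <- Reduce("+", D2)
  XtX <- if (family == "linear") {
    lapply(seq_len(D), function(k) tcrossprod(Xu[, k]))
  } else NULL

  ku_fun <- switch(family,
    rbf = function(p) exp(p[1]) * exp(-D2tot / exp(2 * p[2])),
    ard_rbf = function(p) {
      E <- matrix(0, U, U)
      for (k in seq_len(D)) E <- E + D2[[k]] / exp(2 * p[1 + k])
      exp(p[1]) * exp(-E)
    },
    matern32 = function(p) {
      r <- sqrt(D2tot) / exp(p[2])
      exp(p[1]) * (1 + sqrt(3) * r) * exp(-sqrt(3) * r)
    },
    linear = function(p) {
      K <- matrix(0, U, U)
      for (k in seq_len(D)) K <- K + exp(p[k]) * XtX[[k]]
      K
    })
  # list of dKu/d(log param_j) for the kernel parameters, given p and Ku
  dku_fun <- switch(family,
    rbf = function(p, Ku) list(Ku, Ku * (2 * D2tot / exp(2 * p[2]))),
    ard_rbf = function(p, Ku) {
      c(list(Ku),
        lapply(seq_len(D), function(k) Ku * (2 * D2[[k]] / exp(2 * p[1 + k]))))
    },
    matern32 = function(p, Ku) {
      r <- sqrt(D2tot) / exp(p[2])
      list(Ku, 3 * exp(p[1]) * r^2 * exp(-sqrt(3) * r))
    },
    linear = function(p, Ku) {
      lapply(seq_len(D), function(k) exp(p[k]) * XtX[[k]])
    })
  n_kern <- switch(family, rbf = 2L, matern32 = 2L,
                   ard_rbf = D + 1L, linear = D)

  # memoize the per-point decomposition so fn and gr share one Cholesky
  cache <- new.env(parent = emptyenv())
  compute <- function(p) {
    if (!is.null(cache$p) && identical(cache$p, p)) return(cache$res)
    s2 <- exp(p[length(p)])
    Ku <- ku_fun(p)
    aux <- lml_grouped(Ku, s2, n, d, s, yty, aux = TRUE)
    res <- if (!is.list(aux)) NULL else list(Ku = Ku, s2 = s2, aux = aux)
    cache$p <- p; cache$res <- res
    res
  }
  list(
    n_kern = n_kern, n_par = n_kern + 1L, D = D, n = n,
    nll = function(p) {
      res <- compute(p)
      if (is.null(res) || !is.finite(res$aux$value)) 1e10 else -res$aux$value
    },
    gr = function(p) {
      res <- compute(p)
      if (is.null(res) || !is.finite(res$aux$value)) return(rep(0, length(p)))
      dks <- dku_fun(p, res$Ku)
      g <- vapply(dks, function(dk) grad_kernel_term(res$aux, dk), numeric(1))
      gnug <- grad_nugget_term(res$aux, res$Ku, res$s2, n, d, s, yty) * res$s2
      -c(g, gnug)
    })
}

param_bounds <- function(family, D, lengthscale_bounds = c(1e-2, 1e3)) {
  lv <- log(c(1e-8, 1e4))           # signal variance
  ll <- log(lengthscale_bounds)     # lengthscales
  ln <- log(c(1e-8, 1e2))           # nugget
  switch(family,
    rbf = ,
    matern32 = list(lower = c(lv[1], ll[1], ln[1]), upper = c(lv[2], ll[2], ln[2])),
    ard_rbf = list(lower = c(lv[1], rep(ll[1], D), ln[1]),
                   upper = c(lv[2], rep(ll[2], D), ln[2])),
    linear = list(lower = c(rep(lv[1], D), ln[1]),
                  upper = c(rep(lv[2], D), ln[2])))
}

init_params <- function(family, X, y) {
  vy <- max(stats::var(y), 1e-4)
  l0 <- apply(X, 2, function(col) {
    span <- diff(range(col))
    if (span <= 0) 1 else max(span / 4, 0.05)
  })
  switch(family,
    rbf = ,
    matern32 = log(c(vy, l0[1], 0.1 * vy)),
    ard_rbf = log(c(vy, l0, 0.1 * vy)),
    linear = {
      msq <- apply(X, 2, function(col) max(mean(col^2), 1e-6))
      log(c(vy / msq, 0.1 * vy))
    })
}

#' Fit a GP regression model to growth data
#'
#' Maximizes the log marginal likelihood over the kernel hyperparameters
#' (signal variance, lengthscales, nugget) with a log-parameterized
#' quasi-Newton search, keeping the best of several seeded random restarts.
#' Lengthscales are bounded to [1e-2, 1e3] input units.
#'
#' @param table a log-transformed growth table (\code{is_log = TRUE}).
#' @param design design columns, see \code{\link{encode_design}}.
#' @param family kernel family (default \code{"rbf"} for 1-D designs and
#'   \code{"ard_rbf"} otherwise).
#' @param spec0 optional \code{kernel_spec} supplying the starting point.
#' @param restarts number of optimizer starts (first at the heuristic or
#'   supplied initialization, the rest randomly perturbed).
#' @param seed integer seed controlling the restarts.
#' @param parent,control reference levels, see \code{\link{encode_design}}.
#' @param maxit optimizer iteration cap per start.
#' @return object of class \code{gp_fit}: the training arrays, optimized
#'   \code{kernel_spec}, log marginal likelihood, and the cached Cholesky
#'   factor used for prediction.
#' @export
fit_gp <- function(table, design = "time", family = NULL, spec0 = NULL,
                   restarts = 5, seed = 1L, parent = NULL, control = NULL,
                   maxit = 200) {
  stopifnot(inherits(table, "growth_table"))
  if (!is_log(table))
    stop("fit_gp expects log-transformed data; run log_baseline_normalize() first",
         call. = FALSE)
  X <- encode_design(table, design, parent = parent, control = control)
  y <- as.numeric(table$od)
  if (is.null(family)) family <- if (ncol(X) > 1) "ard_rbf" else "rbf"
  fit <- fit_gp_xy(X, y, family, spec0 = spec0, restarts = restarts,
                   seed = seed, maxit = maxit)
  fit$design <- colnames(X)
  fit$parent <- parent
  fit$control <- control
  fit
}

# Core fitter on raw arrays (also used by the difftest permutation loop).
# `start` may be a single parameter vector or a list of vectors; every
# supplied start is tried (in addition to `restarts` - 1 random
# perturbations of the first).
fit_gp_xy <- function(X, y, family, spec0 = NULL, restarts = 5, seed = 1L,
                      maxit = 200, start = NULL) {
  X <- as_row(X)
  obj <- make_nll(X, y, family)
  b <- param_bounds(family, obj$D)
  clamp <- function(p) pmin(pmax(p, b$lower + 1e-9), b$upper - 1e-9)
  explicit <- if (is.null(start)) list() else
    if (is.list(start)) start else list(start)
  p0 <- if (length(explicit) > 0) explicit[[1]] else if (!is.null(spec0)) {
    spec_to_params(spec0, obj$D)
  } else init_params(family, X, y)
  p0 <- clamp(p0)
  starts <- c(list(p0), lapply(explicit[-1], clamp))
  if (restarts > 1) {
    with_seed(seed, {
      for (i in seq_len(restarts - 1)) {
        starts[[length(starts) + 1]] <-
          clamp(p0 + stats::runif(length(p0), -1.5, 1.5))
      }
    })
  }
  best <- NULL
  for (p in starts) {
    res <- tryCatch(
      stats::optim(p, obj$nll, gr = obj$gr, method = "L-BFGS-B",
                   lower = b$lower, upper = b$upper,
                   control = list(maxit = maxit, factr = 1e7)),
      error = function(e) NULL)
    if (!is.null(res) && is.finite(res$value) &&
        (is.null(best) || res$value < best$value)) best <- res
  }
  if (is.null(best))
    stop("GP hyperparameter optimization failed on all restarts", call. = FALSE)
  spec <- params_to_spec(best$par, family, obj$D)
  K <- kernel_matrix(spec, X, nugget = TRUE)
  R <- chol_jitter(K)
  alpha <- backsolve(R, forwardsolve(t(R), y))
  structure(list(
    X = X, y = y, design = colnames(X), family = family, kernel = spec,
    log_marginal = -best$value, chol = R, alpha = alpha,
    optim_par = best$par, convergence = best$convergence
  ), class = "gp_fit")
}

spec_to_params <- function(spec, D) {
  switch(spec$family,
    rbf = ,
    matern32 = log(c(spec$variance, spec$lengthscales[1], max(spec$nugget, 1e-8))),
    ard_rbf = log(c(spec$variance, rep_len(spec$lengthscales, D),
                    max(spec$nugget, 1e-8))),
    linear = log(c(rep_len(spec$linear_variances, D), max(spec$nugget, 1e-8))))
}

params_to_spec <- function(p, family, D) {
  np <- length(p)
  switch(family,
    rbf = ,
    matern32 = kernel_spec(family, variance = exp(p[1]),
                           lengthscales = exp(p[2]), nugget = exp(p[np])),
    ard_rbf = kernel_spec(family, variance = exp(p[1]),
                          lengthscales = exp(p[2:(np - 1)]), nugget = exp(p[np])),
    linear = kernel_spec("linear", linear_variances = exp(p[-np]),
                         nugget = exp(p[np])))
}

#' @export
print.gp_fit <- function(x, ...) {
  cat(sprintf("gp_fit: %d observations, design {%s}, %s kernel\n",
              length(x$y), paste(x$design, collapse = ", "), x$family))
  cat(sprintf("  log marginal likelihood: %.4f\n", x$log_marginal))
  print(x$kernel)
  invisible(x)
}

#' GP posterior at new inputs
#'
#' Standard Gaussian-process conditioning: the posterior over the latent
#' growth function (or, with \code{include_noise = TRUE}, over new noisy
#' observations) at the query inputs is multivariate normal.
#'
#' @param model a \code{gp_fit}.
#' @param Xstar query inputs: a numeric matrix with the model's design
#'   columns, or (for a pure-time design) a numeric vector of times.
#' @param include_noise add the nugget variance to the diagonal.
#' @return object of class \code{posterior_mvn} with fields
#'   \code{locations}, \code{mean}, \code{cov}, \code{includes_noise}.
#' @export
predict_posterior <- function(model, Xstar, include_noise = FALSE) {
  stopifnot(inherits(model, "gp_fit"))
  if (!is.matrix(Xstar)) {
    if (length(model$design) != 1)
      stop("Xstar must be a matrix with columns ",
           paste(model$design, collapse = ", "), call. = FALSE)
    Xstar <- matrix(as.numeric(Xstar), ncol = 1)
  }
  if (ncol(Xstar) != ncol(model$X))
    stop("Xstar dimension does not match the model design", call. = FALSE)
  Ks <- kernel_matrix(model$kernel, Xstar, model$X)
  Kss <- kernel_matrix(model$kernel, Xstar, nugget = FALSE)
  mu <- as.numeric(Ks %*% model$alpha)
  V <- forwardsolve(t(model$chol), t(Ks))
  S <- Kss - crossprod(V)
  S <- (S + t(S)) / 2
  if (include_noise) S <- S + diag(model$kernel$nugget, nrow(Xstar))
  structure(list(locations = Xstar, mean = mu, cov = S,
                 includes_noise = include_noise),
            class = "posterior_mvn")
}

#' @export
print.posterior_mvn <- function(x, ...) {
  cat(sprintf("posterior_mvn over %d points (%s noise)\n",
              length(x$mean), if (x$includes_noise) "with" else "without"))
  invisible(x)
}

#' Draw joint samples from a posterior
#'
#' @param post a \code{posterior_mvn}.
#' @param n number of draws.
#' @param seed integer seed.
#' @return matrix, one row per draw.
#' @export
sample_posterior <- function(post, n = 1, seed = NULL) {
  p <- length(post$mean)
  S <- post$cov + diag(1e-10 * max(mean(diag(post$cov)), 1e-12), p)
  R <- chol_jitter(S)
  draw <- function() {
    Z <- matrix(stats::rnorm(n * p), n, p)
    sweep(Z %*% R, 2, post$mean, "+")
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' Bayesian information criterion of a fitted GP
#'
#' \eqn{-2 \log L + k \log n}, where \eqn{L} is the maximized marginal
#' likelihood, \eqn{k} the number of kernel hyperparameters and \eqn{n} the
#' number of observations.
#' @param model a \code{gp_fit}.
#' @return scalar BIC (lower is better).
#' @export
bic <- function(model) {
  stopifnot(inherits(model, "gp_fit"))
  k <- n_hyperparameters(model$kernel, ncol(model$X))
  -2 * model$log_marginal + k * log(length(model$y))
}

#' Serialize a fitted GP to structured text
#'
#' Writes the design, kernel family, hyperparameters and training arrays
#' as JSON so a fit can be stored alongside CLI outputs and reloaded
#' without refitting.
#'
#' @param model a \code{gp_fit}.
#' @param path output file path.
#' @export
write_gp_fit <- function(model, path) {
  stopifnot(inherits(model, "gp_fit"))
  obj <- list(
    design = model$design, family = model$family,
    kernel = list(variance = model$kernel$variance,
                  lengthscales = model$kernel$lengthscales,
                  nugget = model$kernel$nugget,
                  linear_variances = model$kernel$linear_variances),
    log_marginal = model$log_marginal,
    X = apply(model$X, 2, identity, simplify = FALSE),
    y = model$y,
    y_digest = sum(model$y) + length(model$y))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Reload a serialized GP fit
#'
#' Rebuilds the cached decomposition from the stored arrays; the kernel
#' hyperparameters are taken as stored (no refitting).
#'
#' @param path path written by \code{\link{write_gp_fit}}.
#' @return a \code{gp_fit}.
#' @export
read_gp_fit <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  X <- do.call(cbind, obj$X)
  colnames(X) <- obj$design
  spec <- kernel_spec(obj$family, variance = obj$kernel$variance %||% 1,
                      lengthscales = obj$kernel$lengthscales %||% 1,
                      nugget = obj$kernel$nugget,
                      linear_variances = obj$kernel$linear_variances)
  y <- as.numeric(obj$y)
  if (abs((sum(y) + length(y)) - obj$y_digest) > 1e-6)
    stop("stored data digest does not match; file corrupted?", call. = FALSE)
  K <- kernel_matrix(spec, X, nugget = TRUE)
  R <- chol_jitter(K)
  structure(list(
    X = X, y = y, design = obj$design, family = obj$family, kernel = spec,
    log_marginal = obj$log_marginal, chol = R,
    alpha = backsolve(R, forwardsolve(t(R), y)),
    optim_par = spec_to_params(spec, ncol(X)), convergence = 0L
  ), class = "gp_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
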