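#' Posterior of the growth-rate (time-derivative) process
#'
#' The squared-exponential kernel is infinitely differentiable, so the
#' time derivative of the latent growth function is itself a GP.  With
#' \eqn{k(x,x') = \sigma^2 \exp(-\Delta t^2/\ell_t^2 - \dots)} the
#' cross-covariance with an observation and the derivative
#' auto-covariance are the analytic partials
#' \deqn{\partial_{t^*} k = -\tfrac{2\Delta t}{\ell_t^2}\,k, \qquad
#'       \partial_{t}\partial_{t'} k =
#'       \left(\tfrac{2}{\ell_t^2} - \tfrac{4\Delta t^2}{\ell_t^4}\right) k,}
#' from which the usual GP conditioning gives the derivative posterior.
#' The derivative prior mean is zero, inherited from the zero-mean prior
#' on the growth function itself.
#'
#' @param model a \code{gp_fit} with an \code{rbf} or \code{ard_rbf}
#'   kernel (other families are not smooth enough).
#' @param tgrid numeric vector of times at which to evaluate d/dt log2-OD.
#' @param at named list fixing the non-time design columns (e.g.
#'   \code{list(strain = 1)}); required when the model has covariates.
#' @return a \code{posterior_mvn} over the derivative values on
#'   \code{tgrid}.
#' @export
derivative_posterior <- function(model, tgrid, at = NULL) {
  stopifnot(inherits(model, "gp_fit"))
  if (!model$family %in% c("rbf", "ard_rbf")) {
    stop(sprintf(
      "derivative GP requires an rbf-family kernel ('%s' is not smooth enough)",
      model$family), call. = FALSE)
  }
  Xstar <- expand_time_grid(model, tgrid, at)
  spec <- model$kernel
  lt <- if (spec$family == "rbf") spec$lengthscales[1] else spec$lengthscales[1]
  # base (noise-free) covariances
  Ks <- kernel_matrix(spec, Xstar, model$X)         # m x n
  Kss <- kernel_matrix(spec, Xstar, nugget = FALSE) # m x m
  dt_sn <- outer(Xstar[, 1], model$X[, 1], "-")
  dt_ss <- outer(Xstar[, 1], Xstar[, 1], "-")
  dKs <- (-2 * dt_sn / lt^2) * Ks
  ddKss <- (2 / lt^2 - 4 * dt_ss^2 / lt^4) * Kss
  mu <- as.numeric(dKs %*% model$alpha)
  V <- forwardsolve(t(model$chol), t(dKs))
  S <- ddKss - crossprod(V)
  S <- (S + t(S)) / 2
  structure(list(locations = Xstar, mean = mu, cov = S, includes_noise = FALSE),
            class = "posterior_mvn")
}

# Build a query matrix from a time grid plus fixed covariate values.
expand_time_grid <- function(model, tgrid, at = NULL) {
  D <- ncol(model$X)
  if (D == 1) return(matrix(as.numeric(tgrid), ncol = 1,
                            dimnames = list(NULL, model$design)))
  others <- model$design[-1]
  vals <- vapply(others, function(nm) {
    if (!is.null(at) && nm %in% names(at)) as.numeric(at[[nm]])
    else stop("fix covariate '", nm, "' via the 'at' argument", call. = FALSE)
  }, numeric(1))
  X <- cbind(as.numeric(tgrid),
             matrix(rep(vals, each = length(tgrid)), ncol = length(vals)))
  colnames(X) <- model$design
  X
}

max_with_ci <- function(post, n_samples, seed, level = 0.95) {
  point <- max(post$mean)
  draws <- sample_posterior(post, n_samples, seed = seed)
  mx <- apply(draws, 1, max)
  a <- (1 - level) / 2
  ci <- unname(stats::quantile(mx, c(a, 1 - a)))
  list(point = point, ci = ci, samples = mx)
}

#' Maximum specific growth rate from a fitted GP
#'
#' The point estimate is the maximum over the time grid of the posterior
#' mean of d/dt log2-OD (the MAP derivative).  The credible interval is
#' taken, by default, from the distribution of the grid maximum across
#' joint posterior derivative samples; \code{ci_method = "pointwise"}
#' instead uses the derivative marginal at the argmax.
#'
#' @param model a \code{gp_fit} (rbf-family kernel).
#' @param tgrid evaluation times; default 100 evenly spaced points over
#'   the observed time range.
#' @param at fixed covariate values, see
#'   \code{\link{derivative_posterior}}.
#' @param n_samples posterior draws for the max-over-samples interval.
#' @param seed integer seed for the draws.
#' @param ci_method \code{"max_samples"} (default) or \code{"pointwise"}.
#' @return list with \code{point} (per-hour rate), \code{ci}
#'   (95\% interval) and \code{t_at_max}.
#' @export
estimate_mu_max <- function(model, tgrid = NULL, at = NULL, n_samples = 10000,
                            seed = 1L, ci_method = c("max_samples", "pointwise")) {
  ci_method <- match.arg(ci_method)
  if (is.null(tgrid)) tgrid <- default_tgrid(model, 100)
  post <- derivative_posterior(model, tgrid, at = at)
  if (ci_method == "pointwise") {
    i <- which.max(post$mean)
    sd_i <- sqrt(max(post$cov[i, i], 0))
    list(point = post$mean[i],
         ci = post$mean[i] + c(-1, 1) * stats::qnorm(0.975) * sd_i,
         t_at_max = tgrid[i])
  } else {
    r <- max_with_ci(post, n_samples, seed)
    list(point = r$point, ci = r$ci, t_at_max = tgrid[which.max(post$mean)])
  }
}

#' Carrying capacity from a fitted GP
#'
#' Maximum over the time grid of the noiseless posterior mean of log2-OD
#' (the MAP growth level), with a max-over-samples 95\% credible interval.
#'
#' @inheritParams estimate_mu_max
#' @return list with \code{point} (log2-OD units), \code{ci} and
#'   \code{t_at_max}.
#' @export
estimate_carrying_capacity <- function(model, tgrid = NULL, at = NULL,
                                       n_samples = 10000, seed = 1L) {
  if (is.null(tgrid)) tgrid <- default_tgrid(model, 100)
  post <- predict_posterior(model, expand_time_grid(model, tgrid, at),
                            include_noise = FALSE)
  r <- max_with_ci(post, n_samples, seed)
  list(point = r$point, ci = r$ci, t_at_max = tgrid[which.max(post$mean)])
}

default_tgrid <- function(model, n) {
  rng <- range(model$X[, 1])
  seq(rng[1], rng[2], length.out = n)
}

#' Area under the growth curve, with exact posterior uncertainty
#'
#' The noiseless posterior of log2-OD is evaluated on \code{n_points}
#' evenly spaced times; the AUC is the linear functional \eqn{a \cdot f}
#' with left-Riemann weights \eqn{a = (\Delta t, \Delta t, \dots)}, so it
#' is exactly Gaussian: \eqn{AUC \sim N(a\mu, a\Sigma a^T)}.
#'
#' @param model a \code{gp_fit}.
#' @param t_start,t_end integration limits (default: observed time range).
#' @param n_points number of grid points (default 50).
#' @param at fixed covariate values for models with covariates.
#' @return list with \code{mean}, \code{variance} (log2-OD * hours) and
#'   the \code{grid} used.
#' @export
estimate_auc <- function(model, t_start = NULL, t_end = NULL, n_points = 50,
                         at = NULL) {
  if (n_points < 2) stop("n_points must be at least 2", call. = FALSE)
  rng <- range(model$X[, 1])
  if (is.null(t_start)) t_start <- rng[1]
  if (is.null(t_end)) t_end <- rng[2]
  if (t_end <= t_start) stop("t_end must exceed t_start", call. = FALSE)
  grid <- seq(t_start, t_end, length.out = n_points)
  dt <- grid[2] - grid[1]
  post <- predict_posterior(model, expand_time_grid(model, grid, at),
                            include_noise = FALSE)
  a <- rep(dt, n_points)
  list(mean = sum(a * post$mean),
       variance = max(as.numeric(a %*% post$cov %*% a), 0),
       grid = grid)
}

#' Growth-parameter table for every (strain, condition) group
#'
#' Fits a time-only GP to each (strain, condition) group of a normalized
#' growth table and extracts the three GP growth metrics.
#'
#' @param table a log-transformed growth table.
#' @param restarts,seed passed to \code{\link{fit_gp}}.
#' @param n_samples posterior draws for the credible intervals.
#' @param path optional CSV output path.
#' @return data frame with one row per (strain, condition): point
#'   estimates and 95\% intervals for mu_max and carrying capacity, and
#'   the AUC mean/variance.
#' @export
growth_parameter_table <- function(table, restarts = 3, seed = 1L,
                                   n_samples = 4000, path = NULL) {
  stopifnot(inherits(table, "growth_table"), is_log(table))
  grp <- group_id(table)
  out <- lapply(unique(grp), function(g) {
    sub <- table[grp == g, , drop = FALSE]
    sub <- structure(sub, class = class(table), is_log = TRUE)
    fit <- fit_gp(sub, design = "time", family = "rbf",
                  restarts = restarts, seed = seed)
    mu <- estimate_mu_max(fit, n_samples = n_samples, seed = seed)
    A <- estimate_carrying_capacity(fit, n_samples = n_samples, seed = seed)
    auc <- estimate_auc(fit)
    lab <- strsplit(g, "\r", fixed = TRUE)[[1]]
    keys <- intersect(c("strain", "condition"), names(table))
    row <- as.data.frame(as.list(stats::setNames(lab, keys)),
                         stringsAsFactors = FALSE)
    cbind(row, data.frame(
      mu_max = mu$point, mu_max_lo = mu$ci[1], mu_max_hi = mu$ci[2],
      capacity = A$point, capacity_lo = A$ci[1], capacity_hi = A$ci[2],
      auc_mean = auc$mean, auc_var = auc$variance))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  if (!is.null(path)) utils::write.csv(res, path, row.names = FALSE)
  res
}
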