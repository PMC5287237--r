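#' Classical primary growth models
#'
#' The four sigmoidal growth functions used as parametric baselines, in
#' the reparameterization where \code{A} is the carrying capacity (upper
#' asymptote), \code{mu_max} the maximum specific growth rate (the slope
#' at the inflection point) and \code{lam} the lag time.
#'
#' @param t time, hours (vectorized).
#' @param A carrying capacity (> 0 where present).
#' @param mu_max maximum specific growth rate, per hour.
#' @param lam lag time, hours.
#' @param a,b Schnute shape parameters (no direct biological meaning);
#'   both must be nonzero -- the Gompertz model is the a > 0, b -> 0
#'   limit of the Schnute family.
#' @param v Richards shape parameter (> 0); v = 1 recovers the logistic.
#' @return growth level at \code{t}, same units as the fitted data.
#' @name primary_models
NULL

#' @rdname primary_models
#' @export
gompertz <- function(t, A, mu_max, lam) {
  A * exp(-exp(mu_max * exp(1) / A * (lam - t) + 1))
}

#' @rdname primary_models
#' @export
logistic_growth <- function(t, A, mu_max, lam) {
  A / (1 + exp(4 * mu_max / A * (lam - t) + 2))
}

#' @rdname primary_models
#' @export
schnute <- function(t, mu_max, lam, a, b) {
  if (a == 0 || b == 0) {
    stop("schnute requires a != 0 and b != 0; the b -> 0 (a > 0) limit is the Gompertz model",
         call. = FALSE)
  }
  base <- (1 - b * exp(a * lam + 1 - b - a * t)) / (1 - b)
  if (any(base < 0) && abs(1 / b - round(1 / b)) > 1e-8) {
    stop("schnute bracket is negative with non-integer 1/b; value undefined",
         call. = FALSE)
  }
  mu_max * (1 - b) / a * base^(1 / b)
}

#' @rdname primary_models
#' @export
richards <- function(t, A, mu_max, lam, v) {
  if (v <= 0) stop("richards requires v > 0", call. = FALSE)
  A * (1 + v * exp(1 + v) *
         exp(mu_max / A * (1 + v)^(1 + 1 / v) * (lam - t)))^(-1 / v)
}

#' Mean squared error
#'
#' @param y observed values.
#' @param m model predictions, same length.
#' @return mean of squared differences.
#' @export
mse <- function(y, m) {
  if (length(y) != length(m)) stop("length mismatch in mse()", call. = FALSE)
  if (length(y) == 0) stop("mse() needs at least one value", call. = FALSE)
  mean((y - m)^2)
}

model_fun <- function(model_name) {
  switch(model_name,
    gompertz = function(t, p) gompertz(t, p["A"], p["mu_max"], p["lam"]),
    logistic = function(t, p) logistic_growth(t, p["A"], p["mu_max"], p["lam"]),
    schnute = function(t, p) schnute(t, p["mu_max"], p["lam"], p["a"], p["b"]),
    richards = function(t, p) richards(t, p["A"], p["mu_max"], p["lam"], p["v"]),
    stop("unknown model '", model_name, "'", call. = FALSE))
}

default_init <- function(model_name, t, y) {
  o <- order(t)
  t <- t[o]; y <- y[o]
  A0 <- max(y)
  if (A0 <= 0) A0 <- max(abs(y), 0.1)
  slopes <- diff(y) / pmax(diff(t), 1e-9)
  mu0 <- max(slopes)
  if (!is.finite(mu0) || mu0 <= 0) mu0 <- 0.1
  lam0 <- t[which.max(slopes)]
  switch(model_name,
    gompertz = c(A = A0, mu_max = mu0, lam = lam0),
    logistic = c(A = A0, mu_max = mu0, lam = lam0),
    # a and b from the b -> 0 (Gompertz) limit, where the asymptote is
    # mu*e/a; b must start tiny or the Schnute bracket goes negative at
    # early times
    schnute = c(mu_max = mu0, lam = lam0,
                a = max(mu0 * exp(1) / A0, 2e-4), b = 1e-3),
    richards = c(A = A0, mu_max = mu0, lam = lam0, v = 1))
}

param_limits <- function(model_name) {
  switch(model_name,
    gompertz = ,
    logistic = list(lower = c(A = 1e-6, mu_max = -10, lam = -100),
                    upper = c(A = 100, mu_max = 10, lam = 100)),
    schnute = list(lower = c(mu_max = -10, lam = -100, a = 1e-4, b = 1e-6),
                   upper = c(mu_max = 10, lam = 100, a = 10, b = 0.999)),
    richards = list(lower = c(A = 1e-6, mu_max = -10, lam = -100, v = 1e-3),
                    upper = c(A = 100, mu_max = 10, lam = 100, v = 50)))
}

#' Fit a primary growth model by damped least squares
#'
#' Levenberg-Marquardt nonlinear least squares (via
#' \code{minpack.lm::nls.lm}) of one primary model to a single growth
#' curve.  Initialization defaults to simple heuristics: A = max y,
#' mu_max = steepest finite-difference slope, lam = time of that slope.
#' Non-convergence is reported through the \code{converged} flag rather
#' than an error, so that benchmark sweeps can score every curve.
#'
#' @param model_name one of \code{"gompertz"}, \code{"logistic"},
#'   \code{"schnute"}, \code{"richards"}.
#' @param curve a single-curve, log-transformed growth table (or any
#'   table; all rows are pooled as one curve).
#' @param init optional named parameter start values.
#' @return object of class \code{primary_fit}: parameters, convergence
#'   flag, training MSE and a \code{predict} closure.
#' @export
fit_primary <- function(model_name, curve, init = NULL) {
  model_name <- match.arg(model_name,
                          c("gompertz", "logistic", "schnute", "richards"))
  t <- curve$time; y <- curve$od
  f <- model_fun(model_name)
  p0 <- default_init(model_name, t, y)
  if (!is.null(init)) p0[names(init)] <- unlist(init)
  lim <- param_limits(model_name)
  clamp <- function(p) pmin(pmax(p, lim$lower + 1e-9), lim$upper - 1e-9)
  p0 <- clamp(p0)
  # the Schnute surface has disjoint basins in b; try several shape starts
  starts <- list(p0)
  if (model_name == "schnute" && is.null(init)) {
    for (b0 in c(0.2, 0.5)) starts[[length(starts) + 1]] <-
      clamp(replace(p0, "b", b0))
  }
  resid_fun <- function(p) {
    pv <- stats::setNames(p, names(p0))
    r <- tryCatch(y - f(t, pv), error = function(e) NULL)
    if (is.null(r) || any(!is.finite(r))) rep(1e6, length(y))
    else pmin(pmax(r, -1e6), 1e6)
  }
  # a candidate is only acceptable if its curve is defined and finite over
  # the whole fitted time range, not just at the fitted points (the
  # Schnute bracket can cross zero between them)
  tfine <- seq(min(t), max(t), length.out = 200)
  valid_fit <- function(ri) {
    pv <- stats::setNames(unname(ri$par), names(p0))
    pr <- tryCatch(f(tfine, pv), error = function(e) NULL)
    !is.null(pr) && all(is.finite(pr))
  }
  res <- NULL; res_any <- NULL
  for (ps in starts) {
    ri <- tryCatch(
      minpack.lm::nls.lm(par = ps, lower = lim$lower, upper = lim$upper,
                         fn = resid_fun,
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(ri)) next
    if (is.null(res_any) || ri$deviance < res_any$deviance) res_any <- ri
    if (valid_fit(ri) && (is.null(res) || ri$deviance < res$deviance)) res <- ri
  }
  domain_ok <- !is.null(res)
  if (!domain_ok) res <- res_any
  if (is.null(res)) {
    return(structure(list(model_name = model_name, parameters = p0,
                          converged = FALSE, mse_train = NA_real_,
                          predict = function(t) rep(NA_real_, length(t))),
                     class = "primary_fit"))
  }
  pars <- stats::setNames(unname(res$par), names(p0))
  preds <- tryCatch(f(t, pars), error = function(e) rep(NA_real_, length(t)))
  ok <- domain_ok && res$info %in% 1:4 && all(is.finite(pars)) &&
    all(is.finite(preds))
  structure(list(
    model_name = model_name, parameters = pars, converged = ok,
    mse_train = if (ok) mse(y, preds) else NA_real_,
    predict = function(t) f(t, pars)
  ), class = "primary_fit")
}

#' @export
print.primary_fit <- function(x, ...) {
  cat(sprintf("primary_fit: %s (%s)\n", x$model_name,
              if (x$converged) "converged" else "NOT converged"))
  print(signif(x$parameters, 4))
  invisible(x)
}

#' Held-out MSE benchmark: GP versus primary models
#'
#' For every growth curve: split records 80/20 into train/test, fit a
#' time-only GP and all four primary models on the training points, and
#' score each model by MSE between its prediction and the held-out test
#' points (GP prediction = posterior mean).  Per-model MSE distributions
#' are compared with one-sided Welch t-tests of the hypothesis that the
#' GP's held-out MSE is smaller.
#'
#' @param tables list of single-curve growth tables, or one growth table
#'   (split into curves by replicate/strain/condition/batch).
#' @param seed integer seed (splits and GP restarts).
#' @param train_frac training fraction per curve.
#' @param restarts GP optimizer restarts.
#' @return list of class \code{growth_benchmark}: \code{per_curve} data
#'   frame (curve, model, test/train MSE, converged), \code{summary}
#'   (mean/median MSE and failure counts per model), and \code{tests}
#'   (one-sided Welch t-test of GP vs each primary model).
#' @export
benchmark_models <- function(tables, seed = 1L, train_frac = 0.8, restarts = 3) {
  if (inherits(tables, "growth_table")) {
    id <- curve_id(tables)
    tables <- lapply(unique(id), function(cid) {
      sub <- tables[id == cid, , drop = FALSE]
      structure(sub, class = c("growth_table", "data.frame"),
                is_log = is_log(tables))
    })
  }
  if (length(tables) < 2) stop("benchmark needs at least 2 curves", call. = FALSE)
  models <- c("gp", "gompertz", "logistic", "schnute", "richards")
  rows <- list()
  for (i in seq_along(tables)) {
    curve <- tables[[i]]
    # per-curve seed derived from the curve's content, so results do not
    # depend on processing order and duplicated curves score identically
    curve_seed <- (seed + (round(abs(sum(curve$od)) * 1e4) %% 1000003L)) %%
      .Machine$integer.max
    sp <- train_test_split(curve, train_frac, seed = curve_seed)
    tr <- sp$train; te <- sp$test
    for (m in models) {
      if (m == "gp") {
        fit <- fit_gp(tr, design = "time", family = "rbf",
                      restarts = restarts, seed = curve_seed)
        pred <- predict_posterior(fit, matrix(te$time, ncol = 1))$mean
        ok <- TRUE
        mtr <- mse(tr$od, predict_posterior(fit, matrix(tr$time, ncol = 1))$mean)
      } else {
        fit <- fit_primary(m, tr)
        ok <- fit$converged
        pred <- if (ok) {
          tryCatch(fit$predict(te$time), error = function(e) NULL)
        } else NULL
        if (is.null(pred) || any(!is.finite(pred))) {
          ok <- FALSE
          pred <- rep(NA_real_, nrow(te))
        }
        mtr <- fit$mse_train
      }
      rows[[length(rows) + 1]] <- data.frame(
        curve = i, model = m, converged = ok,
        mse_train = mtr,
        mse_test = if (ok) mse(te$od, pred) else NA_real_)
    }
  }
  per_curve <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(models, function(m) {
    v <- per_curve$mse_test[per_curve$model == m]
    data.frame(model = m, n_curves = length(v), n_failed = sum(is.na(v)),
               mean_mse = mean(v, na.rm = TRUE),
               median_mse = stats::median(v, na.rm = TRUE))
  }))
  gp_mse <- per_curve$mse_test[per_curve$model == "gp"]
  tests <- do.call(rbind, lapply(setdiff(models, "gp"), function(m) {
    v <- per_curve$mse_test[per_curve$model == m]
    tt <- tryCatch(
      stats::t.test(gp_mse, v, alternative = "less"),
      error = function(e) NULL)
    data.frame(comparison = paste0("gp_vs_", m),
               t = if (is.null(tt)) NA_real_ else unname(tt$statistic),
               p_value = if (is.null(tt)) NA_real_ else tt$p.value)
  }))
  structure(list(per_curve = per_curve, summary = summ, tests = tests,
                 seed = seed, train_frac = train_frac),
            class = "growth_benchmark")
}

#' @export
print.growth_benchmark <- function(x, ...) {
  cat("growth model benchmark (held-out MSE)\n")
  print(x$summary, row.names = FALSE)
  cat("\none-sided Welch t-tests (GP MSE smaller):\n")
  print(x$tests, row.names = FALSE)
  invisible(x)
}

#' Welch t-test between two groups of parameter estimates
#'
#' Used to compare classical growth-parameter estimates (e.g. per-replicate
#' Gompertz mu_max) between a parent and a mutant strain.
#'
#' @param group_a,group_b numeric vectors of estimates (each length >= 2).
#' @param alternative \code{"two.sided"}, \code{"less"} or
#'   \code{"greater"} (a vs b).
#' @return list with \code{t}, \code{p_value}, \code{df} and the group
#'   means.
#' @export
parameter_ttest <- function(group_a, group_b,
                            alternative = c("two.sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  if (length(group_a) < 2 || length(group_b) < 2)
    stop("each group needs at least 2 estimates", call. = FALSE)
  tt <- stats::t.test(group_a, group_b, alternative = alternative)
  list(t = unname(tt$statistic), p_value = tt$p.value,
       df = unname(tt$parameter),
       mean_a = mean(group_a), mean_b = mean(group_b))
}

#' Bonferroni family-wise correction for a set of parameter tests
#'
#' @param p_values numeric vector of raw p-values.
#' @param alpha family-wise error-rate budget (default 0.25).
#' @return data frame with adjusted p-values and significance calls.
#' @export
fwer_adjust <- function(p_values, alpha = 0.25) {
  adj <- stats::p.adjust(p_values, method = "bonferroni")
  data.frame(p_raw = p_values, p_adjusted = adj, significant = adj <= alpha)
}
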