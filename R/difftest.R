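#' Null/alternative covariate designs for differential-growth tests
#'
#' Two nested designs define each Bayes-factor test:
#' \describe{
#'   \item{strain_test}{null \{time\} vs alternative \{time, strain\}: is
#'     growth different between parent and mutant?}
#'   \item{stress_test}{null \{time, strain, stress\} vs alternative
#'     \{time, strain, stress, interaction\}: does the mutant respond to
#'     stress differently from the parent, controlling for its baseline
#'     difference?  The interaction column is strain * stress, always
#'     recomputed from the labels.}
#' }
#'
#' @param table a growth table with the required covariate columns.
#' @param which \code{"strain_test"} or \code{"stress_test"}.
#' @param parent,control reference levels, see \code{\link{encode_design}}.
#' @return list with character vectors \code{null} and \code{alt}.
#' @export
build_design <- function(table, which = c("strain_test", "stress_test"),
                         parent = NULL, control = NULL) {
  which <- match.arg(which)
  if (!"strain" %in% names(table))
    stop("table has no 'strain' column", call. = FALSE)
  lev <- sort(unique(table$strain))
  if (length(lev) < 2)
    stop("strain test needs both parent and mutant levels (found only '",
         lev, "')", call. = FALSE)
  if (length(lev) > 2)
    stop("pairwise tests only: strain has ", length(lev), " levels", call. = FALSE)
  if (which == "strain_test") {
    list(null = "time", alt = c("time", "strain"))
  } else {
    if (!"condition" %in% names(table))
      stop("stress test needs a 'condition' column", call. = FALSE)
    if (length(unique(table$condition)) != 2)
      stop("stress test needs exactly 2 condition levels", call. = FALSE)
    list(null = c("time", "strain", "stress"),
         alt = c("time", "strain", "stress", "interaction"))
  }
}

#' Approximate log Bayes factor between nested GP designs
#'
#' The Bayes factor is approximated as the ratio of maximized marginal
#' likelihoods: each design is fitted with an ARD squared-exponential
#' kernel over its columns (point estimates of the hyperparameters; no
#' hyperparameter integration), and
#' \eqn{\log BF = \log p(Y | H_a) - \log p(Y | H_0)}.
#'
#' @param table a log-transformed growth table.
#' @param which test type, see \code{\link{build_design}}.
#' @param restarts,seed,maxit GP optimizer settings.
#' @param parent,control reference levels.
#' @return scalar log Bayes factor, with the two \code{gp_fit}s attached
#'   as attributes \code{"fit_alt"} and \code{"fit_null"}.
#' @export
bayes_factor <- function(table, which = c("strain_test", "stress_test"),
                         restarts = 5, seed = 1L, maxit = 200,
                         parent = NULL, control = NULL) {
  which <- match.arg(which)
  des <- build_design(table, which, parent, control)
  y <- as.numeric(table$od)
  fit0 <- fit_gp_xy(encode_design(table, des$null, parent, control), y,
                    "ard_rbf", restarts = restarts, seed = seed, maxit = maxit)
  fit1 <- fit_gp_xy(encode_design(table, des$alt, parent, control), y,
                    "ard_rbf", restarts = restarts, seed = seed, maxit = maxit,
                    start = alt_start_from_null(fit0$optim_par,
                                                length(des$alt) - length(des$null)))
  structure(fit1$log_marginal - fit0$log_marginal,
            fit_alt = fit1, fit_null = fit0)
}

# Starting point for the alternative design derived from the fitted null:
# same variance/lengthscales/nugget, with the added covariate's ARD
# lengthscale at (near) its upper bound so the start reproduces the null
# fit and the optimizer can only improve on it.  Keeps the optimized
# designs practically nested.
alt_start_from_null <- function(null_par, n_add) {
  np <- length(null_par)
  list(off = c(null_par[-np], rep(log(999), n_add), null_par[np]),
       on = c(null_par[-np], rep(log(0.5), n_add), null_par[np]))
}

#' Permute strain labels within time points
#'
#' Null datasets for permutation calibration are built by shuffling the
#' strain labels among the observations at each time point (optionally
#' within a further grouping such as the stress arm), which preserves the
#' per-time-point label distribution exactly while destroying any
#' association between label and growth level.
#'
#' @param table a growth table.
#' @param covariate column to permute (default \code{"strain"}).
#' @param seed integer seed.
#' @param within optional column name; labels are shuffled only among
#'   rows sharing a value of it (e.g. \code{"condition"}).
#' @return the table with permuted labels; all other fields untouched.
#' @export
permute_strain_labels <- function(table, covariate = "strain", seed = 1L,
                                  within = NULL) {
  if (!covariate %in% names(table))
    stop("no column '", covariate, "' to permute", call. = FALSE)
  key <- format(table$time, digits = 15)
  if (!is.null(within)) key <- paste(key, table[[within]])
  lab <- table[[covariate]]
  with_seed(seed, {
    for (k in unique(key)) {
      rows <- which(key == k)
      if (length(rows) > 1) lab[rows] <- lab[sample(rows)]
    }
  })
  out <- table
  out[[covariate]] <- lab
  out
}

#' Permutation-based FDR at a threshold
#'
#' Empirical false-discovery-rate estimate
#' \eqn{FDR(c) = |BF_{perm} > c| / (|BF_{real} > c| \cdot n_{perm})}: the
#' count of real scores exceeding the threshold is scaled by the number of
#' permutations so numerator and denominator count the same number of
#' tests.
#'
#' @param perm_log_bfs permuted log Bayes factors.
#' @param real_log_bfs real log Bayes factor(s).
#' @param threshold threshold c.
#' @return FDR estimate (can exceed 1; \code{Inf} when nothing is called).
#' @export
permutation_fdr <- function(perm_log_bfs, real_log_bfs, threshold) {
  n_perm <- length(perm_log_bfs)
  n_real <- length(real_log_bfs)
  fp <- sum(perm_log_bfs > threshold)
  disc <- sum(real_log_bfs > threshold) * n_perm / n_real
  if (disc == 0) return(Inf)
  fp / disc
}

#' Permutation-calibrated Bayes-factor test for differential growth
#'
#' Computes the real log Bayes factor, then an empirical null
#' distribution by recomputing it on label-permuted data
#' (\code{\link{permute_strain_labels}}; for the stress test, strain
#' labels are permuted within each stress arm and the interaction column
#' recomputed).  Significance: the real score must strictly exceed the
#' empirical 80th percentile of the permuted scores, corresponding to an
#' FDR of at most 20\%.
#'
#' Permuted refits are started from the real fit's optimum (the permuted
#' alternative is a small perturbation of the same likelihood surface),
#' which keeps the 100-permutation default affordable.
#'
#' @inheritParams bayes_factor
#' @param n_perm number of permutations (default 100; at least 5).
#' @param fdr_percentile percentile of the permuted scores used as the
#'   significance threshold (default 0.80).
#' @return object of class \code{bf_test}: \code{log_bf},
#'   \code{perm_log_bfs}, \code{threshold}, \code{fdr} (estimated FDR at
#'   the real score), \code{significant}.
#' @export
permutation_test <- function(table, which = c("strain_test", "stress_test"),
                             n_perm = 100, seed = 1L, restarts = 5,
                             maxit = 200, fdr_percentile = 0.80,
                             parent = NULL, control = NULL) {
  which <- match.arg(which)
  if (n_perm < 5)
    stop("n_perm < 5 gives an uninformative permutation null; refusing",
         call. = FALSE)
  des <- build_design(table, which, parent, control)
  y <- as.numeric(table$od)
  n_add <- length(des$alt) - length(des$null)
  fit0 <- fit_gp_xy(encode_design(table, des$null, parent, control), y,
                    "ard_rbf", restarts = restarts, seed = seed, maxit = maxit)
  fit1 <- fit_gp_xy(encode_design(table, des$alt, parent, control), y,
                    "ard_rbf", restarts = restarts, seed = seed, maxit = maxit,
                    start = alt_start_from_null(fit0$optim_par, n_add))
  real <- fit1$log_marginal - fit0$log_marginal
  within <- if (which == "stress_test") "condition" else NULL
  perm_seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L, n_perm))
  perm <- vapply(seq_len(n_perm), function(i) {
    ptab <- permute_strain_labels(table, "strain", seed = perm_seeds[i],
                                  within = within)
    f0 <- if (which == "strain_test") fit0 else {
      fit_gp_xy(encode_design(ptab, des$null, parent, control), y,
                "ard_rbf", restarts = 1, maxit = maxit,
                start = fit0$optim_par)
    }
    p1 <- fit_gp_xy(encode_design(ptab, des$alt, parent, control), y,
                    "ard_rbf", restarts = 1, maxit = maxit,
                    start = c(list(fit1$optim_par),
                              alt_start_from_null(f0$optim_par, n_add)))
    p1$log_marginal - f0$log_marginal
  }, numeric(1))
  thr <- sort(perm)[ceiling(fdr_percentile * n_perm)]
  structure(list(
    which = which, log_bf = real, perm_log_bfs = perm, threshold = thr,
    fdr = sum(perm > real) / n_perm, significant = real > thr,
    n_perm = n_perm, fdr_percentile = fdr_percentile, seed = seed,
    fit_alt = fit1, fit_null = fit0
  ), class = "bf_test")
}

#' @export
print.bf_test <- function(x, ...) {
  cat(sprintf("%s: log BF = %.3f, permutation threshold (%.0f%%) = %.3f\n",
              x$which, x$log_bf, 100 * x$fdr_percentile, x$threshold))
  cat(sprintf("  estimated FDR at real score: %.3f -> %s\n", x$fdr,
              if (x$significant) "SIGNIFICANT" else "not significant"))
  invisible(x)
}

#' Per-time-point posterior growth difference (baseline-corrected)
#'
#' For each time t_k the contrast between mutant and parent latent growth,
#' corrected for their difference at the experiment start t_0, is the
#' linear functional \eqn{a \cdot f_k} with \eqn{a = (1, -1, -1, 1)} of
#' the joint noiseless posterior over
#' \eqn{(f_m(t_k), f_m(t_0), f_p(t_k), f_p(t_0))}, hence exactly Gaussian.
#' A time point is flagged significant when the central 95\% interval
#' excludes zero.  In \code{mode = "interaction"} the contrast is instead
#' between the stressed mutant's growth with and without the interaction
#' term (the stress response beyond what strain and stress explain
#' separately).
#'
#' @param model a \code{gp_fit} whose design supports the contrast
#'   (\code{strain} column for \code{"strain"}; \code{interaction} column
#'   for \code{"interaction"}).
#' @param times evaluation times; the start time t_0 is prepended when
#'   absent.
#' @param mode \code{"strain"} or \code{"interaction"}.
#' @param at fixed values for design columns not involved in the
#'   contrast (default: stress = 0 in strain mode).
#' @param level credible level (default 0.95).
#' @return data frame of class \code{od_delta_series}: time, mean,
#'   variance, ci_low, ci_high, significant.  The value at t_0 is exactly
#'   0 with zero variance by construction.
#' @export
od_delta <- function(model, times, mode = c("strain", "interaction"),
                     at = NULL, level = 0.95) {
  mode <- match.arg(mode)
  stopifnot(inherits(model, "gp_fit"))
  need <- if (mode == "strain") "strain" else "interaction"
  if (!need %in% model$design)
    stop("model design lacks the '", need, "' column required for this contrast",
         call. = FALSE)
  t0 <- min(model$X[, 1])
  times <- sort(unique(c(t0, times)))
  Tn <- length(times)
  base <- stats::setNames(rep(0, length(model$design)), model$design)
  if (!is.null(at)) base[names(at)] <- unlist(at)
  mk <- function(flag) {
    v <- base
    if (mode == "strain") {
      v["strain"] <- flag
      if (all(c("interaction", "stress") %in% model$design))
        v["interaction"] <- v["strain"] * v["stress"]
    } else {
      v["strain"] <- 1; v["stress"] <- 1; v["interaction"] <- flag
    }
    X <- cbind(times, matrix(rep(v[-1], each = Tn), nrow = Tn))
    colnames(X) <- model$design
    X
  }
  Xstar <- rbind(mk(1), mk(0))   # rows 1..Tn: "on" arm; Tn+1..2Tn: "off" arm
  post <- predict_posterior(model, Xstar, include_noise = FALSE)
  i0 <- which(times == t0)
  mu <- post$mean; S <- post$cov
  out <- data.frame(time = times, mean = NA_real_, variance = NA_real_)
  for (k in seq_len(Tn)) {
    idx <- c(k, i0, Tn + k, Tn + i0)
    a <- c(1, -1, -1, 1)
    out$mean[k] <- sum(a * mu[idx])
    out$variance[k] <- max(as.numeric(a %*% S[idx, idx] %*% a), 0)
  }
  z <- stats::qnorm(1 - (1 - level) / 2)
  sd <- sqrt(out$variance)
  out$ci_low <- out$mean - z * sd
  out$ci_high <- out$mean + z * sd
  out$significant <- out$ci_low > 0 | out$ci_high < 0
  structure(out, class = c("od_delta_series", "data.frame"),
            mode = mode, level = level)
}

#' Hypergeometric enrichment test
#'
#' Upper-tail probability that a random draw of \code{drawn} items from a
#' population containing \code{successes_in_population} marked items
#' would contain at least \code{successes_drawn} marked ones.
#'
#' @param population total population size.
#' @param successes_in_population marked items in the population.
#' @param drawn number of items drawn.
#' @param successes_drawn marked items observed in the draw.
#' @return p-value \eqn{P(X \ge successes\_drawn)}.
#' @export
enrichment_test <- function(population, successes_in_population, drawn,
                            successes_drawn) {
  if (successes_in_population > population || drawn > population ||
      successes_drawn > min(drawn, successes_in_population) ||
      any(c(population, successes_in_population, drawn, successes_drawn) < 0))
    stop("inconsistent hypergeometric counts", call. = FALSE)
  stats::phyper(successes_drawn - 1, successes_in_population,
                population - successes_in_population, drawn,
                lower.tail = FALSE)
}
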