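#' Specification of a synthetic growth dataset
#'
#' Describes a generative model emulating a plate-reader experiment:
#' Gompertz-shaped log2-OD trajectories for a parent and (optionally) a
#' mutant strain under a control and (optionally) a stress condition,
#' with multiplicative strain/stress/interaction effects on the Gompertz
#' parameters, optional additive post-inoculation offsets, an optional
#' post-peak linear decline emulating non-sigmoid stress kinetics,
#' smooth per-batch offsets drawn from a long-lengthscale GP, and IID
#' Gaussian observation noise.
#'
#' Defaults mirror a 48-h experiment sampled every 30 min with 12
#' replicates per (strain, condition) arm, a carrying capacity of 2
#' log2 units, a maximum specific growth rate of 0.3/h and a 5-h lag.
#'
#' @param A,mu_max,lam baseline Gompertz parameters.
#' @param timegrid sampling times, hours.
#' @param n_replicates replicates per (strain, condition, batch) arm.
#' @param noise_sd standard deviation of the IID Gaussian noise on
#'   log2-OD.
#' @param strains strain labels; the first is the parent.
#' @param conditions condition labels; the first is the control.
#' @param strain_effect,stress_effect,interaction_effect lists with any
#'   of \code{A_factor}, \code{mu_factor} (multiplicative, applied to the
#'   mutant / stressed / stressed-mutant arm), \code{delta} (additive
#'   log2 offset for t > 0), \code{decline_rate} (per-hour linear decline
#'   after \code{decline_onset} hours; produces the non-sigmoid
#'   "rise-then-fall" stress shape).
#' @param n_batches number of batches; offsets are added when > 1 or
#'   \code{batch_amplitude} is set explicitly.
#' @param batch_amplitude,batch_lengthscale amplitude (log2 units) and
#'   lengthscale (hours) of the GP-drawn smooth batch offsets.
#' @param batch_offset_scope \code{"batch"}: one smooth offset per batch,
#'   applied to every arm (instrument/media recalibration);
#'   \code{"arm"}: an independent smooth offset per
#'   (batch, strain, condition) arm (condition-specific study effects).
#' @param batch_offset_funs optional list of deterministic offset
#'   functions, one per batch (e.g. equal and opposite smooth offsets);
#'   overrides the GP-drawn offsets when supplied.  Each function takes
#'   either \code{(t)} or \code{(t, is_mutant, is_stress)}, the latter
#'   allowing arm-specific study effects such as an offset confined to
#'   the stressed-mutant arm.
#' @return object of class \code{synthetic_spec}.
#' @export
synthetic_spec <- function(A = 2, mu_max = 0.3, lam = 5,
                           timegrid = seq(0, 47.5, by = 0.5),
                           n_replicates = 12, noise_sd = 0.05,
                           strains = c("parent", "mutant"),
                           conditions = "standard",
                           strain_effect = list(),
                           stress_effect = list(),
                           interaction_effect = list(),
                           n_batches = 1, batch_amplitude = 0.3,
                           batch_lengthscale = 12,
                           batch_offset_scope = c("batch", "arm"),
                           batch_offset_funs = NULL) {
  batch_offset_scope <- match.arg(batch_offset_scope)
  if (!is.null(batch_offset_funs) && length(batch_offset_funs) != n_batches)
    stop("need one batch offset function per batch", call. = FALSE)
  stopifnot(noise_sd >= 0, all(diff(timegrid) > 0), n_replicates >= 1)
  eff <- function(e) {
    utils::modifyList(list(A_factor = 1, mu_factor = 1, delta = 0,
                           decline_rate = 0, decline_onset = 24), e)
  }
  structure(list(
    A = A, mu_max = mu_max, lam = lam, timegrid = timegrid,
    n_replicates = n_replicates, noise_sd = noise_sd,
    strains = strains, conditions = conditions,
    strain_effect = eff(strain_effect), stress_effect = eff(stress_effect),
    interaction_effect = eff(interaction_effect),
    n_batches = n_batches, batch_amplitude = batch_amplitude,
    batch_lengthscale = batch_lengthscale,
    batch_offset_scope = batch_offset_scope,
    batch_offset_funs = batch_offset_funs
  ), class = "synthetic_spec")
}

# True mean log2-OD trajectory for one (strain, condition) arm.
true_mean_curve <- function(spec, t, is_mutant, is_stress) {
  A <- spec$A; mu <- spec$mu_max
  add <- rep(0, length(t))
  apply_eff <- function(e) {
    A <<- A * e$A_factor
    mu <<- mu * e$mu_factor
    add <<- add + e$delta * (t > 0) -
      e$decline_rate * pmax(t - e$decline_onset, 0)
  }
  if (is_mutant) apply_eff(spec$strain_effect)
  if (is_stress) apply_eff(spec$stress_effect)
  if (is_mutant && is_stress) apply_eff(spec$interaction_effect)
  gompertz(t, A, mu, spec$lam) + add
}

# Smooth random offset: one draw from a zero-mean GP with an RBF kernel.
smooth_offset <- function(t, amplitude, lengthscale) {
  ks <- kernel_spec("rbf", variance = amplitude^2,
                    lengthscales = lengthscale, nugget = 0)
  K <- kernel_matrix(ks, matrix(t, ncol = 1), nugget = FALSE)
  R <- chol_jitter(K + diag(1e-10, length(t)))
  as.numeric(crossprod(R, stats::rnorm(length(t))))
}

#' Simulate a growth dataset with known ground truth
#'
#' @param spec a \code{synthetic_spec}.
#' @param seed integer seed; the output is deterministic given
#'   (spec, seed).
#' @return a log-scale growth table (\code{is_log = TRUE}) with columns
#'   time, od, replicate, strain, condition (and batch when
#'   \code{n_batches > 1}).  The true mean curves are attached as
#'   attribute \code{"truth"} (data frame: strain, condition, time,
#'   mean).
#' @export
simulate_dataset <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "synthetic_spec"))
  t <- spec$timegrid
  batches <- seq_len(spec$n_batches)
  rows <- list()
  truth <- list()
  with_seed(seed, {
    for (b in batches) {
      has_offsets <- spec$n_batches > 1 &&
        (spec$batch_amplitude > 0 || !is.null(spec$batch_offset_funs))
      offset_fun <- if (is.null(spec$batch_offset_funs)) NULL else
        spec$batch_offset_funs[[b]]
      batch_offset <- if (!is.null(offset_fun) && length(formals(offset_fun)) == 1) {
        offset_fun(t)
      } else if (is.null(offset_fun) && has_offsets &&
                 spec$batch_offset_scope == "batch") {
        smooth_offset(t, spec$batch_amplitude, spec$batch_lengthscale)
      } else rep(0, length(t))
      for (s in spec$strains) {
        for (cond in spec$conditions) {
          is_mut <- s != spec$strains[1]
          is_str <- cond != spec$conditions[1]
          offset <- if (!is.null(offset_fun) && length(formals(offset_fun)) > 1) {
            offset_fun(t, is_mut, is_str)
          } else if (is.null(offset_fun) && has_offsets &&
                     spec$batch_offset_scope == "arm") {
            smooth_offset(t, spec$batch_amplitude, spec$batch_lengthscale)
          } else batch_offset
          m <- true_mean_curve(spec, t, is_mutant = is_mut, is_stress = is_str)
          if (b == batches[1]) {
            truth[[length(truth) + 1]] <- data.frame(
              strain = s, condition = cond, time = t, mean = m)
          }
          for (r in seq_len(spec$n_replicates)) {
            noise <- if (spec$noise_sd > 0) {
              stats::rnorm(length(t), 0, spec$noise_sd)
            } else 0
            rows[[length(rows) + 1]] <- data.frame(
              time = t, od = m + offset + noise,
              replicate = sprintf("r%02d", r), strain = s,
              condition = cond, batch = sprintf("batch%d", b))
          }
        }
      }
    }
  })
  out <- do.call(rbind, rows)
  if (spec$n_batches == 1) out$batch <- NULL
  if (length(spec$conditions) == 1) out$condition <- NULL
  tab <- growth_table(out, is_log = TRUE)
  attr(tab, "truth") <- do.call(rbind, truth)
  tab
}

#' Simulate a matched null pair of strains
#'
#' Two strains drawn from the identical generative process (all effect
#' terms neutral): the reference dataset for permutation-test
#' calibration.
#'
#' @param spec a \code{synthetic_spec}; its effect terms are ignored.
#' @param seed integer seed.
#' @return a growth table with strains \code{"parent"} and
#'   \code{"mutant"} sharing the same true mean curve.
#' @export
simulate_null_pair <- function(spec, seed = 1L) {
  nspec <- spec
  nspec$strains <- c("parent", "mutant")
  nspec$strain_effect <- synthetic_spec()$strain_effect
  nspec$interaction_effect <- synthetic_spec()$interaction_effect
  simulate_dataset(nspec, seed = seed)
}
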