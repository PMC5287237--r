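# Shared fixture builders.  All fixtures are generated in code at test
# time; seeds are fixed so the suite is deterministic.

# One clean growth curve as a log-scale growth table.
single_curve <- function(A = 2, mu_max = 0.3, lam = 5, noise_sd = 0,
                         times = seq(0, 47.5, by = 1), seed = 1) {
  sp <- synthetic_spec(A = A, mu_max = mu_max, lam = lam, timegrid = times,
                       n_replicates = 1, strains = "s1", noise_sd = noise_sd)
  simulate_dataset(sp, seed = seed)
}

# Stress-shaped single curve: sigmoid rise then linear decline.
stress_curve <- function(seed, noise_sd = 0.03) {
  sp <- synthetic_spec(timegrid = seq(0, 47.5, by = 1), n_replicates = 1,
                       strains = "s1", conditions = c("standard", "stress"),
                       stress_effect = list(decline_rate = 0.06,
                                            decline_onset = 20),
                       noise_sd = noise_sd)
  tab <- simulate_dataset(sp, seed = seed)
  sub <- tab[tab$condition == "stress", , drop = FALSE]
  structure(sub, class = class(tab), is_log = TRUE)
}

# Parent/mutant pair on the paper-style 4-h grid.
effect_pair <- function(seed, mu_factor = 0.5, n_replicates = 12) {
  sp <- synthetic_spec(timegrid = seq(0, 44, by = 4),
                       n_replicates = n_replicates,
                       strain_effect = list(mu_factor = mu_factor))
  simulate_dataset(sp, seed = seed)
}

null_pair <- function(seed, n_replicates = 6) {
  sp <- synthetic_spec(timegrid = seq(0, 44, by = 4),
                       n_replicates = n_replicates)
  simulate_null_pair(sp, seed = seed)
}

# Two-batch cross-study dataset: equal and opposite smooth study offsets
# applied to every arm, with a late-decline interaction present in both
# batches.  This is the regime where the pooled stress test is swamped by
# the study effects while the hierarchical test retains power.
masked_interaction_tab <- function(seed, amplitude = 0.8,
                                   decline_rate = 0.01, noise_sd = 0.03) {
  off <- function(s) function(t) s * amplitude * sin(pi * t / 44)
  sp <- synthetic_spec(timegrid = seq(0, 42, by = 6), n_replicates = 12,
                       conditions = c("standard", "stress"),
                       stress_effect = list(mu_factor = 0.8),
                       interaction_effect = list(decline_rate = decline_rate,
                                                 decline_onset = 18),
                       noise_sd = noise_sd, n_batches = 2,
                       batch_offset_funs = list(off(1), off(-1)))
  simulate_dataset(sp, seed = seed)
}

# Two-batch dataset with +-0.4 opposite offsets (the batch-recovery
# fixture) and moderate arm structure.
opposite_offset_tab <- function(seed, amplitude = 0.4, noise_sd = 0.05) {
  off <- function(s) function(t) s * amplitude * sin(pi * t / 44)
  sp <- synthetic_spec(timegrid = seq(0, 42, by = 6), n_replicates = 6,
                       conditions = c("standard", "stress"),
                       stress_effect = list(mu_factor = 0.8),
                       interaction_effect = list(mu_factor = 0.6,
                                                 decline_rate = 0.03),
                       noise_sd = noise_sd, n_batches = 2,
                       batch_offset_funs = list(off(1), off(-1)))
  simulate_dataset(sp, seed = seed)
}

# Brute-force MVN log-density via explicit inverse and determinant --
# deliberately a different code path from the package's Cholesky /
# grouped computations.
mvn_logpdf_bruteforce <- function(y, K) {
  n <- length(y)
  -0.5 * as.numeric(t(y) %*% solve(K) %*% y) -
    0.5 * as.numeric(determinant(K, logarithm = TRUE)$modulus) -
    0.5 * n * log(2 * pi)
}
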