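# Shared fixtures: all data is generated in code, nothing is read from disk.

# standard two-group design used by the recovery and error-rate harnesses:
# 12 samples in two groups of six, shared replicate batches
two_group_config <- function(seed, n_features = 500L, n_signal = 10L,
                             effect_size = 2, ...) {
  sim_config(n_groups = 2L, n_reps_per_group = 6L, n_features = n_features,
             n_signal = n_signal, effect_size = effect_size, seed = seed, ...)
}

# generate, batch-correct and return the pieces most tests need
corrected_two_group <- function(seed, ...) {
  sim <- simulate_dataset(two_group_config(seed, ...))
  adj <- correct_batch(sim$data, fit_batch_lmm(sim$data))
  list(adj = adj, truth = sim$truth, cmp = build_comparisons(adj)[[1L]])
}

# rank AUC of pip for signal vs null features (Wilcoxon statistic scaled)
pip_rank_auc <- function(summary, truth) {
  is_sig <- summary$feature_id %in% truth$signal_ids
  w <- wilcox.test(summary$pip[is_sig], summary$pip[!is_sig],
                   exact = FALSE)$statistic
  unname(w / (sum(is_sig) * sum(!is_sig)))
}

# small deterministic intensity matrix built by hand
toy_matrix <- function(K = 3L, groups = c("A", "B"), reps = 2L, seed = 1L) {
  set.seed(seed)
  samples <- data.frame(
    sample_id = paste0(rep(groups, each = reps), rep(seq_len(reps), length(groups))),
    group = rep(groups, each = reps),
    genotype = NA_character_, treatment = NA_character_,
    replicate = rep(seq_len(reps), length(groups)),
    stringsAsFactors = FALSE
  )
  vals <- matrix(rnorm(K * nrow(samples), 20), K, nrow(samples),
                 dimnames = list(sprintf("p%02d", seq_len(K)),
                                 samples$sample_id))
  intensity_matrix(vals, samples)
}
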