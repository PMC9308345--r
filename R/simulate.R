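#' Simulation configuration for synthetic proteomics datasets
#'
#' Describes a balanced factorial quantitative-proteomics design on the
#' log-intensity scale with crossed replicate and protein-by-replicate
#' random effects, Gaussian residual noise, and a sparse set of
#' group-associated proteins.  The generative model for protein \eqn{k} in
#' group \eqn{g}, replicate \eqn{j} is
#' \deqn{y_{kgj} = \mu + \delta_k \, 1[g \in \mathrm{affected}]
#'   + b_j + s_{kj} + e_{kgj},}
#' with \eqn{b_j \sim N(0, \sigma_r^2)}, \eqn{s_{kj} \sim N(0, \sigma_s^2)},
#' \eqn{e_{kgj} \sim N(0, \sigma_e^2)}.  Replicate index \eqn{j} is shared
#' across groups (the j-th replicates of all groups form one processing
#' batch), so \eqn{b_j} and \eqn{s_{kj}} act as batch effects.
#'
#' With `n_groups = 4` the groups form the 2x2 genotype-by-treatment
#' factorial labelled RCK, MCK, R400, M400 and signal proteins differ
#' between genotypes (R vs M); otherwise the first group carries the shift.
#' Half of the signal proteins are shifted by `+effect_size`, half by
#' `-effect_size`.
#'
#' @param n_groups Number of sample groups (default 4, the 2x2 factorial).
#' @param n_reps_per_group Biological replicates per group (default 3).
#' @param n_features Number of protein features (default 500; use 3000 for
#'   a full-scale dataset).
#' @param n_signal Number of truly group-associated proteins (default 10).
#' @param effect_size Absolute log-intensity shift carried by each signal
#'   protein (default 2, i.e. twice the default residual SD).
#' @param sigma_r SD of the replicate (batch) random effect (default 0.3).
#' @param sigma_s SD of the protein-by-replicate random effect (default 0.5).
#' @param sigma_e Residual SD (default 1).
#' @param baseline_mean Grand mean log-intensity (default 20).
#' @param seed Integer RNG seed; required, there is no implicit default.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_groups = 4L, n_reps_per_group = 3L,
                       n_features = 500L, n_signal = 10L, effect_size = 2,
                       sigma_r = 0.3, sigma_s = 0.5, sigma_e = 1,
                       baseline_mean = 20, seed) {
  if (missing(seed) || is.null(seed)) {
    stop("`seed` is required: simulations must be explicitly reproducible")
  }
  cfg <- list(
    n_groups = as.integer(n_groups),
    n_reps_per_group = as.integer(n_reps_per_group),
    n_features = as.integer(n_features),
    n_signal = as.integer(n_signal),
    effect_size = as.numeric(effect_size),
    sigma_r = as.numeric(sigma_r), sigma_s = as.numeric(sigma_s),
    sigma_e = as.numeric(sigma_e),
    baseline_mean = as.numeric(baseline_mean),
    seed = as.integer(seed)
  )
  if (cfg$n_groups < 1L || cfg$n_reps_per_group < 1L || cfg$n_features < 1L) {
    stop("n_groups, n_reps_per_group and n_features must all be >= 1")
  }
  if (cfg$n_signal < 0L) stop("n_signal must be >= 0")
  if (cfg$n_signal > cfg$n_features) {
    stop("n_signal (", cfg$n_signal, ") cannot exceed n_features (",
         cfg$n_features, ")")
  }
  if (cfg$sigma_r < 0 || cfg$sigma_s < 0 || cfg$sigma_e < 0) {
    stop("all SDs must be >= 0")
  }
  structure(cfg, class = "sim_config")
}

group_labels <- function(n_groups) {
  if (n_groups == 4L) {
    data.frame(group = c("RCK", "MCK", "R400", "M400"),
               genotype = c("R", "M", "R", "M"),
               treatment = c("CK", "CK", "400", "400"),
               stringsAsFactors = FALSE)
  } else {
    data.frame(group = paste0("G", seq_len(n_groups)),
               genotype = NA_character_, treatment = NA_character_,
               stringsAsFactors = FALSE)
  }
}

#' Generate a synthetic log-intensity dataset with known ground truth
#'
#' Draws one dataset from the generative model described in
#' [sim_config()].  The returned truth object records which proteins carry
#' a group effect and the realized random-effect draws, enabling
#' parameter-recovery and error-rate testing of every downstream stage.
#'
#' @param config A [sim_config()] object.
#' @return A list with elements `data` (an [intensity_matrix()]) and
#'   `truth` (class `sim_truth`: `signal_ids`, `true_effects`, `true_b`,
#'   `true_s`, `group_assignment`).
#' @examples
#' sim <- simulate_dataset(sim_config(n_features = 50, seed = 1))
#' dim(sim$data$values)
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  G <- config$n_groups; J <- config$n_reps_per_group; K <- config$n_features
  lab <- group_labels(G)

  samples <- data.frame(
    sample_id = paste0(rep(lab$group, each = J), "_", rep(seq_len(J), G)),
    group = rep(lab$group, each = J),
    genotype = rep(lab$genotype, each = J),
    treatment = rep(lab$treatment, each = J),
    replicate = rep(seq_len(J), G),
    stringsAsFactors = FALSE
  )
  n <- nrow(samples)
  feature_ids <- sprintf("prot%04d", seq_len(K))

  # affected groups carry the signal shift: genotype axis for the factorial,
  # the first group otherwise
  affected <- if (G == 4L) lab$group[lab$genotype == "R"] else lab$group[1L]
  affected_sample <- samples$group %in% affected

  b <- rnorm(J, 0, config$sigma_r)                       # replicate batches
  s <- matrix(rnorm(K * J, 0, config$sigma_s), K, J)     # protein x replicate
  e <- matrix(rnorm(K * n, 0, config$sigma_e), K, n)

  effects <- numeric(0)
  signal_ids <- character(0)
  if (config$n_signal > 0L) {
    idx <- sample.int(K, config$n_signal)
    n_up <- ceiling(config$n_signal / 2)
    effects <- rep(c(config$effect_size, -config$effect_size),
                   c(n_up, config$n_signal - n_up))
    signal_ids <- feature_ids[idx]
    names(effects) <- signal_ids
  }

  values <- matrix(config$baseline_mean, K, n,
                   dimnames = list(feature_ids, samples$sample_id))
  if (length(signal_ids)) {
    values[match(signal_ids, feature_ids), affected_sample] <-
      values[match(signal_ids, feature_ids), affected_sample] + effects
  }
  values <- values + matrix(b[samples$replicate], K, n, byrow = TRUE) +
    s[, samples$replicate, drop = FALSE] + e

  dimnames(s) <- list(feature_ids, paste0("rep", seq_len(J)))
  truth <- structure(list(
    signal_ids = signal_ids,
    true_effects = effects,
    true_b = setNames(b, paste0("rep", seq_len(J))),
    true_s = s,
    group_assignment = setNames(samples$group, samples$sample_id)
  ), class = "sim_truth")

  list(data = intensity_matrix(values, samples), truth = truth)
}

#' Generate a global-null synthetic dataset
#'
#' Identical to [simulate_dataset()] with `n_signal` forced to zero; used by
#' the type-I-error and false-discovery-rate test harnesses.
#'
#' @inheritParams simulate_dataset
#' @return As [simulate_dataset()]; `truth$signal_ids` is empty.
#' @export
simulate_null_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  config$n_signal <- 0L
  simulate_dataset(config)
}

#' Write the ground-truth sidecar of a simulated dataset as JSON
#'
#' @param truth A `sim_truth` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sim_truth <- function(truth, path) {
  stopifnot(inherits(truth, "sim_truth"))
  obj <- list(
    signal_ids = truth$signal_ids,
    true_effects = as.list(truth$true_effects),
    true_b = as.list(truth$true_b),
    true_s = as.data.frame(truth$true_s),
    group_assignment = as.list(truth$group_assignment)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
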