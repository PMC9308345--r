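#' Control settings for the spike-and-slab Bayesian route
#'
#' The model is Bayesian logistic regression with, per protein, the
#' spike-and-slab prior
#' \eqn{P(\beta_j | \gamma_j) = (1-\gamma_j)\,\delta_0 + \gamma_j\,
#' N(0, \sigma_j^2)}, a fixed Bernoulli prior inclusion probability
#' \eqn{w} on \eqn{\gamma_j}, and an Inverse-Gamma(a, b) prior on each
#' slab variance.  Polya-Gamma augmentation renders the logistic
#' likelihood conditionally Gaussian so every conditional is exact and the
#' sampler is a pure Gibbs scheme (no accept/reject moves).
#'
#' @param w_prior Prior inclusion probability in \[0, 1\] (default 0.05,
#'   reflecting that only a small fraction of proteins is expected to be
#'   associated).
#' @param a_hyper,b_hyper Inverse-Gamma shape and rate (default 0.1 and
#'   0.1, non-informative).
#' @param n_iter Total Gibbs sweeps (default 5000).
#' @param n_burnin Discarded initial sweeps (default 1000).
#' @param thin Thinning interval (default 1).
#' @param intercept_var Gaussian prior variance of the always-included
#'   intercept (default 100, diffuse).
#' @param standardize Standardize features within the comparison (default
#'   `TRUE`).
#' @param slab How the slab-variance prior enters the coefficient updates.
#'   `"conditional"` (default) redraws each per-protein variance from its
#'   Inverse-Gamma full conditional every sweep (the prior when the
#'   protein is excluded).  `"marginal"` additionally integrates the slab
#'   variance out of the inclusion odds alongside the coefficient, via an
#'   `n_nodes`-point quantile discretization of the prior.  `"shared"`
#'   pools a single sampled variance across proteins.
#' @param n_nodes Number of quadrature atoms for `slab = "marginal"`.
#' @param sigma2_max Upper truncation of the slab-variance prior, on the
#'   standardized-feature scale (default 25, i.e. slab SD at most 5;
#'   coefficients are log-abundance contrasts per feature SD, so larger
#'   scales are implausible).  With an unbounded heavy-tailed slab and far
#'   more candidate proteins than samples, the posterior places real mass
#'   on configurations whose huge coefficients separate the two groups
#'   perfectly, saturating the likelihood and decoupling selection from
#'   the data; the truncation removes that degenerate region.  `Inf`
#'   disables the truncation.
#' @param seed RNG seed; the whole chain is a deterministic function of it.
#' @return An object of class `ssvs_control`.
#' @export
ssvs_control <- function(w_prior = 0.05, a_hyper = 0.1, b_hyper = 0.1,
                         n_iter = 5000L, n_burnin = 1000L, thin = 1L,
                         intercept_var = 100, standardize = TRUE,
                         slab = c("conditional", "marginal", "shared"),
                         n_nodes = 64L, sigma2_max = 25, seed = 1L) {
  stopifnot(w_prior >= 0, w_prior <= 1, a_hyper > 0, b_hyper > 0,
            n_burnin < n_iter, thin >= 1L, intercept_var > 0, n_nodes >= 4L,
            sigma2_max > 0)
  slab <- match.arg(slab)
  structure(list(w_prior = w_prior, a_hyper = a_hyper, b_hyper = b_hyper,
                 n_iter = as.integer(n_iter), n_burnin = as.integer(n_burnin),
                 thin = as.integer(thin), intercept_var = intercept_var,
                 standardize = standardize, slab = slab,
                 n_nodes = as.integer(n_nodes), sigma2_max = sigma2_max,
                 seed = as.integer(seed)),
            class = "ssvs_control")
}

#' Draw from the Polya-Gamma distribution
#'
#' Exact draws from PG(b, c) for integer shape `b` via a Devroye-type
#' alternating-series rejection sampler (summed over `b` for shapes above
#' one, using the convolution property of the family); non-integer shapes
#' fall back to a truncated sum-of-gammas representation.  The mean of
#' PG(b, c) is \eqn{(b/2c)\tanh(c/2)}, reducing to \eqn{b/4} at c = 0.
#'
#' @param n Number of draws.
#' @param b Shape parameter, > 0.
#' @param c Tilt parameter (recycled across draws).
#' @param nterms Series length of the non-integer-shape fallback.
#' @return Numeric vector of `n` positive draws.
#' @export
rpolyagamma <- function(n, b = 1, c = 0, nterms = 200L) {
  if (!is.numeric(b) || length(b) != 1L || b <= 0) {
    stop("shape parameter b must be a positive scalar")
  }
  if (abs(b - round(b)) < 1e-12) {
    .rpg_devroye_cpp(as.integer(n), as.integer(round(b)), as.numeric(c))
  } else {
    .rpg_gamma_sum_cpp(as.integer(n), b, as.numeric(c), as.integer(nterms))
  }
}

#' Run the Polya-Gamma Gibbs sampler for spike-and-slab selection
#'
#' One Gibbs sweep consists of (1) a PG(1, eta_i) draw per sample given
#' the linear predictor, (2) the intercept's Gaussian conditional and, in
#' fixed feature order, each (beta_j, gamma_j) pair drawn from its exact
#' spike-and-slab conditional (Bernoulli inclusion odds with beta_j
#' marginalized analytically, then a Gaussian draw when included), and
#' (3) truncated Inverse-Gamma slab-variance updates (reducing to the
#' prior for excluded proteins, which keeps the chain irreducible).
#' Excluded proteins have beta_j exactly 0 in every draw.  See
#' [ssvs_control()] for the slab-handling schemes and the rationale for
#' the slab-scale truncation.
#'
#' @param data An [intensity_matrix()], normally batch-corrected.
#' @param cmp A comparison from [build_comparisons()].
#' @param control An [ssvs_control()].
#' @param fixed_phi Optional fixed Polya-Gamma latents (diagnostic hook:
#'   substitutes a Gaussian likelihood with known weights for the PG step).
#' @param update_sigma2 Diagnostic hook; `FALSE` freezes the slab
#'   variances at `sigma2_init`.
#' @param sigma2_init Initial slab variances (recycled; default 1).
#' @return An object of class `ssvs_draws` with matrices `beta`, `gamma`,
#'   `sigma2` (kept sweeps by protein), vector `beta0`, final `phi`,
#'   `feature_ids` and the `control` used.
#' @export
run_ssvs <- function(data, cmp, control = ssvs_control(),
                     fixed_phi = NULL, update_sigma2 = TRUE,
                     sigma2_init = 1) {
  stopifnot(inherits(control, "ssvs_control"))
  des <- comparison_design(data, cmp)
  X <- t(data$values[, des$idx, drop = FALSE])
  y <- des$y
  sds <- apply(X, 2L, sd)
  drop <- sds < 1e-12
  if (any(drop)) {
    warning(sum(drop), " constant feature(s) excluded from the SSVS fit")
    X <- X[, !drop, drop = FALSE]
    sds <- sds[!drop]
  }
  if (control$standardize) X <- scale(X, center = TRUE, scale = sds)

  set.seed(control$seed)
  res <- .ssvs_gibbs_cpp(X, as.integer(y), control$w_prior, control$a_hyper,
                         control$b_hyper, control$n_iter, control$n_burnin,
                         control$thin, control$intercept_var, fixed_phi,
                         update_sigma2, as.numeric(sigma2_init),
                         match(control$slab,
                               c("marginal", "conditional", "shared")) - 1L,
                         control$n_nodes, control$sigma2_max)
  colnames(res$beta) <- colnames(X)
  colnames(res$gamma) <- colnames(X)
  colnames(res$sigma2) <- colnames(X)
  structure(list(beta = res$beta, gamma = res$gamma, sigma2 = res$sigma2,
                 beta0 = drop(res$beta0), phi = drop(res$phi),
                 feature_ids = colnames(X), control = control,
                 comparison = cmp$name, axis = cmp$axis),
            class = "ssvs_draws")
}

# effective sample size by the initial-positive-sequence autocorrelation rule
chain_ess <- function(x, max_lag = 50L) {
  n <- length(x)
  if (var(x) == 0) return(n)
  rho <- drop(acf(x, lag.max = min(max_lag, n - 1L), plot = FALSE,
                  demean = TRUE)$acf)[-1L]
  neg <- which(rho < 0)
  if (length(neg)) rho <- rho[seq_len(neg[1L] - 1L)]
  n / (1 + 2 * sum(rho))
}

#' Summarize SSVS draws into posterior inclusion probabilities
#'
#' The posterior inclusion probability of a protein is the mean of its
#' retained inclusion-indicator draws; the posterior effect is the mean of
#' its coefficient draws conditional on inclusion (0 for a protein that
#' was never included).
#'
#' @param draws An [run_ssvs()] result with at least 100 retained sweeps.
#' @return A data frame of class `ssvs_summary`: `feature_id`, `pip`,
#'   `post_mean_beta`, `ess` (effective sample size of the indicator
#'   chain).
#' @export
compute_pip <- function(draws) {
  stopifnot(inherits(draws, "ssvs_draws"))
  n_kept <- nrow(draws$gamma)
  if (is.null(n_kept) || n_kept < 100L) {
    stop("need at least 100 retained sweeps to summarize (got ",
         n_kept %||% 0L, ")")
  }
  pip <- colMeans(draws$gamma)
  post_mean <- vapply(seq_along(pip), function(j) {
    inc <- draws$gamma[, j] == 1L
    if (!any(inc)) 0 else mean(draws$beta[inc, j])
  }, numeric(1))
  ess <- vapply(seq_along(pip), function(j) chain_ess(draws$gamma[, j]),
                numeric(1))
  structure(data.frame(feature_id = draws$feature_ids, pip = pip,
                       post_mean_beta = post_mean, ess = ess,
                       row.names = NULL, stringsAsFactors = FALSE),
            class = c("ssvs_summary", "data.frame"),
            comparison = draws$comparison, axis = draws$axis)
}
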