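#' Fit the crossed-random-effects batch model by maximum likelihood
#'
#' Fits, to a balanced group-by-replicate design, the linear mixed model
#' \deqn{y_{kgj} = \mu_{kg} + b_j + s_{kj} + e_{kgj},}
#' where \eqn{\mu_{kg}} are fixed feature-by-group means, \eqn{b_j \sim
#' N(0,\sigma_r^2)} is a replicate (batch) effect shared by all features,
#' \eqn{s_{kj} \sim N(0,\sigma_s^2)} is a feature-by-replicate interaction,
#' and \eqn{e_{kgj} \sim N(0,\sigma_e^2)}.  Estimation is full maximum
#' likelihood (not REML).
#'
#' Balance makes the likelihood separable over three orthogonal subspaces
#' (within-cell interaction contrasts; feature deviations of the
#' replicate-mean table; replicate means of that table), so the ML estimates
#' have closed form up to non-negativity constraints and no iterative
#' optimizer is needed.  BLUPs (posterior means) of \eqn{b_j} and
#' \eqn{s_{kj}} are evaluated at the ML variance components.
#'
#' @param data An [intensity_matrix()] whose metadata forms a complete
#'   group-by-replicate grid with at least 2 groups, 2 replicates and 2
#'   features.
#' @return An object of class `batch_model_fit` with elements
#'   `fixed_effects` (feature-by-group means), `blup_b` (per replicate),
#'   `blup_s` (feature-by-replicate matrix), `var_r`, `var_s`, `var_e`,
#'   and `loglik`.
#' @export
fit_batch_lmm <- function(data) {
  stopifnot(inherits(data, "intensity_matrix"))
  Y <- data$values
  meta <- data$samples
  K <- nrow(Y)
  groups <- unique(meta$group)
  reps <- sort(unique(meta$replicate))
  G <- length(groups); J <- length(reps)
  if (K < 2L) stop("need at least 2 features")
  if (G < 2L) stop("need at least 2 groups")
  if (J < 2L) stop("single-replicate design: replicate variance is unidentifiable")
  tab <- table(factor(meta$group, groups), factor(meta$replicate, reps))
  if (any(tab != 1L)) {
    stop("design must be a complete balanced group x replicate grid")
  }
  g_of <- match(meta$group, groups)
  j_of <- match(meta$replicate, reps)

  # replicate-mean table C (K x J): average over groups within a replicate
  C <- vapply(seq_len(J),
              function(j) rowMeans(Y[, j_of == j, drop = FALSE]),
              numeric(K))
  # feature-by-group cell means (the GLS = OLS fixed effects under balance)
  M <- vapply(seq_len(G),
              function(g) rowMeans(Y[, g_of == g, drop = FALSE]),
              numeric(K))
  colnames(M) <- groups
  ybar <- rowMeans(Y)

  resid_int <- Y - C[, j_of, drop = FALSE] - M[, g_of, drop = FALSE] + ybar
  SS_int <- sum(resid_int^2)

  r <- C - rowMeans(C)
  m_j <- colMeans(r)
  d <- sweep(r, 2L, m_j)
  SS_d <- sum(d^2)
  SS_b <- K * sum(m_j^2)

  sigma_e2 <- SS_int / (K * (G - 1) * J)
  tau1 <- SS_d / (J * (K - 1))
  tau2 <- SS_b / J
  sigma_s2 <- tau1 - sigma_e2 / G
  sigma_r2 <- (tau2 - tau1) / K

  # non-negativity boundaries: re-maximize jointly with the component pinned
  if (sigma_s2 < 0) {
    sigma_s2 <- 0
    sigma_e2 <- (SS_int + G * SS_d) / (K * (G - 1) * J + J * (K - 1))
    sigma_r2 <- (tau2 - sigma_e2 / G) / K
    if (sigma_r2 < 0) {
      sigma_r2 <- 0
      sigma_e2 <- (SS_int + G * SS_d + G * SS_b) /
        (K * (G - 1) * J + J * (K - 1) + J)
    }
  } else if (sigma_r2 < 0) {
    sigma_r2 <- 0
    tau1_c <- (SS_d + SS_b) / (J * K)
    sigma_s2 <- tau1_c - sigma_e2 / G
    if (sigma_s2 < 0) {
      sigma_s2 <- 0
      sigma_e2 <- (SS_int + G * SS_d + G * SS_b) /
        (K * (G - 1) * J + J * (K - 1) + J)
    }
  }

  tau1s <- sigma_s2 + sigma_e2 / G
  tau2s <- tau1s + K * sigma_r2

  blup_b <- K * sigma_r2 * m_j / tau2s
  blup_s <- sigma_s2 * (sweep(r, 2L, m_j) / tau1s +
                          matrix(m_j / tau2s, K, J, byrow = TRUE))
  names(blup_b) <- reps
  dimnames(blup_s) <- list(rownames(Y), reps)

  safe_log <- function(v) log(max(v, 1e-300))
  N <- K * G * J
  loglik <- -0.5 * N * log(2 * pi) -
    0.5 * (K * J * (G - 1) * safe_log(sigma_e2) +
             J * (K - 1) * safe_log(G * tau1s) + J * safe_log(G * tau2s)) -
    0.5 * (SS_int / max(sigma_e2, 1e-300) + SS_d / max(tau1s, 1e-300) +
             SS_b / max(tau2s, 1e-300))

  structure(list(
    fixed_effects = M, blup_b = blup_b, blup_s = blup_s,
    var_r = sigma_r2, var_s = sigma_s2, var_e = sigma_e2,
    loglik = loglik,
    feature_ids = rownames(Y), sample_ids = meta$sample_id,
    replicates = reps,
    data_fingerprint = c(dim(Y), sum(Y), sum(Y^2))
  ), class = "batch_model_fit")
}

#' @export
print.batch_model_fit <- function(x, ...) {
  cat("batch_model_fit:", length(x$feature_ids), "features,",
      length(x$sample_ids), "samples\n")
  cat(sprintf("  var_r = %.4g, var_s = %.4g, var_e = %.4g, logLik = %.2f\n",
              x$var_r, x$var_s, x$var_e, x$loglik))
  invisible(x)
}

#' Remove the protein-by-replicate batch effect
#'
#' Subtracts the BLUP of the protein-by-replicate random effect from each
#' observation: \eqn{x_{ik} = y_{ik} - \hat s_{j(i),k}}.  Nothing else is
#' removed: fixed group effects and the whole-replicate shift \eqn{b_j}
#' stay in the data (the latter cancels in any between-group contrast).
#'
#' @param data The [intensity_matrix()] that `fit` was estimated from.
#' @param fit A [fit_batch_lmm()] result for `data`.
#' @return An `intensity_matrix` (additionally classed `adjusted_matrix`)
#'   of identical shape.
#' @export
correct_batch <- function(data, fit) {
  stopifnot(inherits(data, "intensity_matrix"),
            inherits(fit, "batch_model_fit"))
  if (!identical(rownames(data$values), fit$feature_ids) ||
      !identical(data$samples$sample_id, fit$sample_ids) ||
      !isTRUE(all.equal(fit$data_fingerprint,
                        c(dim(data$values), sum(data$values),
                          sum(data$values^2))))) {
    stop("`fit` was not produced from this matrix")
  }
  j_of <- match(data$samples$replicate, fit$replicates)
  adj <- data$values - fit$blup_s[, j_of, drop = FALSE]
  colnames(adj) <- colnames(data$values)
  out <- intensity_matrix(adj, data$samples)
  class(out) <- c("adjusted_matrix", class(out))
  attr(out, "batch_fit") <- fit
  out
}

#' Principal component analysis of the samples
#'
#' PCA of feature-centered, unscaled data with samples as observations
#' (the intensities share a common unit).  Components are ordered by
#' decreasing variance and given a deterministic sign: the largest-magnitude
#' feature loading of each component is made positive.
#'
#' @param data An [intensity_matrix()] (raw or batch-corrected).
#' @param n_components Number of component scores to return; defaults to
#'   every component with potentially nonzero variance.
#' @return A list of class `pca_result`: `scores` (sample x component),
#'   `loadings`, and `var_explained` (percentage per component over all
#'   components, summing to 100).
#' @export
run_pca <- function(data, n_components = NULL) {
  stopifnot(inherits(data, "intensity_matrix"))
  X <- t(data$values)
  n <- nrow(X)
  if (n < 2L) stop("PCA needs at least 2 samples")
  max_comp <- min(n - 1L, ncol(X))
  if (is.null(n_components)) n_components <- max_comp
  if (n_components > max_comp) {
    stop("n_components exceeds min(samples - 1, features) = ", max_comp)
  }
  pc <- prcomp(X, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  keep <- seq_len(max_comp)
  ev <- ev[keep]
  flip <- vapply(keep, function(k) {
    l <- pc$rotation[, k]
    if (l[which.max(abs(l))] < 0) -1 else 1
  }, numeric(1))
  scores <- sweep(pc$x[, keep, drop = FALSE], 2L, flip, `*`)
  loadings <- sweep(pc$rotation[, keep, drop = FALSE], 2L, flip, `*`)
  structure(list(
    scores = scores[, seq_len(n_components), drop = FALSE],
    loadings = loadings[, seq_len(n_components), drop = FALSE],
    var_explained = 100 * ev / sum(ev)
  ), class = "pca_result")
}

#' Scatter plot of the first two principal components
#'
#' A ggplot2 QC view of [run_pca()] scores, colored by group and shaped by
#' replicate, to judge whether replicate structure dominates before batch
#' correction and disappears after it.
#'
#' @param pca A [run_pca()] result.
#' @param samples The sample metadata of the matrix the PCA was run on.
#' @return A ggplot object.
#' @export
plot_pca <- function(pca, samples) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_pca requires the ggplot2 package")
  }
  df <- data.frame(PC1 = pca$scores[, 1L], PC2 = pca$scores[, 2L],
                   group = samples$group,
                   replicate = factor(samples$replicate))
  ggplot2::ggplot(df, ggplot2::aes(.data$PC1, .data$PC2,
                                   colour = .data$group,
                                   shape = .data$replicate)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", pca$var_explained[1L]),
      y = sprintf("PC2 (%.1f%%)", pca$var_explained[2L])
    ) +
    ggplot2::theme_minimal()
}
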