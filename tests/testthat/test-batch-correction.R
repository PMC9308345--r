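test_that("ML variance components, likelihood and BLUPs match lme4", {
  skip_if_not_installed("lme4")
  sim <- simulate_dataset(sim_config(n_features = 8, n_signal = 2, seed = 42))
  fit <- fit_batch_lmm(sim$data)

  d <- sim$data
  df <- data.frame(
    y = as.vector(d$values),
    feature = factor(rep(rownames(d$values), ncol(d$values))),
    group = factor(rep(d$samples$group, each = nrow(d$values))),
    rep = factor(rep(d$samples$replicate, each = nrow(d$values)))
  )
  m <- lme4::lmer(y ~ 0 + feature:group + (1 | rep) + (1 | feature:rep),
                  data = df, REML = FALSE)
  vc <- as.data.frame(lme4::VarCorr(m))
  vc_named <- setNames(vc$vcov, vc$grp)

  expect_equal(fit$var_r, vc_named[["rep"]], tolerance = 1e-5)
  expect_equal(fit$var_s, vc_named[["feature:rep"]], tolerance = 1e-5)
  expect_equal(fit$var_e, vc_named[["Residual"]], tolerance = 1e-5)
  expect_equal(fit$loglik, as.numeric(logLik(m)), tolerance = 1e-7)

  re <- lme4::ranef(m)
  b_or <- setNames(re$rep[, 1], rownames(re$rep))
  expect_equal(unname(fit$blup_b[names(b_or)]), unname(b_or),
               tolerance = 1e-6)
  s_or <- re[["feature:rep"]]
  key <- do.call(rbind, strsplit(rownames(s_or), ":"))
  expect_equal(unname(fit$blup_s[cbind(key[, 1], key[, 2])]),
               unname(s_or[, 1]), tolerance = 1e-6)
})

test_that("BLUPs center to zero and recover the injected batch effects", {
  # the per-feature mean of s over replicates is confounded with the fixed
  # feature effect, so BLUPs estimate the within-feature-centered effects;
  # at J replicates the attainable correlation with the raw draws is
  # sqrt((J-1)/J), hence the replicate-rich design for the raw comparison
  sim <- simulate_dataset(sim_config(n_reps_per_group = 8, n_features = 200,
                                     n_signal = 0, sigma_s = 1,
                                     sigma_e = 0.2, seed = 8))
  fit <- fit_batch_lmm(sim$data)
  expect_lt(max(abs(rowSums(fit$blup_s))), 1e-6 * max(abs(fit$blup_s)))
  expect_lt(abs(sum(fit$blup_b)), 1e-8)
  expect_gt(cor(as.vector(fit$blup_s), as.vector(sim$truth$true_s)), 0.9)

  # at the study design (3 replicates) the centered effects are still
  # recovered almost perfectly
  sim3 <- simulate_dataset(sim_config(n_features = 200, n_signal = 0,
                                      sigma_s = 1, sigma_e = 0.2, seed = 9))
  fit3 <- fit_batch_lmm(sim3$data)
  s_centered <- sim3$truth$true_s - rowMeans(sim3$truth$true_s)
  expect_gt(cor(as.vector(fit3$blup_s), as.vector(s_centered)), 0.95)
})

test_that("a design without interaction noise shrinks blup_s to zero", {
  sim <- simulate_dataset(sim_config(n_features = 100, n_signal = 0,
                                     sigma_s = 0, seed = 12))
  fit <- fit_batch_lmm(sim$data)
  expect_lte(fit$var_s, 0.01 * fit$var_e)
  expect_lt(max(abs(fit$blup_s)), 0.1)
})

test_that("variance estimates are consistent over repeated designs", {
  # nominal (sigma_r^2, sigma_s^2, sigma_e^2) = (0.09, 0.25, 1.0); ML
  # variance estimates carry a (J-1)/J small-sample factor and the
  # replicate variance has only J-1 df per dataset, so the oracle design
  # uses 30 replicate batches
  est <- matrix(0, 100, 3)
  for (r in seq_len(100)) {
    sim <- simulate_dataset(sim_config(
      n_groups = 2, n_reps_per_group = 30, n_features = 60, n_signal = 0,
      sigma_r = 0.3, sigma_s = 0.5, sigma_e = 1, seed = 9000 + r))
    f <- fit_batch_lmm(sim$data)
    est[r, ] <- c(f$var_r, f$var_s, f$var_e)
  }
  pooled <- colMeans(est)
  expect_lt(abs(pooled[1] - 0.09) / 0.09, 0.10)
  expect_lt(abs(pooled[2] - 0.25) / 0.25, 0.10)
  expect_lt(abs(pooled[3] - 1.0) / 1.0, 0.10)
})

test_that("correction subtracts exactly the interaction BLUP", {
  sim <- simulate_dataset(two_group_config(31, n_features = 50))
  fit <- fit_batch_lmm(sim$data)
  adj <- correct_batch(sim$data, fit)
  expect_equal(dim(adj$values), dim(sim$data$values))
  # inverse property: adding the BLUP back reconstructs the input
  j_of <- match(sim$data$samples$replicate, fit$replicates)
  recon <- adj$values + fit$blup_s[, j_of]
  expect_equal(unname(recon), unname(sim$data$values), tolerance = 1e-12)

  # identity when there is nothing to correct
  fit0 <- fit
  fit0$blup_s[] <- 0
  adj0 <- correct_batch(sim$data, fit0)
  expect_equal(adj0$values, sim$data$values)

  # mismatched input is refused
  other <- simulate_dataset(two_group_config(32, n_features = 50))
  expect_error(correct_batch(other$data, fit), "not produced from")
})

test_that("correction reduces between-replicate structure and is idempotent", {
  sim <- simulate_dataset(sim_config(n_features = 150, n_signal = 0,
                                     sigma_s = 0.8, seed = 77))
  fit <- fit_batch_lmm(sim$data)
  adj <- correct_batch(sim$data, fit)
  # between-replicate variance of feature values strictly decreases
  rep_var <- function(x) {
    j <- x$samples$replicate
    mean(apply(x$values, 1, function(v) var(tapply(v, j, mean))))
  }
  expect_lt(rep_var(adj), rep_var(sim$data))
  # refitting on corrected data finds (almost) no interaction variance left
  fit2 <- fit_batch_lmm(adj)
  expect_lt(fit2$var_s, 0.05 * fit$var_s + 1e-8)
})

test_that("degenerate designs are rejected", {
  sim <- simulate_dataset(sim_config(n_groups = 2, n_reps_per_group = 1,
                                     n_features = 10, n_signal = 0, seed = 1))
  expect_error(fit_batch_lmm(sim$data), "single-replicate")
})

test_that("PCA matches an eigendecomposition oracle and normalizes", {
  sim <- simulate_dataset(two_group_config(13, n_features = 40))
  pca <- run_pca(sim$data)
  expect_equal(sum(pca$var_explained), 100, tolerance = 1e-8)
  expect_true(all(pca$var_explained >= 0))

  # brute-force oracle: eigendecomposition of the sample covariance
  Xc <- scale(t(sim$data$values), center = TRUE, scale = FALSE)
  ev <- eigen(cov(Xc), symmetric = TRUE)
  k <- ncol(pca$scores)
  oracle <- Xc %*% ev$vectors[, seq_len(k)]
  for (c_ in seq_len(k)) {
    d1 <- max(abs(pca$scores[, c_] - oracle[, c_]))
    d2 <- max(abs(pca$scores[, c_] + oracle[, c_]))
    expect_lt(min(d1, d2), 1e-8)
  }
  # deterministic sign: the dominant loading of each component is positive
  for (c_ in seq_len(k)) {
    l <- pca$loadings[, c_]
    expect_gt(l[which.max(abs(l))], 0)
  }
  expect_error(run_pca(sim$data, n_components = 50), "exceeds")
})

test_that("collinear samples put all variance on PC1", {
  t_s <- c(-3, -1, 0, 1, 3)
  vals <- outer(rnorm(10), t_s) + 20
  rownames(vals) <- paste0("f", 1:10)
  colnames(vals) <- paste0("s", 1:5)
  samples <- data.frame(sample_id = colnames(vals), group = "G1",
                        replicate = 1:5, stringsAsFactors = FALSE)
  pca <- run_pca(intensity_matrix(vals, samples))
  expect_equal(pca$var_explained[1], 100, tolerance = 1e-8)
})

test_that("replicate clustering on PCs disappears after correction", {
  sim <- simulate_dataset(sim_config(n_groups = 2, n_reps_per_group = 6,
                                     n_features = 300, n_signal = 20,
                                     effect_size = 1.5, sigma_s = 1.2,
                                     sigma_e = 0.4, seed = 19))
  silhouette1d <- function(scores, lab) {
    # mean silhouette on the first two PCs
    d <- as.matrix(dist(scores[, 1:2]))
    mean(vapply(seq_along(lab), function(i) {
      a <- mean(d[i, lab == lab[i] & seq_along(lab) != i])
      b <- min(tapply(d[i, lab != lab[i]], lab[lab != lab[i]], mean))
      (b - a) / max(a, b)
    }, numeric(1)))
  }
  before <- run_pca(sim$data)
  fit <- fit_batch_lmm(sim$data)
  after <- run_pca(correct_batch(sim$data, fit))
  rep_lab <- sim$data$samples$replicate
  grp_lab <- sim$data$samples$group
  expect_gt(silhouette1d(before$scores, rep_lab),
            silhouette1d(after$scores, rep_lab))
  expect_gt(silhouette1d(after$scores, grp_lab),
            silhouette1d(after$scores, rep_lab))
})
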