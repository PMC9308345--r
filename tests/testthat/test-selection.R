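pip_frame <- function(pip, ids = sprintf("f%03d", seq_along(pip))) {
  structure(data.frame(feature_id = ids, pip = pip,
                       post_mean_beta = rep(1, length(pip)),
                       stringsAsFactors = FALSE),
            class = c("ssvs_summary", "data.frame"),
            comparison = "cmp", axis = "custom")
}

test_that("BFDR hand-worked example selects the first three features", {
  s <- pip_frame(1 - c(0.01, 0.02, 0.10, 0.90))
  sel <- bfdr_select(s, alpha = 0.05)
  # cumulative means: 0.01, 0.015, 0.0433, 0.2575
  expect_equal(sel$control$T_selected, 3L)
  expect_equal(sel$selected_ids, c("f001", "f002", "f003"))
  expect_equal(sel$control$bfdr_path[1:3],
               c(0.01, 0.015, 0.13 / 3), tolerance = 1e-12)
})

test_that("BFDR boundary cases behave as specified", {
  all_sure <- pip_frame(rep(1, 5))
  expect_length(bfdr_select(all_sure, 0.05)$selected_ids, 5L)

  all_weak <- pip_frame(c(0.9, 0.8, 0.95))     # every lfdr >= alpha
  expect_length(bfdr_select(all_weak, 0.05)$selected_ids, 0L)

  expect_error(bfdr_select(pip_frame(numeric(0))), "empty")
  expect_error(bfdr_select(pip_frame(0.5), alpha = 0), "alpha")
})

test_that("BFDR path is monotone and selection grows with alpha", {
  set.seed(3)
  s <- pip_frame(runif(100))
  sel <- bfdr_select(s, 0.2)
  expect_true(all(diff(sel$control$bfdr_path) >= -1e-15))
  sizes <- vapply(c(0.01, 0.05, 0.1, 0.3, 0.6),
                  function(a) length(bfdr_select(s, a)$selected_ids),
                  integer(1))
  expect_true(all(diff(sizes) >= 0))
  # every feature with lfdr < alpha is selected
  for (a in c(0.05, 0.3)) {
    sel_a <- bfdr_select(s, a)
    expect_true(all(s$feature_id[(1 - s$pip) < a] %in% sel_a$selected_ids))
  }
})

test_that("BFDR ties are broken deterministically by feature id", {
  s <- pip_frame(c(0.99, 0.99, 0.99), ids = c("z", "a", "m"))
  sel <- bfdr_select(s, 0.05)
  expect_equal(sel$selected_ids, c("a", "m", "z"))
})

test_that("BFDR controls the FDR on calibrated local fdrs", {
  # mixture oracle: z ~ N(0,1) under the null (prob 0.9) and
  # z ~ N(0, 1 + tau2) under the signal; the exact lfdr is computable, so
  # selection operates on perfectly calibrated pips
  set.seed(42)
  n_rep <- 200L; p <- 400L; pi1 <- 0.1; tau2 <- 24
  fdp <- numeric(n_rep); nsel <- integer(n_rep)
  for (r in seq_len(n_rep)) {
    is_sig <- runif(p) < pi1
    z <- rnorm(p, 0, sqrt(1 + tau2 * is_sig))
    d1 <- dnorm(z, 0, sqrt(1 + tau2)); d0 <- dnorm(z)
    lfdr <- (1 - pi1) * d0 / ((1 - pi1) * d0 + pi1 * d1)
    sel <- bfdr_select(pip_frame(1 - lfdr), 0.05)
    fp <- sum(!is_sig[match(sel$selected_ids, sprintf("f%03d", 1:p))])
    nsel[r] <- length(sel$selected_ids)
    fdp[r] <- fp / max(1, nsel[r])
  }
  mc_se <- sd(fdp) / sqrt(n_rep)
  expect_lte(mean(fdp), 0.05 + 3 * mc_se)
  expect_gt(mean(nsel), 1) # the regime genuinely selects features
})

test_that("pip threshold selection is strict and monotone", {
  s <- pip_frame(c(0.9, 0.5, 0.51))
  expect_equal(pip_threshold_select(s, 0.5)$selected_ids, c("f001", "f003"))
  expect_equal(pip_threshold_select(s, 0)$selected_ids,
               s$feature_id[s$pip > 0])
  s2 <- pip_frame(runif(50))
  low <- pip_threshold_select(s2, 0.3)$selected_ids
  high <- pip_threshold_select(s2, 0.7)$selected_ids
  expect_true(all(high %in% low))
})

test_that("direction classification follows the sign convention", {
  sel <- tridap:::new_dap_selection(
    method = "marginal", comparison = "A_vs_B", axis = "custom",
    selected_ids = c("f1", "f2"), table = NULL, control = list()
  )
  rec <- classify_direction(sel, c(f1 = 1.2, f2 = -0.4, f3 = 9))
  expect_equal(rec$direction, c("up", "down"))
  expect_equal(rec$method, rep("marginal", 2))
  expect_error(classify_direction(sel, c(f1 = 1.2)), "missing")
  empty <- tridap:::new_dap_selection("marginal", "A_vs_B", "custom",
                                      character(0), NULL, list())
  expect_equal(nrow(classify_direction(empty, c(f1 = 1))), 0L)
})

test_that("direction agrees with the simulated truth for marginal hits", {
  sc <- corrected_two_group(51, n_features = 300, n_signal = 30,
                            effect_size = 3)
  fit <- fit_marginal(sc$adj, sc$cmp)
  sel <- adjust_bonferroni(fit, 0.05)
  rec <- classify_direction(sel, setNames(fit$beta, fit$feature_id))
  hits <- rec[rec$feature_id %in% sc$truth$signal_ids, ]
  expect_gt(nrow(hits), 10)
  truth_dir <- ifelse(sc$truth$true_effects[hits$feature_id] > 0, "up", "down")
  expect_gte(mean(hits$direction == truth_dir), 0.95)
})

make_records <- function(sets, axis, comparison) {
  do.call(rbind, lapply(names(sets), function(m) {
    if (!length(sets[[m]])) return(NULL)
    data.frame(feature_id = sets[[m]], comparison = comparison, axis = axis,
               method = m, direction = "up", stat = 1,
               stringsAsFactors = FALSE)
  }))
}

test_that("pooling reproduces the published set arithmetic", {
  # genotype axis: 340 marginal, 40 elastic-net (subset of marginal),
  # 21 SSVS sharing only 2 with marginal and none with elastic net
  marg_g <- sprintf("g%03d", 1:340)
  en_g <- marg_g[101:140]
  ssvs_g <- c(marg_g[1:2], sprintf("gs%02d", 1:19))
  rec_g <- make_records(list(marginal = marg_g, elastic_net = en_g,
                             ssvs = ssvs_g), "genotype", "RCK_vs_MCK")
  # treatment axis: 126 marginal, 60 elastic-net subset, 26 SSVS with 4
  # detected by all three methods
  marg_t <- sprintf("t%03d", 1:126)
  en_t <- marg_t[1:60]
  ssvs_t <- c(marg_t[1:4], sprintf("ts%02d", 1:22))
  rec_t <- make_records(list(marginal = marg_t, elastic_net = en_t,
                             ssvs = ssvs_t), "treatment", "MCK_vs_M400")
  pool <- pool_comparisons(rbind(rec_g, rec_t))

  expect_equal(pool$per_axis$genotype$union_size, 359)
  expect_equal(pool$per_axis$treatment$union_size, 148)
  expect_equal(pool$overall_total, 507)
  expect_equal(unname(pool$per_axis$genotype$method_counts[c(
    "marginal", "elastic_net", "ssvs")]), c(340L, 40L, 21L))
  expect_equal(pool$per_axis$genotype$pairwise_intersections[["marginal&ssvs"]], 2L)
  expect_equal(pool$per_axis$treatment$pairwise_intersections[["marginal&ssvs"]], 4L)
})

test_that("pooling counts obey inclusion-exclusion on random fixtures", {
  set.seed(99)
  universe <- sprintf("u%03d", 1:150)
  A <- sample(universe, 60); B <- sample(universe, 40)
  rec <- make_records(list(marginal = A, ssvs = B), "genotype", "c1")
  pool <- pool_comparisons(rec)
  expect_equal(pool$per_axis$genotype$union_size,
               length(A) + length(B) - length(intersect(A, B)))
})

test_that("duplicate records are refused", {
  rec <- make_records(list(marginal = c("f1", "f2")), "genotype", "c1")
  expect_error(pool_comparisons(rbind(rec, rec[1, ])), "duplicate")
})
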