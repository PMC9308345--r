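#' Control settings for the elastic-net route
#'
#' Tuning and optimizer settings for the penalized logistic regression
#' \deqn{\min_{\beta_0,\beta} \sum_i [\log(1+e^{\eta_i}) - y_i \eta_i]
#'   + \lambda\,[\omega \|\beta\|_1 + (1-\omega)\|\beta\|_2^2],}
#' with \eqn{\eta_i = \beta_0 + \sum_k x_{ik}\beta_k}.  Note the quadratic
#' term carries no 1/2 factor; popular implementations parameterize the
#' penalty as \eqn{\lambda_g[\alpha\|\beta\|_1 + (1-\alpha)/2\,\|\beta\|_2^2]}
#' averaged over n observations, which corresponds to
#' \eqn{\lambda_g = \lambda(2-\omega)/n}, \eqn{\alpha = \omega/(2-\omega)}.
#'
#' @param lambda_grid Optional decreasing positive sequence of penalty
#'   strengths; when `NULL` a per-omega grid of `n_lambda` values is laid
#'   log-spaced from the smallest all-zero lambda down to
#'   `lambda_min_ratio` times it.
#' @param omega_grid L1 weight values in (0, 1).
#' @param n_lambda,lambda_min_ratio Grid shape when `lambda_grid` is `NULL`.
#' @param n_inner_folds Inner folds of the nested cross-validation.
#' @param max_iter Maximum IRLS iterations per fit.
#' @param tol Coordinate-descent convergence tolerance.
#' @param kkt_tol Required KKT residual of the returned solution.
#' @param standardize Standardize features within the comparison (kept for
#'   tests; the penalty is scale-sensitive so the default is `TRUE`).
#' @param seed RNG seed for cross-validation fold assignment.
#' @return An object of class `enet_control`.
#' @export
enet_control <- function(lambda_grid = NULL,
                         omega_grid = c(0.1, 0.3, 0.5, 0.7, 0.9),
                         n_lambda = 50L, lambda_min_ratio = 0.01,
                         n_inner_folds = 3L, max_iter = 200L,
                         tol = 1e-9, kkt_tol = 1e-7,
                         standardize = TRUE, seed = 1L) {
  stopifnot(length(omega_grid) >= 1L, all(omega_grid > 0 & omega_grid <= 1),
            n_inner_folds >= 2L)
  if (!is.null(lambda_grid)) {
    stopifnot(all(lambda_grid > 0), !is.unsorted(rev(lambda_grid)))
  }
  structure(list(lambda_grid = lambda_grid, omega_grid = omega_grid,
                 n_lambda = as.integer(n_lambda),
                 lambda_min_ratio = lambda_min_ratio,
                 n_inner_folds = as.integer(n_inner_folds),
                 max_iter = as.integer(max_iter), tol = tol,
                 kkt_tol = kkt_tol, standardize = standardize,
                 seed = as.integer(seed)),
            class = "enet_control")
}

# feature matrix of a comparison: samples x features, optionally
# standardized; constant features are excluded (their coefficient is 0)
enet_design <- function(data, cmp, standardize) {
  des <- comparison_design(data, cmp)
  X <- t(data$values[, des$idx, drop = FALSE])
  sds <- apply(X, 2L, sd)
  drop <- sds < 1e-12
  if (any(drop)) {
    warning(sum(drop), " constant feature(s) excluded from the penalized fit")
    X <- X[, !drop, drop = FALSE]
    sds <- sds[!drop]
  }
  if (standardize) X <- scale(X, center = TRUE, scale = sds)
  list(X = X, y = des$y, feature_ids = colnames(X), dropped = names(drop)[drop])
}

# smallest lambda at which the all-zero coefficient vector is optimal
enet_lambda_max <- function(X, y, omega) {
  pbar <- mean(y)
  g <- abs(drop(crossprod(X, y - pbar)))
  max(g) / omega
}

#' Fit the elastic-net logistic regression at fixed tuning values
#'
#' Minimizes the penalized negative Bernoulli log-likelihood described in
#' [enet_control()] by iteratively reweighted least squares with cyclic
#' coordinate descent; the returned solution satisfies the KKT conditions
#' of the exact objective to `control$kkt_tol`.  Proteins with nonzero
#' coefficients form the selected set.
#'
#' @param data An [intensity_matrix()], normally batch-corrected.
#' @param cmp A comparison from [build_comparisons()].
#' @param lambda Penalty strength, > 0.
#' @param omega L1 weight in (0, 1]; 1 is the pure-lasso endpoint, kept for
#'   testing.
#' @param control An [enet_control()].
#' @return An object of class `enet_fit`: `beta0`, `beta` (named, on the
#'   standardized scale), `pi`, `lambda`, `omega`, `selected`, `kkt`,
#'   `objective`.
#' @export
fit_enet <- function(data, cmp, lambda, omega, control = enet_control()) {
  stopifnot(lambda > 0, omega > 0, omega <= 1)
  d <- enet_design(data, cmp, control$standardize)
  if (length(unique(d$y)) < 2L) stop("degenerate response: only one class")
  fit <- .enet_fit_cpp(d$X, as.numeric(d$y), lambda, omega, 0,
                       numeric(ncol(d$X)), control$max_iter, control$tol,
                       control$kkt_tol)
  if (!fit$converged) {
    stop("elastic-net optimizer did not reach KKT tolerance ",
         control$kkt_tol, " after ", control$max_iter,
         " IRLS iterations (residual ", signif(fit$kkt, 3), ")")
  }
  beta <- setNames(drop(fit$beta), d$feature_ids)
  structure(list(beta0 = fit$beta0, beta = beta, pi = drop(fit$pi),
                 lambda = lambda, omega = omega,
                 selected = d$feature_ids[beta != 0],
                 kkt = fit$kkt, objective = fit$objective,
                 comparison = cmp$name, axis = cmp$axis),
            class = "enet_fit")
}

# stratified fold ids: within each class, shuffle then deal round-robin
stratified_folds <- function(y, k) {
  folds <- integer(length(y))
  for (cl in unique(y)) {
    idx <- which(y == cl)
    idx <- idx[sample.int(length(idx))]
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

binomial_deviance <- function(y, pi) {
  pi <- pmin(pmax(pi, 1e-8), 1 - 1e-8)
  -2 * sum(y * log(pi) + (1 - y) * log(1 - pi))
}

#' Tune the elastic net by nested cross-validation and refit
#'
#' The outer loop is leave-one-sample-out; within each outer training set a
#' stratified `n_inner_folds`-fold cross-validation scores binomial
#' deviance on the full (lambda, omega) grid, fitting whole lambda paths
#' with warm starts.  The deviance surface is averaged over all inner
#' validation sets, the minimizing pair is chosen (ties broken toward
#' larger lambda, then larger omega, i.e. the sparser model) and the final
#' model is refit on all samples of the comparison.
#'
#' @inheritParams fit_enet
#' @return The final `enet_fit`, with extra elements `cv_deviance`
#'   (lambda-index by omega matrix of mean deviances), `lambda_grids`
#'   (per-omega lambda sequences) and the chosen `lambda`/`omega`.
#' @export
tune_enet_cv <- function(data, cmp, control = enet_control()) {
  d <- enet_design(data, cmp, control$standardize)
  X <- d$X; y <- d$y
  n <- length(y)
  if (length(unique(y)) < 2L) stop("degenerate response: only one class")

  omegas <- control$omega_grid
  lgrids <- lapply(omegas, function(om) {
    if (!is.null(control$lambda_grid)) return(control$lambda_grid)
    lmax <- enet_lambda_max(X, y, om)
    exp(seq(log(lmax), log(lmax * control$lambda_min_ratio),
            length.out = control$n_lambda))
  })
  L <- length(lgrids[[1L]])
  dev_sum <- matrix(0, L, length(omegas))
  n_val <- 0L

  set.seed(control$seed)
  for (i in seq_len(n)) {                      # outer: leave-one-sample-out
    tr <- setdiff(seq_len(n), i)
    folds <- stratified_folds(y[tr], control$n_inner_folds)
    for (f in seq_len(control$n_inner_folds)) { # inner: stratified k-fold
      fit_idx <- tr[folds != f]
      val_idx <- tr[folds == f]
      if (length(unique(y[fit_idx])) < 2L) next
      for (w in seq_along(omegas)) {
        path <- .enet_path_cpp(X[fit_idx, , drop = FALSE],
                               as.numeric(y[fit_idx]), lgrids[[w]],
                               omegas[w], control$max_iter, control$tol,
                               control$kkt_tol)
        eta <- X[val_idx, , drop = FALSE] %*% path$beta
        eta <- sweep(eta, 2L, path$beta0, `+`)
        pv <- plogis(eta)
        for (l in seq_len(L)) {
          dev_sum[l, w] <- dev_sum[l, w] + binomial_deviance(y[val_idx], pv[, l])
        }
      }
      n_val <- n_val + length(val_idx)
    }
  }
  cv_dev <- dev_sum / n_val

  best <- which(cv_dev == min(cv_dev), arr.ind = TRUE)
  # ties: prefer larger lambda (smaller row index), then larger omega
  best <- best[order(best[, "row"], -best[, "col"]), , drop = FALSE][1L, ]
  lambda_star <- lgrids[[best["col"]]][best["row"]]
  omega_star <- omegas[best["col"]]

  fit <- fit_enet(data, cmp, lambda_star, omega_star, control)
  fit$cv_deviance <- cv_dev
  fit$lambda_grids <- lgrids
  fit
}

#' Turn an elastic-net fit into a selection object
#'
#' @param fit An [fit_enet()] or [tune_enet_cv()] result.
#' @return A `dap_selection` whose table carries the signed coefficients.
#' @export
enet_selection <- function(fit) {
  stopifnot(inherits(fit, "enet_fit"))
  tab <- data.frame(feature_id = names(fit$beta),
                    coefficient = unname(fit$beta),
                    selected = fit$beta != 0,
                    direction = ifelse(fit$beta > 0, "up", "down"),
                    stringsAsFactors = FALSE)
  new_dap_selection(
    method = "elastic_net", comparison = fit$comparison, axis = fit$axis,
    selected_ids = fit$selected, table = tab,
    control = list(lambda = fit$lambda, omega = fit$omega)
  )
}
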