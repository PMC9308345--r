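#' Per-protein marginal regression on the group indicator
#'
#' Fits, one protein at a time, the simple regression
#' \eqn{x_{ik} = \beta_0 + y_i \beta_k + e_{ik}} on the samples of a
#' comparison, where \eqn{y_i} is the 0/1 group indicator (1 for the
#' first-listed group).  Ordinary least squares on a binary regressor makes
#' \eqn{\hat\beta_k} the difference of group means and the t test on
#' \eqn{\beta_k} algebraically identical to the pooled equal-variance
#' two-sample t test with \eqn{n - 2} degrees of freedom.
#'
#' Proteins with zero residual variance (constant within both groups) are
#' flagged and get `NA` p-values rather than spuriously extreme ones.
#'
#' @param data An [intensity_matrix()], normally batch-corrected.
#' @param cmp A comparison from [build_comparisons()].
#' @return A data frame of class `marginal_fit` with one row per protein:
#'   `feature_id`, `beta0`, `beta`, `se`, `t`, `df`, `p_raw`,
#'   `residual_var`, `flagged`.
#' @export
fit_marginal <- function(data, cmp) {
  des <- comparison_design(data, cmp)
  X <- data$values[, des$idx, drop = FALSE]
  y <- des$y
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  n <- n1 + n0
  df <- n - 2L

  mean1 <- rowMeans(X[, y == 1L, drop = FALSE])
  mean0 <- rowMeans(X[, y == 0L, drop = FALSE])
  ss1 <- rowSums((X[, y == 1L, drop = FALSE] - mean1)^2)
  ss0 <- rowSums((X[, y == 0L, drop = FALSE] - mean0)^2)
  s2 <- (ss1 + ss0) / df
  beta <- mean1 - mean0
  se <- sqrt(s2 * (1 / n1 + 1 / n0))

  flagged <- s2 <= .Machine$double.eps * pmax(mean1^2, 1)
  tstat <- ifelse(flagged, NA_real_, beta / se)
  p <- 2 * pt(-abs(tstat), df)

  structure(data.frame(
    feature_id = rownames(X), beta0 = mean0, beta = beta, se = se,
    t = tstat, df = df, p_raw = p, residual_var = s2, flagged = flagged,
    row.names = NULL, stringsAsFactors = FALSE
  ), class = c("marginal_fit", "data.frame"),
  comparison = cmp$name, axis = cmp$axis)
}

#' Bonferroni family-wise error control of marginal tests
#'
#' Adjusts the raw marginal p-values by the Bonferroni rule
#' \eqn{p_{adj} = \min(1, m\, p)} with \eqn{m} the number of proteins
#' tested in the comparison, and selects proteins with \eqn{p_{adj} <
#' \alpha}.  Flagged (`NA`) proteins are never selected.
#'
#' @param fits A [fit_marginal()] result.
#' @param alpha Significance level in (0, 1); default 0.05.
#' @return A `dap_selection` object (see [bfdr_select()] for the shape).
#' @export
adjust_bonferroni <- function(fits, alpha = 0.05) {
  stopifnot(inherits(fits, "marginal_fit"))
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1) {
    stop("alpha must lie strictly inside (0, 1)")
  }
  m <- nrow(fits)
  if (m < 1L) stop("no fitted proteins")
  p_adj <- pmin(1, fits$p_raw * m)
  selected <- !is.na(p_adj) & p_adj < alpha
  tab <- fits
  tab$p_adj <- p_adj
  tab$selected <- selected
  tab$direction <- ifelse(tab$beta > 0, "up", "down")
  new_dap_selection(
    method = "marginal",
    comparison = attr(fits, "comparison"), axis = attr(fits, "axis"),
    selected_ids = fits$feature_id[selected],
    table = tab,
    control = list(alpha = alpha, m = m)
  )
}
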