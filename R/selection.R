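new_dap_selection <- function(method, comparison, axis, selected_ids, table,
                              control) {
  structure(list(method = method, comparison = comparison, axis = axis,
                 selected_ids = selected_ids, table = table,
                 control = control),
            class = "dap_selection")
}

#' @export
print.dap_selection <- function(x, ...) {
  cat("dap_selection [", x$method, "] ", x$comparison %||% "", ": ",
      length(x$selected_ids), " selected\n", sep = "")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Bayesian FDR selection from posterior inclusion probabilities
#'
#' Each protein's local false discovery rate is `lfdr = 1 - pip`, the
#' posterior probability that it is null.  LFDRs are sorted in ascending
#' order (ties broken by feature id for determinism) and the running mean
#' of the first `T` values is the Bayesian FDR of calling those `T`
#' proteins significant.  The procedure picks the largest `T` whose
#' running mean is still strictly below `alpha` and selects those proteins;
#' `T = 0` (no selection) when even the smallest LFDR is at or above
#' `alpha`.
#'
#' @param summary An [compute_pip()] summary (any data frame with
#'   `feature_id` and `pip` columns works).
#' @param alpha BFDR control level in (0, 1); default 0.05.
#' @return A `dap_selection` with `control$T_selected` and the sorted
#'   cumulative-mean path `control$bfdr_path`.
#' @export
bfdr_select <- function(summary, alpha = 0.05) {
  if (!is.data.frame(summary) || nrow(summary) == 0L) {
    stop("empty summary: nothing to select from")
  }
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1) {
    stop("alpha must lie strictly inside (0, 1)")
  }
  stopifnot(all(summary$pip >= 0 & summary$pip <= 1))
  lfdr <- 1 - summary$pip
  ord <- order(lfdr, summary$feature_id)
  path <- cumsum(lfdr[ord]) / seq_along(ord)
  ok <- which(path < alpha)
  T_sel <- if (length(ok)) max(ok) else 0L
  selected_ids <- if (T_sel > 0L) summary$feature_id[ord[seq_len(T_sel)]] else character(0)
  tab <- summary
  tab$lfdr <- lfdr
  tab$selected <- summary$feature_id %in% selected_ids
  new_dap_selection(
    method = "ssvs", comparison = attr(summary, "comparison"),
    axis = attr(summary, "axis"),
    selected_ids = selected_ids, table = tab,
    control = list(alpha = alpha, T_selected = T_sel, bfdr_path = path)
  )
}

#' Heuristic selection by a posterior inclusion probability cutoff
#'
#' Selects proteins with `pip` strictly greater than `cut` (0.5 by
#' convention).  Unlike [bfdr_select()] this rule does not control the
#' overall false discovery rate; it is provided as the familiar heuristic
#' companion.
#'
#' @inheritParams bfdr_select
#' @param cut PIP cutoff in (0, 1).
#' @return A `dap_selection`.
#' @export
pip_threshold_select <- function(summary, cut = 0.5) {
  if (!is.data.frame(summary) || nrow(summary) == 0L) {
    stop("empty summary: nothing to select from")
  }
  stopifnot(cut >= 0, cut < 1)
  selected <- summary$pip > cut
  tab <- summary
  tab$selected <- selected
  new_dap_selection(
    method = "ssvs", comparison = attr(summary, "comparison"),
    axis = attr(summary, "axis"),
    selected_ids = summary$feature_id[selected], table = tab,
    control = list(cut = cut)
  )
}

#' Classify selected proteins as up- or down-regulated
#'
#' Direction is read off the method's signed effect for the comparison's
#' y = 1 (first-listed) group: a positive marginal slope, elastic-net
#' coefficient or conditional posterior mean marks the protein as more
#' abundant there ("up"), a negative one as "down".
#'
#' @param selection A `dap_selection`.
#' @param stats Named numeric vector of signed per-protein statistics
#'   (name = feature id), covering every selected protein.
#' @return A data frame of DAP records: `feature_id`, `comparison`, `axis`,
#'   `method`, `direction`, `stat`.
#' @export
classify_direction <- function(selection, stats) {
  stopifnot(inherits(selection, "dap_selection"))
  ids <- selection$selected_ids
  if (length(ids) == 0L) {
    return(data.frame(feature_id = character(0), comparison = character(0),
                      axis = character(0), method = character(0),
                      direction = character(0), stat = numeric(0),
                      stringsAsFactors = FALSE))
  }
  miss <- setdiff(ids, names(stats))
  if (length(miss)) {
    stop("missing signed statistic for selected protein(s): ",
         paste(head(miss, 5L), collapse = ", "))
  }
  s <- stats[ids]
  if (anyNA(s)) stop("NA statistic for a selected protein")
  data.frame(
    feature_id = ids,
    comparison = selection$comparison %||% NA_character_,
    axis = selection$axis %||% NA_character_,
    method = selection$method,
    direction = ifelse(s > 0, "up", "down"),
    stat = unname(s),
    stringsAsFactors = FALSE
  )
}

#' Pool DAP records across methods and comparisons
#'
#' Summarizes a long-format table of selected proteins: per pooling axis
#' the distinct-protein union across methods and that axis's pairwise
#' comparisons, per-method counts, and all pairwise between-method
#' intersection sizes (Venn input).  The overall total is the sum of the
#' axis-level distinct counts, so a protein recovered on both axes is
#' counted once per axis.
#'
#' @param records A data frame of DAP records as produced by
#'   [classify_direction()] (rows may be concatenated across methods and
#'   comparisons).
#' @return A list of class `dap_pool`: `per_axis` (each with
#'   `union_size`, `method_counts`, `pairwise_intersections`,
#'   `up_down`), and `overall_total`.
#' @export
pool_comparisons <- function(records) {
  stopifnot(is.data.frame(records))
  req <- c("feature_id", "comparison", "axis", "method", "direction")
  miss <- setdiff(req, names(records))
  if (length(miss)) stop("records lack column(s): ", paste(miss, collapse = ", "))
  if (nrow(records) == 0L) stop("no DAP records to pool")
  key <- paste(records$feature_id, records$comparison, records$method)
  if (anyDuplicated(key)) {
    stop("duplicate (feature, comparison, method) record(s)")
  }
  per_axis <- lapply(split(records, records$axis), function(r) {
    methods <- unique(r$method)
    sets <- lapply(methods, function(m) unique(r$feature_id[r$method == m]))
    names(sets) <- methods
    inter <- list()
    if (length(methods) > 1L) {
      pairs <- utils::combn(methods, 2L, simplify = FALSE)
      for (pr in pairs) {
        inter[[paste(pr, collapse = "&")]] <-
          length(intersect(sets[[pr[1L]]], sets[[pr[2L]]]))
      }
    }
    updown <- table(comparison = r$comparison, method = r$method,
                    direction = r$direction)
    list(union_size = length(unique(r$feature_id)),
         method_counts = vapply(sets, length, integer(1)),
         pairwise_intersections = inter,
         up_down = updown)
  })
  structure(list(
    per_axis = per_axis,
    overall_total = sum(vapply(per_axis, `[[`, numeric(1), "union_size"))
  ), class = "dap_pool")
}

#' @export
print.dap_pool <- function(x, ...) {
  for (ax in names(x$per_axis)) {
    a <- x$per_axis[[ax]]
    cat(ax, "axis:", a$union_size, "distinct DAPs (",
        paste(names(a$method_counts), a$method_counts, sep = "=",
              collapse = ", "), ")\n")
  }
  cat("overall total:", x$overall_total, "DAPs\n")
  invisible(x)
}
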