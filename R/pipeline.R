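#' Assemble a pipeline configuration
#'
#' @param out_dir Output directory (created if needed).
#' @param simulate Optional list of [sim_config()] arguments; when given,
#'   the input dataset is simulated and written alongside the results.
#' @param matrix_path,meta_path Input tables (ignored when simulating).
#' @param log_transform Passed to [read_intensity_table()].
#' @param methods Which routes to run: any of `"marginal"`,
#'   `"elastic_net"`, `"ssvs"`.
#' @param alpha Control level shared by the Bonferroni and BFDR rules.
#' @param enet List of [enet_control()] arguments.
#' @param ssvs List of [ssvs_control()] arguments.
#' @param seed Global seed; per-stage seeds are derived from it.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, simulate = NULL, matrix_path = NULL,
                            meta_path = NULL, log_transform = FALSE,
                            methods = c("marginal", "elastic_net", "ssvs"),
                            alpha = 0.05, enet = list(), ssvs = list(),
                            seed = 1L) {
  methods <- match.arg(methods, c("marginal", "elastic_net", "ssvs"),
                       several.ok = TRUE)
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie strictly inside (0, 1)")
  if (is.null(simulate) && (is.null(matrix_path) || is.null(meta_path))) {
    stop("either `simulate` or both input paths must be given")
  }
  structure(list(out_dir = out_dir, simulate = simulate,
                 matrix_path = matrix_path, meta_path = meta_path,
                 log_transform = log_transform, methods = methods,
                 alpha = alpha, enet = enet, ssvs = ssvs,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys mirror the [pipeline_config()]
#'   arguments.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

write_tsv <- function(df, path) {
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(x) sprintf("%.17g", x))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full differential-abundance pipeline
#'
#' Orchestrates simulate/read, LMM batch correction, the enabled selection
#' routes on every comparison of the design, direction classification,
#' DAP-table assembly and cross-method pooling.  All result tables, a
#' pooling summary JSON and a run manifest (configuration hash, seed) are
#' written under `config$out_dir`; identical configuration and seed yield
#' byte-identical result tables.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the pooling summary, the DAP table, all
#'   selection objects, the batch fit and the output paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()

  if (!is.null(config$simulate)) {
    sim_args <- config$simulate
    if (is.null(sim_args$seed)) sim_args$seed <- config$seed
    sim <- simulate_dataset(do.call(sim_config, sim_args))
    data <- sim$data
    paths$matrix <- file.path(config$out_dir, "intensity_matrix.tsv")
    paths$meta <- file.path(config$out_dir, "sample_metadata.csv")
    write_intensity_table(data, paths$matrix, paths$meta)
    paths$truth <- file.path(config$out_dir, "sim_truth.json")
    write_sim_truth(sim$truth, paths$truth)
  } else {
    data <- read_intensity_table(config$matrix_path, config$meta_path,
                                 config$log_transform)
  }

  fit <- fit_batch_lmm(data)
  adj <- correct_batch(data, fit)
  paths$corrected <- file.path(config$out_dir, "corrected_matrix.tsv")
  write_intensity_table(adj, paths$corrected,
                        file.path(config$out_dir, "corrected_metadata.csv"))
  pca_before <- run_pca(data)
  pca_after <- run_pca(adj)
  write_tsv(data.frame(sample_id = data$samples$sample_id,
                       PC1_before = pca_before$scores[, 1L],
                       PC2_before = pca_before$scores[, 2L],
                       PC1_after = pca_after$scores[, 1L],
                       PC2_after = pca_after$scores[, 2L]),
            file.path(config$out_dir, "pca_scores.tsv"))

  cmps <- build_comparisons(adj)
  selections <- list()
  records <- list()
  for (ci in seq_along(cmps)) {
    cmp <- cmps[[ci]]
    if ("marginal" %in% config$methods) {
      mf <- fit_marginal(adj, cmp)
      sel <- adjust_bonferroni(mf, config$alpha)
      stats <- setNames(mf$beta, mf$feature_id)
      key <- paste0("marginal_", cmp$name)
      selections[[key]] <- sel
      records[[key]] <- classify_direction(sel, stats)
      paths[[key]] <- write_tsv(sel$table,
        file.path(config$out_dir, paste0(key, ".tsv")))
    }
    if ("elastic_net" %in% config$methods) {
      en_args <- config$enet
      if (is.null(en_args$seed)) en_args$seed <- config$seed + ci
      ef <- tune_enet_cv(adj, cmp, do.call(enet_control, en_args))
      sel <- enet_selection(ef)
      key <- paste0("elastic_net_", cmp$name)
      selections[[key]] <- sel
      records[[key]] <- classify_direction(sel, setNames(ef$beta, names(ef$beta)))
      paths[[key]] <- write_tsv(sel$table,
        file.path(config$out_dir, paste0(key, ".tsv")))
    }
    if ("ssvs" %in% config$methods) {
      sv_args <- config$ssvs
      if (is.null(sv_args$seed)) sv_args$seed <- config$seed + 100L + ci
      dr <- run_ssvs(adj, cmp, do.call(ssvs_control, sv_args))
      summ <- compute_pip(dr)
      sel <- bfdr_select(summ, config$alpha)
      key <- paste0("ssvs_", cmp$name)
      selections[[key]] <- sel
      records[[key]] <- classify_direction(
        sel, setNames(summ$post_mean_beta, summ$feature_id))
      paths[[key]] <- write_tsv(sel$table,
        file.path(config$out_dir, paste0(key, ".tsv")))
    }
  }

  dap <- do.call(rbind, records)
  rownames(dap) <- NULL
  paths$dap_table <- write_tsv(dap, file.path(config$out_dir, "dap_table.tsv"))
  pool <- if (nrow(dap)) pool_comparisons(dap) else NULL
  if (!is.null(pool)) {
    summ_json <- list(
      per_axis = lapply(pool$per_axis, function(a) {
        list(union_size = a$union_size,
             method_counts = as.list(a$method_counts),
             pairwise_intersections = a$pairwise_intersections)
      }),
      overall_total = pool$overall_total
    )
    paths$summary <- file.path(config$out_dir, "pool_summary.json")
    jsonlite::write_json(summ_json, paths$summary, auto_unbox = TRUE,
                         digits = NA)
  }

  cfg_file <- tempfile(fileext = ".json")
  jsonlite::write_json(unclass(config), cfg_file, auto_unbox = TRUE,
                       digits = NA, null = "null", force = TRUE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("tridap")),
    seed = config$seed,
    config_hash = unname(tools::md5sum(cfg_file)),
    methods = config$methods,
    n_features = nrow(adj$values), n_samples = ncol(adj$values),
    comparisons = vapply(cmps, `[[`, character(1), "name"),
    var_components = list(var_r = fit$var_r, var_s = fit$var_s,
                          var_e = fit$var_e)
  )
  unlink(cfg_file)
  paths$manifest <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE, digits = NA)

  invisible(list(pool = pool, dap_table = dap, selections = selections,
                 batch_fit = fit, pca_before = pca_before,
                 pca_after = pca_after, paths = paths))
}
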