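#' Construct an intensity matrix with aligned sample metadata
#'
#' The central data container: a protein-by-sample grid of log intensities
#' plus one metadata row per sample (group, genotype, treatment, replicate).
#' Column order of `values` always matches row order of `samples`.
#'
#' @param values Numeric matrix, features in rows (rownames = feature ids),
#'   samples in columns (colnames = sample ids).
#' @param samples Data frame with columns `sample_id`, `group`, `genotype`,
#'   `treatment`, `replicate`; one row per column of `values`, same order.
#' @return An object of class `intensity_matrix`.
#' @export
intensity_matrix <- function(values, samples) {
  stopifnot(is.matrix(values), is.numeric(values), is.data.frame(samples))
  req <- c("sample_id", "group", "replicate")
  miss <- setdiff(req, names(samples))
  if (length(miss)) stop("metadata lacks column(s): ", paste(miss, collapse = ", "))
  if (!("genotype" %in% names(samples))) samples$genotype <- NA_character_
  if (!("treatment" %in% names(samples))) samples$treatment <- NA_character_
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("`values` must carry feature ids as rownames and sample ids as colnames")
  }
  if (anyDuplicated(rownames(values))) stop("duplicate feature ids")
  if (anyDuplicated(samples$sample_id)) stop("duplicate sample ids")
  if (ncol(values) != nrow(samples) ||
      !identical(colnames(values), as.character(samples$sample_id))) {
    stop("columns of `values` must match `samples$sample_id` in the same order")
  }
  if (anyDuplicated(samples[, c("group", "replicate")])) {
    stop("(group, replicate) pairs must be unique")
  }
  samples$replicate <- as.integer(samples$replicate)
  structure(list(values = values, samples = samples),
            class = "intensity_matrix")
}

#' @export
print.intensity_matrix <- function(x, ...) {
  cat("intensity_matrix:", nrow(x$values), "features x", ncol(x$values),
      "samples\n")
  cat("groups:", paste(unique(x$samples$group), collapse = ", "), "\n")
  invisible(x)
}

read_table_auto <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  } else {
    read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  }
}

#' Read an intensity table and its sample metadata from disk
#'
#' The matrix file (TSV or CSV by extension) holds feature ids in the first
#' column and one column per sample; the metadata file holds columns
#' `sample_id`, `genotype`, `treatment`, `replicate` and optionally `group`
#' (derived as `paste0(genotype, treatment)` when absent).  Features with
#' any missing value are dropped (the count is reported via `message()`),
#' and matrix columns are aligned to the metadata row order — samples are
#' never silently reordered relative to the metadata file.
#'
#' @param matrix_path Path to the feature-by-sample table.
#' @param meta_path Path to the sample metadata table.
#' @param log_transform If `TRUE`, intensities are natural-log transformed;
#'   non-positive values are then an error.
#' @return An [intensity_matrix()].
#' @export
read_intensity_table <- function(matrix_path, meta_path, log_transform = FALSE) {
  raw <- read_table_auto(matrix_path)
  meta <- read_table_auto(meta_path)
  req <- c("sample_id", "genotype", "treatment", "replicate")
  miss <- setdiff(req, names(meta))
  if (length(miss)) stop("metadata lacks column(s): ", paste(miss, collapse = ", "))
  if (!("group" %in% names(meta))) {
    meta$group <- paste0(meta$genotype, meta$treatment)
  }
  feature_ids <- as.character(raw[[1L]])
  mat <- as.matrix(raw[, -1L, drop = FALSE])
  storage.mode(mat) <- "double"
  rownames(mat) <- feature_ids

  only_mat <- setdiff(colnames(mat), meta$sample_id)
  only_meta <- setdiff(meta$sample_id, colnames(mat))
  if (length(only_mat) || length(only_meta)) {
    stop("sample-id mismatch between matrix and metadata; only in matrix: [",
         paste(only_mat, collapse = ", "), "]; only in metadata: [",
         paste(only_meta, collapse = ", "), "]")
  }
  mat <- mat[, meta$sample_id, drop = FALSE] # metadata order rules

  keep <- !apply(mat, 1L, anyNA)
  n_drop <- sum(!keep)
  if (n_drop > 0L) {
    message("read_intensity_table: dropped ", n_drop,
            " feature(s) with missing values")
    mat <- mat[keep, , drop = FALSE]
  }
  if (log_transform) {
    if (any(mat <= 0)) {
      stop("log_transform requires strictly positive intensities")
    }
    mat <- log(mat)
  }
  intensity_matrix(mat, meta)
}

#' Write an intensity matrix and its metadata to disk
#'
#' Values are written with 17 significant digits so that a write/read
#' round trip reproduces the matrix bit for bit.
#'
#' @param x An [intensity_matrix()] (or adjusted matrix).
#' @param matrix_path Output path for the feature-by-sample table (TSV or
#'   CSV by extension).
#' @param meta_path Output path for the sample metadata table.
#' @return `matrix_path`, invisibly.
#' @export
write_intensity_table <- function(x, matrix_path, meta_path) {
  stopifnot(inherits(x, "intensity_matrix"))
  sep_of <- function(p) if (grepl("\\.csv$", p, ignore.case = TRUE)) "," else "\t"
  fmt <- matrix(sprintf("%.17g", x$values), nrow(x$values), ncol(x$values),
                dimnames = dimnames(x$values))
  out <- data.frame(feature_id = rownames(x$values), fmt,
                    check.names = FALSE, stringsAsFactors = FALSE)
  write.table(out, matrix_path, sep = sep_of(matrix_path), quote = FALSE,
              row.names = FALSE)
  write.table(x$samples, meta_path, sep = sep_of(meta_path), quote = FALSE,
              row.names = FALSE)
  invisible(matrix_path)
}

new_comparison <- function(name, group_a, group_b, axis) {
  structure(list(name = name, group_a = group_a, group_b = group_b,
                 axis = axis), class = "dap_comparison")
}

#' @export
print.dap_comparison <- function(x, ...) {
  cat("comparison ", x$name, " (axis: ", x$axis, "): y=1 for ", x$group_a,
      ", y=0 for ", x$group_b, "\n", sep = "")
  invisible(x)
}

#' Build the pairwise group comparisons implied by the design
#'
#' For a complete 2x2 genotype-by-treatment factorial this yields the four
#' standard comparisons: the genotype axis contrasts the two genotypes at
#' each treatment level (e.g. RCK vs MCK and R400 vs M400) and the
#' treatment axis contrasts the two treatments within each genotype
#' (e.g. RCK vs R400 and MCK vs M400).  For a two-group design a single
#' comparison is returned.  In every comparison the first-listed group
#' (`group_a`, first level in metadata order) is coded y = 1, so a positive
#' effect downstream means higher abundance in `group_a`.
#'
#' @param x An [intensity_matrix()] or a sample-metadata data frame.
#' @return A list of comparison objects, each with a `name`, `group_a`,
#'   `group_b` and pooling `axis` (`"genotype"`, `"treatment"` or
#'   `"custom"`).
#' @export
build_comparisons <- function(x) {
  meta <- if (inherits(x, "intensity_matrix")) x$samples else x
  groups <- unique(meta$group)
  if (length(groups) == 2L) {
    return(list(new_comparison(paste0(groups[1L], "_vs_", groups[2L]),
                               groups[1L], groups[2L], "custom")))
  }
  gl <- unique(meta$genotype[!is.na(meta$genotype)])
  tl <- unique(meta$treatment[!is.na(meta$treatment)])
  if (length(gl) != 2L || length(tl) != 2L) {
    stop("need either exactly 2 groups or a 2x2 genotype x treatment design")
  }
  cell <- function(g, t) {
    grp <- unique(meta$group[meta$genotype == g & meta$treatment == t])
    if (length(grp) != 1L) {
      stop("factorial cell missing from metadata: genotype=", g,
           ", treatment=", t)
    }
    grp
  }
  cells <- outer(gl, tl, Vectorize(cell))
  cmps <- list()
  for (t in seq_along(tl)) { # genotype axis, one contrast per treatment level
    a <- cells[1L, t]; b <- cells[2L, t]
    cmps[[length(cmps) + 1L]] <-
      new_comparison(paste0(a, "_vs_", b), a, b, "genotype")
  }
  for (g in seq_along(gl)) { # treatment axis, one contrast per genotype
    a <- cells[g, 1L]; b <- cells[g, 2L]
    cmps[[length(cmps) + 1L]] <-
      new_comparison(paste0(a, "_vs_", b), a, b, "treatment")
  }
  cmps
}

# samples and 0/1 response of a comparison, in metadata order
comparison_design <- function(data, cmp) {
  stopifnot(inherits(data, "intensity_matrix"), inherits(cmp, "dap_comparison"))
  meta <- data$samples
  if (!all(c(cmp$group_a, cmp$group_b) %in% meta$group)) {
    stop("comparison groups not present in metadata")
  }
  idx <- which(meta$group %in% c(cmp$group_a, cmp$group_b))
  y <- as.integer(meta$group[idx] == cmp$group_a)
  if (sum(y) < 2L || sum(1L - y) < 2L) {
    stop("each comparison group needs at least 2 samples")
  }
  list(idx = idx, y = y, sample_ids = meta$sample_id[idx])
}
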