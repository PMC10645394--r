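#' Per-sample per-cell-type pseudobulks
#'
#' Collapses the cohort into one expression column per (sample, cell type)
#' pair: the arithmetic mean of the log-scaled expression of the pair's cells.
#' Pairs with fewer than `min_cells` cells are dropped (and reported in the
#' `dropped` element), since a pseudobulk over very few cells is dominated by
#' cell-level noise.
#'
#' @param cohort a [cell_cohort()].
#' @param min_cells minimum cells per (sample, cell type) pair; default 10.
#' @param conditions which sample conditions to pseudobulk; default both.
#'
#' @return An object of class `"pseudobulk_set"`: list with `values`
#'   (genes x columns matrix, columns named `"sample|celltype"`), `meta`
#'   (data.frame: column, sample_id, cell_type, condition, batch, n_cells)
#'   and `dropped` (pairs below the floor, with their cell counts).
#' @export
compute_pseudobulks <- function(cohort, min_cells = 10,
                                conditions = c("disease", "control")) {
  stopifnot(inherits(cohort, "cell_cohort"))
  conditions <- match.arg(conditions, c("disease", "control"),
                          several.ok = TRUE)
  if (min_cells < 1) stop("'min_cells' must be >= 1", call. = FALSE)
  cond <- .cond_of(cohort)
  batch <- .batch_of(cohort)

  keep_cell <- cond[cohort$cells$sample_id] %in% conditions
  if (!any(keep_cell))
    stop("no cells in the requested conditions", call. = FALSE)
  cells <- cohort$cells[keep_cell, , drop = FALSE]
  key <- paste(cells$sample_id, cells$cell_type, sep = "|")
  counts <- table(key)

  ok <- names(counts)[counts >= min_cells]
  if (length(ok) == 0L)
    stop("no pseudobulks: every (sample, cell type) pair has fewer than ",
         min_cells, " cells", call. = FALSE)
  ok <- sort(ok)

  # group means via a sparse indicator: values = E %*% G where G[cell, pair] = 1/n
  idx <- match(key, ok)
  in_ok <- !is.na(idx)
  G <- Matrix::sparseMatrix(
    i = which(keep_cell)[in_ok], j = idx[in_ok],
    x = 1 / as.numeric(counts[ok])[idx[in_ok]],
    dims = c(ncol(cohort$expression), length(ok)))
  values <- as.matrix(cohort$expression %*% G)
  dimnames(values) <- list(rownames(cohort$expression), ok)

  parts <- do.call(rbind, strsplit(ok, "|", fixed = TRUE))
  meta <- data.frame(
    column = ok, sample_id = parts[, 1], cell_type = parts[, 2],
    condition = unname(cond[parts[, 1]]), batch = unname(batch[parts[, 1]]),
    n_cells = as.integer(counts[ok]), stringsAsFactors = FALSE)

  drop_keys <- setdiff(names(counts), ok)
  dparts <- if (length(drop_keys)) do.call(rbind, strsplit(drop_keys, "|", fixed = TRUE)) else
    matrix(character(), 0, 2)
  dropped <- data.frame(sample_id = dparts[, 1], cell_type = dparts[, 2],
                        n_cells = as.integer(counts[drop_keys]),
                        stringsAsFactors = FALSE)

  structure(list(values = values, meta = meta, dropped = dropped),
            class = "pseudobulk_set")
}

#' @export
print.pseudobulk_set <- function(x, ...) {
  cat(sprintf("Pseudobulk set: %d genes x %d (sample, cell type) columns\n",
              nrow(x$values), ncol(x$values)))
  cat(sprintf("  conditions: %s; %d pair(s) dropped below the cell floor\n",
              paste(sort(unique(x$meta$condition)), collapse = "+"),
              nrow(x$dropped)))
  invisible(x)
}

#' Aggregate control reference per cell type (and batch)
#'
#' Builds one reference expression column per (cell type, batch) from the
#' cohort's control samples. Two aggregation modes are offered:
#' `"mean_of_sample_pseudobulks"` (default) averages per-control-sample
#' pseudobulks with equal weight per sample, so that one deeply sampled control
#' cannot dominate the reference; `"pooled_cells"` averages over all control
#' cells pooled, weighting samples by their cell counts.
#'
#' @param cohort a [cell_cohort()].
#' @param min_cells per-sample cell floor used when forming the contributing
#'   control pseudobulks (mean_of_sample_pseudobulks mode); pooled mode pools
#'   every control cell of the cell type.
#' @param mode aggregation mode, see Description.
#'
#' @return Class `"control_reference"`: list with `values` (genes x reference
#'   columns, named `"celltype|batch"`), `meta` (cell_type, batch,
#'   n_control_samples, n_cells) and `mode`.
#' @export
aggregate_control_reference <- function(cohort, min_cells = 10,
                                        mode = c("mean_of_sample_pseudobulks",
                                                 "pooled_cells")) {
  stopifnot(inherits(cohort, "cell_cohort"))
  mode <- match.arg(mode)
  cond <- .cond_of(cohort)
  batch <- .batch_of(cohort)
  if (!any(cond == "control"))
    stop("cohort has no control samples", call. = FALSE)

  is_ctrl_cell <- cond[cohort$cells$sample_id] == "control"
  cells <- cohort$cells[is_ctrl_cell, , drop = FALSE]
  cells$batch <- unname(batch[cells$sample_id])

  if (mode == "pooled_cells") {
    key <- paste(cells$cell_type, cells$batch, sep = "|")
    counts <- table(key)
    keys <- sort(names(counts))
    idx <- match(key, keys)
    G <- Matrix::sparseMatrix(
      i = which(is_ctrl_cell), j = idx,
      x = 1 / as.numeric(counts[keys])[idx],
      dims = c(ncol(cohort$expression), length(keys)))
    values <- as.matrix(cohort$expression %*% G)
    dimnames(values) <- list(rownames(cohort$expression), keys)
    nsamp <- vapply(keys, function(k)
      length(unique(cells$sample_id[key == k])), integer(1))
    ncell <- as.integer(counts[keys])
  } else {
    pb <- compute_pseudobulks(cohort, min_cells = min_cells,
                              conditions = "control")
    key <- paste(pb$meta$cell_type, pb$meta$batch, sep = "|")
    keys <- sort(unique(key))
    values <- matrix(vapply(keys, function(k)
      rowMeans(pb$values[, key == k, drop = FALSE]),
      numeric(nrow(pb$values))), nrow = nrow(pb$values))
    dimnames(values) <- list(rownames(pb$values), keys)
    nsamp <- vapply(keys, function(k) sum(key == k), integer(1))
    ncell <- vapply(keys, function(k)
      sum(pb$meta$n_cells[key == k]), integer(1))
  }

  parts <- do.call(rbind, strsplit(keys, "|", fixed = TRUE))
  structure(list(
    values = values,
    meta = data.frame(cell_type = parts[, 1], batch = parts[, 2],
                      n_control_samples = as.integer(nsamp),
                      n_cells = as.integer(ncell), stringsAsFactors = FALSE),
    mode = mode), class = "control_reference")
}

#' @export
print.control_reference <- function(x, ...) {
  cat(sprintf("Control reference (%s): %d genes x %d (cell type, batch) columns\n",
              x$mode, nrow(x$values), ncol(x$values)))
  invisible(x)
}

# shift each gene row so its minimum over columns is zero (non-negativity
# required by the factorization); idempotent because row minima become 0
.shift_nonneg <- function(raw) {
  gene_min <- apply(raw, 1, min)
  list(shifted = raw - gene_min, gene_min = gene_min)
}

.new_fold_matrix <- function(raw, meta) {
  sh <- .shift_nonneg(raw)
  structure(list(raw = raw, shifted = sh$shifted, gene_min = sh$gene_min,
                 meta = meta), class = "fold_matrix")
}

#' Control-normalized fold differentials
#'
#' Subtracts from every pseudobulk column the aggregate control reference of
#' its cell type (and batch). Because expression is log-scaled, this difference
#' of means is a log fold change. A non-negative variant (`shifted`) is also
#' produced by subtracting each gene's minimum fold across all columns of the
#' run, as required by the downstream factorization; the raw matrix is kept for
#' feature selection and reporting.
#'
#' @param pseudobulks a [compute_pseudobulks()] result (usually
#'   disease-condition columns).
#' @param reference an [aggregate_control_reference()] result.
#'
#' @return Class `"fold_matrix"`: list with `raw`, `shifted`, `gene_min` and
#'   the pseudobulk column `meta`.
#' @export
fold_differentials <- function(pseudobulks, reference) {
  stopifnot(inherits(pseudobulks, "pseudobulk_set"),
            inherits(reference, "control_reference"))
  refkey <- paste(pseudobulks$meta$cell_type, pseudobulks$meta$batch, sep = "|")
  missing_ref <- !(refkey %in% colnames(reference$values))
  if (any(missing_ref))
    stop("no control reference for column(s): ",
         paste(pseudobulks$meta$column[missing_ref], collapse = ", "),
         call. = FALSE)
  if (!identical(rownames(pseudobulks$values), rownames(reference$values)))
    stop("gene sets of pseudobulks and reference differ", call. = FALSE)
  raw <- pseudobulks$values - reference$values[, refkey, drop = FALSE]
  colnames(raw) <- pseudobulks$meta$column
  .new_fold_matrix(raw, pseudobulks$meta)
}

#' Self-fold differentials for control samples
#'
#' For cohort designs without a separate disease arm (for example population
#' cohorts of healthy donors), each control sample's pseudobulk is normalized
#' against the collective control average of its cell type, yielding
#' per-donor deviation profiles that can be clustered or projected like
#' disease folds.
#'
#' @inheritParams compute_pseudobulks
#' @param mode aggregation mode for the collective average, as in
#'   [aggregate_control_reference()].
#' @return A `"fold_matrix"` whose columns are flagged `condition = "control"`.
#' @export
control_self_folds <- function(cohort, min_cells = 10,
                               mode = c("mean_of_sample_pseudobulks",
                                        "pooled_cells")) {
  stopifnot(inherits(cohort, "cell_cohort"))
  mode <- match.arg(mode)
  if (sum(.cond_of(cohort) == "control") < 2)
    stop("self-folds need >= 2 control samples (a single control is ",
         "identically its own average)", call. = FALSE)
  pb <- compute_pseudobulks(cohort, min_cells = min_cells,
                            conditions = "control")
  ref <- aggregate_control_reference(cohort, min_cells = min_cells, mode = mode)
  fold_differentials(pb, ref)
}

#' @export
print.fold_matrix <- function(x, ...) {
  cat(sprintf("Fold matrix: %d genes x %d pseudobulk columns (raw + shifted)\n",
              nrow(x$raw), ncol(x$raw)))
  cat(sprintf("  conditions: %s\n",
              paste(sort(unique(x$meta$condition)), collapse = "+")))
  invisible(x)
}

# subset a fold matrix to a set of columns (used by projection tests/tools)
.subset_folds <- function(folds, cols) {
  keep <- folds$meta$column %in% cols
  .new_fold_matrix(folds$raw[, keep, drop = FALSE],
                   folds$meta[keep, , drop = FALSE])
}
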