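#' Assemble an annotated single-cell cohort
#'
#' Bundles a log-scaled gene-by-cell expression matrix with per-cell sample and
#' cell-type annotations and per-sample condition/batch labels. All downstream
#' pseudobulk and fold computations start from this container. Values are
#' expected to be log-scaled, QC'd expression (library-size normalization,
#' doublet removal and batch correction are upstream concerns); a heuristic
#' warning is emitted when the dynamic range looks like raw counts.
#'
#' @param expression numeric matrix (dense or `Matrix` sparse), genes in rows,
#'   cells in columns. Dimnames are required: rownames are gene identifiers,
#'   colnames are cell identifiers.
#' @param cell_sample character vector (named by cell or in column order)
#'   mapping each cell to its sample identifier.
#' @param cell_type character vector mapping each cell to a cell-type label.
#' @param sample_condition named character vector mapping each sample to
#'   `"disease"` or `"control"`.
#' @param sample_batch optional named character vector mapping samples to batch
#'   labels; unnamed samples fall in batch `"default"`.
#'
#' @return An object of class `"cell_cohort"`: a list with elements
#'   `expression`, `cells` (data.frame: cell_id, sample_id, cell_type) and
#'   `samples` (data.frame: sample_id, condition, batch).
#' @export
cell_cohort <- function(expression, cell_sample, cell_type,
                        sample_condition, sample_batch = NULL) {
  if (is.null(dim(expression)) || nrow(expression) < 1L || ncol(expression) < 1L)
    stop("'expression' must be a non-empty genes x cells matrix", call. = FALSE)
  if (is.null(rownames(expression)) || is.null(colnames(expression)))
    stop("'expression' needs gene rownames and cell colnames", call. = FALSE)
  n_cells <- ncol(expression)
  cell_ids <- colnames(expression)

  align_cellvec <- function(x, what) {
    if (length(x) != n_cells && !is.null(names(x)))
      x <- x[cell_ids]
    if (length(x) != n_cells || anyNA(x))
      stop("'", what, "' must cover every cell exactly once", call. = FALSE)
    x <- as.character(x)
    names(x) <- cell_ids
    x
  }
  cell_sample <- align_cellvec(cell_sample, "cell_sample")
  cell_type <- align_cellvec(cell_type, "cell_type")

  samples <- sort(unique(cell_sample))
  if (is.null(names(sample_condition)))
    stop("'sample_condition' must be named by sample", call. = FALSE)
  cond <- as.character(sample_condition[samples])
  if (anyNA(cond) || !all(cond %in% c("disease", "control")))
    stop("every sample needs a condition in {disease, control}; missing/invalid for: ",
         paste(samples[is.na(cond) | !cond %in% c("disease", "control")], collapse = ", "),
         call. = FALSE)
  if (is.null(sample_batch)) {
    batch <- rep("default", length(samples))
  } else {
    batch <- as.character(sample_batch[samples])
    batch[is.na(batch)] <- "default"
  }

  bad <- !is.finite(range(if (inherits(expression, "sparseMatrix"))
    expression@x else expression))
  if (any(bad))
    stop("expression contains non-finite values (NaN/Inf); inputs must be ",
         "finite log-scaled values", call. = FALSE)
  if (max(expression) >= 50)
    warning("maximum expression value >= 50: input may not be log-scaled",
            call. = FALSE)

  obj <- structure(list(
    expression = expression,
    cells = data.frame(cell_id = cell_ids, sample_id = unname(cell_sample),
                       cell_type = unname(cell_type), stringsAsFactors = FALSE),
    samples = data.frame(sample_id = samples, condition = cond, batch = batch,
                         stringsAsFactors = FALSE)
  ), class = "cell_cohort")

  # every batch holding disease samples must also hold at least one control
  sb <- obj$samples
  for (b in unique(sb$batch)) {
    in_b <- sb$batch == b
    if (any(sb$condition[in_b] == "disease") &&
        !any(sb$condition[in_b] == "control"))
      stop("batch '", b, "' contains disease samples but no control sample",
           call. = FALSE)
  }
  obj
}

#' @export
print.cell_cohort <- function(x, ...) {
  cat("Annotated single-cell cohort\n")
  cat(sprintf("  %d genes x %d cells\n", nrow(x$expression), ncol(x$expression)))
  cat(sprintf("  %d samples (%d disease, %d control), %d cell types, %d batch(es)\n",
              nrow(x$samples), sum(x$samples$condition == "disease"),
              sum(x$samples$condition == "control"),
              length(unique(x$cells$cell_type)),
              length(unique(x$samples$batch))))
  invisible(x)
}

# sample -> condition / batch lookups
.cond_of <- function(cohort) {
  stats::setNames(cohort$samples$condition, cohort$samples$sample_id)
}
.batch_of <- function(cohort) {
  stats::setNames(cohort$samples$batch, cohort$samples$sample_id)
}
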