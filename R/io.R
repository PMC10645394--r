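#' Read a cohort from disk
#'
#' Accepts either 10x-convention MatrixMarket input (`matrix.mtx` +
#' `features.tsv` + `barcodes.tsv` in a directory, genes as rows) or a dense
#' TSV (genes x cells, first column gene identifiers, header of cell ids),
#' plus a cell annotation TSV with columns `cell_id`, `sample_id`,
#' `cell_type`, `condition` and optional `batch`.
#'
#' @param expression path to a dense TSV file or to a directory holding
#'   `matrix.mtx`/`features.tsv`/`barcodes.tsv`.
#' @param annotation path to the cell annotation TSV.
#' @return a [cell_cohort()].
#' @export
read_cohort <- function(expression, annotation) {
  if (dir.exists(expression)) {
    mtx <- file.path(expression, "matrix.mtx")
    feat <- file.path(expression, "features.tsv")
    bc <- file.path(expression, "barcodes.tsv")
    for (f in c(mtx, feat, bc)) if (!file.exists(f))
      stop("missing expected file: ", f, call. = FALSE)
    m <- Matrix::readMM(mtx)
    features <- utils::read.delim(feat, header = FALSE,
                                  stringsAsFactors = FALSE)
    barcodes <- utils::read.delim(bc, header = FALSE,
                                  stringsAsFactors = FALSE)
    if (nrow(features) != nrow(m) || nrow(barcodes) != ncol(m))
      stop("features/barcodes do not match the matrix dimensions",
           call. = FALSE)
    dimnames(m) <- list(features[[1]], barcodes[[1]])
  } else {
    d <- utils::read.delim(expression, check.names = FALSE,
                           stringsAsFactors = FALSE)
    m <- as.matrix(d[, -1, drop = FALSE])
    rownames(m) <- d[[1]]
  }

  ann <- utils::read.delim(annotation, stringsAsFactors = FALSE)
  need <- c("cell_id", "sample_id", "cell_type", "condition")
  miss <- setdiff(need, names(ann))
  if (length(miss))
    stop("annotation table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!all(colnames(m) %in% ann$cell_id))
    stop("annotation table is missing ",
         sum(!colnames(m) %in% ann$cell_id), " cell id(s)", call. = FALSE)
  ann <- ann[match(colnames(m), ann$cell_id), , drop = FALSE]
  cond <- tapply(ann$condition, ann$sample_id, function(x) x[1])
  batch <- if ("batch" %in% names(ann))
    tapply(as.character(ann$batch), ann$sample_id, function(x) x[1]) else NULL
  cell_cohort(m, cell_sample = ann$sample_id, cell_type = ann$cell_type,
              sample_condition = cond, sample_batch = batch)
}

#' Write a cohort as dense TSV + annotation TSV
#'
#' @param cohort a [cell_cohort()].
#' @param dir output directory (created if missing); writes
#'   `expression.tsv` and `annotation.tsv`.
#' @return invisibly, the directory.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cell_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  expr <- as.matrix(cohort$expression)
  df <- data.frame(gene = rownames(expr), expr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, file.path(dir, "expression.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  ann <- merge(cohort$cells, cohort$samples, by = "sample_id", sort = FALSE)
  ann <- ann[match(cohort$cells$cell_id, ann$cell_id),
             c("cell_id", "sample_id", "cell_type", "condition", "batch")]
  utils::write.table(ann, file.path(dir, "annotation.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a per-sample binary covariate table
#'
#' TSV with a `sample_id` column, one column per binary covariate (1/0/NA;
#' thresholding of continuous measurements is the user's responsibility) and
#' optionally a stratum column for confounder-adjusted testing.
#'
#' @param path TSV path.
#' @param confounder optional stratum column name, kept as character.
#' @return data.frame.
#' @export
read_covariates <- function(path, confounder = NULL) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(d))
    stop("covariate table needs a 'sample_id' column", call. = FALSE)
  for (cl in setdiff(names(d), c("sample_id", confounder))) {
    v <- d[[cl]]
    if (!all(is.na(v) | v %in% c(0, 1)))
      stop("covariate '", cl, "' is not binary (1/0/NA); threshold it ",
           "before input", call. = FALSE)
    d[[cl]] <- as.integer(v)
  }
  d
}

# genes x columns matrix -> TSV with a leading gene column
.write_matrix_tsv <- function(m, path) {
  df <- data.frame(gene = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Write a pseudobulk matrix and its column metadata
#'
#' Writes `pseudobulks.tsv` (genes x "sample|celltype" columns) and
#' `pseudobulk_columns.tsv` (sample, cell type, condition, batch, n_cells).
#'
#' @param pseudobulks a [compute_pseudobulks()] result.
#' @param dir output directory.
#' @return invisibly, the directory.
#' @export
write_pseudobulks <- function(pseudobulks, dir) {
  stopifnot(inherits(pseudobulks, "pseudobulk_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  .write_matrix_tsv(pseudobulks$values, file.path(dir, "pseudobulks.tsv"))
  utils::write.table(pseudobulks$meta,
                     file.path(dir, "pseudobulk_columns.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Write fold-matrix artifacts
#'
#' Writes `folds_raw.tsv`, `folds_shifted.tsv` (genes x "sample|celltype"
#' columns) and `fold_columns.tsv` (column metadata: sample, cell type,
#' condition, batch, n_cells).
#'
#' @param folds a `"fold_matrix"`.
#' @param dir output directory.
#' @return invisibly, the directory.
#' @export
write_folds <- function(folds, dir) {
  stopifnot(inherits(folds, "fold_matrix"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  .write_matrix_tsv(folds$raw, file.path(dir, "folds_raw.tsv"))
  .write_matrix_tsv(folds$shifted, file.path(dir, "folds_shifted.tsv"))
  utils::write.table(folds$meta, file.path(dir, "fold_columns.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Write model artifacts
#'
#' Writes cluster labels (`labels.tsv`), the marker table (`markers.tsv`),
#' the per-resolution sweep report (`sweep.tsv`) and a JSON dump of the model
#' (`model.json`: labels, k, guide genes, markers, centroids, parameters) —
#' enough to reload the model with [read_udon_model()] for projection and
#' association testing.
#'
#' @param model a fitted [udon()] model.
#' @param dir output directory.
#' @return invisibly, the directory.
#' @export
write_udon_model <- function(model, dir) {
  stopifnot(inherits(model, "udon"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  lab <- data.frame(column = names(model$labels),
                    sample_id = model$meta$sample_id[
                      match(names(model$labels), model$meta$column)],
                    cell_type = model$meta$cell_type[
                      match(names(model$labels), model$meta$column)],
                    cluster = unname(model$labels), stringsAsFactors = FALSE)
  utils::write.table(lab, file.path(dir, "labels.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(model$markers, file.path(dir, "markers.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(model$sweep, file.path(dir, "sweep.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  dump <- list(
    k_used = model$k_used,
    labels = as.list(stats::setNames(ifelse(is.na(model$labels), "",
                                            model$labels),
                                     names(model$labels))),
    guide_genes = model$guide_genes,
    markers = model$markers,
    centroid_genes = rownames(model$centroids),
    centroids = {
      cd <- as.data.frame(model$centroids)
      rownames(cd) <- NULL
      cd
    },
    dropped_clusters = model$dropped_clusters,
    sweep = model$sweep,
    meta = model$meta,
    params = unclass(model$params))
  jsonlite::write_json(dump, file.path(dir, "model.json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "columns")
  invisible(dir)
}

#' Reload a model written by [write_udon_model()]
#'
#' Restores the parts of the model needed for projection and association
#' testing (labels, markers, centroids, metadata, parameters). The NMF
#' factors themselves are not round-tripped.
#'
#' @param dir directory holding `model.json`.
#' @return an `"udon"` object.
#' @export
read_udon_model <- function(dir) {
  path <- file.path(dir, "model.json")
  if (!file.exists(path)) stop("no model.json under ", dir, call. = FALSE)
  d <- jsonlite::read_json(path, simplifyVector = TRUE)
  labels <- unlist(d$labels)
  labels[labels == ""] <- NA_character_
  cen <- do.call(cbind, d$centroids[setdiff(names(d$centroids), "_row")])
  rownames(cen) <- d$centroid_genes
  markers <- as.data.frame(d$markers)
  params <- d$params
  class(params) <- "udon_params"
  structure(list(labels = labels, k_used = d$k_used, basis = NULL,
                 coefficients = NULL, guide_genes = d$guide_genes,
                 markers = structure(markers,
                                     cutoff = params$marker_pearson_cutoff,
                                     class = c("marker_table", "data.frame")),
                 centroids = cen, dropped_clusters = d$dropped_clusters,
                 sweep = as.data.frame(d$sweep),
                 meta = as.data.frame(d$meta), params = params),
            class = "udon")
}

#' Write association results
#'
#' Writes the full results TSV and the dot-plot ready export.
#'
#' @param results a `"satay"` object.
#' @param dir output directory.
#' @return invisibly, the directory.
#' @export
write_satay <- function(results, dir) {
  stopifnot(inherits(results, "satay"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(as.data.frame(results),
                     file.path(dir, "associations.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(satay_dotplot_data(results),
                     file.path(dir, "associations_dotplot.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
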