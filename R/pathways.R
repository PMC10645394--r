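#' Read a GMT gene-set collection
#'
#' Thin wrapper over `fgsea::gmtPathways()` (MSigDB convention: set name,
#' description, then tab-separated genes).
#'
#' @param path GMT file path.
#' @return named list of character gene vectors.
#' @export
read_gmt <- function(path) {
  if (!requireNamespace("fgsea", quietly = TRUE))
    stop("reading GMT files requires the 'fgsea' package", call. = FALSE)
  sets <- fgsea::gmtPathways(path)
  if (!length(sets)) stop("GMT file contains no gene sets", call. = FALSE)
  sets
}

#' Pathway over-representation of cluster markers
#'
#' For each cluster, tests whether its marker genes are over-represented in
#' each gene set by the one-sided Fisher exact (hypergeometric upper-tail)
#' test. The background universe is the intersection of the fold matrix's
#' genes (`universe`) with the union of the gene-set collection. P-values are
#' BH-adjusted within each cluster.
#'
#' @param model a fitted [udon()] model.
#' @param gene_sets named list of gene vectors (see [read_gmt()]).
#' @param universe character vector of background genes; defaults to the
#'   model's guide genes. Pass all genes of the fold matrix for a
#'   genome-wide background.
#' @param top_n report at most this many sets per cluster (default 10).
#' @return data.frame: cluster, gene_set, n_overlap, n_markers, n_set,
#'   n_universe, p_value, fdr_adjusted_p, genes (semicolon-joined overlap).
#' @export
annotate_cluster_pathways <- function(model, gene_sets,
                                      universe = model$guide_genes,
                                      top_n = 10) {
  stopifnot(inherits(model, "udon"))
  if (!length(gene_sets)) stop("empty gene-set collection", call. = FALSE)
  universe <- intersect(universe, unique(unlist(gene_sets)))
  sets <- lapply(gene_sets, intersect, y = universe)
  rows <- list()
  for (u in sort(unique(model$markers$assigned_cluster))) {
    mk <- intersect(model$markers$gene[model$markers$assigned_cluster == u],
                    universe)
    if (!length(mk)) next
    for (gs in names(sets)) {
      set <- sets[[gs]]
      ov <- intersect(mk, set)
      ft <- fisher_one_sided(length(ov), length(mk) - length(ov),
                             length(set) - length(ov),
                             length(universe) - length(set) - length(mk) +
                               length(ov))
      rows[[length(rows) + 1L]] <- data.frame(
        cluster = u, gene_set = gs, n_overlap = length(ov),
        n_markers = length(mk), n_set = length(set),
        n_universe = length(universe), p_value = ft$p_value,
        genes = paste(sort(ov), collapse = ";"), stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(cluster = character(), gene_set = character(),
                      n_overlap = integer(), n_markers = integer(),
                      n_set = integer(), n_universe = integer(),
                      p_value = numeric(), fdr_adjusted_p = numeric(),
                      genes = character()))
  out <- do.call(rbind, rows)
  out$fdr_adjusted_p <- bh_adjust(out$p_value, out$cluster)
  out <- out[order(out$cluster, out$p_value, out$gene_set), , drop = FALSE]
  keep <- unlist(lapply(split(seq_len(nrow(out)), out$cluster),
                        function(i) i[seq_len(min(top_n, length(i)))]),
                 use.names = FALSE)
  out <- out[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}
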