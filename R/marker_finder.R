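#' MarkerFinder: template-correlation marker assignment
#'
#' Assigns every gene to the cluster whose idealized expression template it
#' best matches. The template of a cluster is its membership indicator over
#' columns (1 inside the cluster, 0 outside); each gene row is correlated
#' (Pearson) with every template, assigned to its maximum-correlation cluster
#' (ties to the lowest cluster index), and retained as a marker when that
#' maximum reaches `cutoff`. Because every gene is assigned to at most one
#' cluster, the resulting per-cluster marker sets are unique by construction.
#'
#' @param x numeric genes x columns matrix (typically shifted folds restricted
#'   to guide genes).
#' @param labels cluster label per column (vector, length `ncol(x)`); at least
#'   two distinct clusters are required.
#' @param cutoff minimum template correlation to retain a marker (default 0.2).
#'
#' @return A `"marker_table"` data.frame with columns `gene`,
#'   `assigned_cluster`, `pearson_r`, `rank` (contiguous from 1 within each
#'   cluster, ordered by descending r, ties by gene identifier). Constant gene
#'   rows have undefined correlation and are excluded; their count is stored in
#'   `attr(, "n_constant_excluded")`, and the cutoff in `attr(, "cutoff")`.
#' @export
marker_finder <- function(x, labels, cutoff = 0.2) {
  x <- as.matrix(x)
  if (length(labels) != ncol(x))
    stop("'labels' must label every column", call. = FALSE)
  if (anyNA(labels)) stop("every column must be labeled", call. = FALSE)
  labels <- as.character(labels)
  clusters <- sort(unique(labels))
  if (length(clusters) < 2)
    stop("MarkerFinder needs >= 2 clusters (templates are degenerate ",
         "otherwise)", call. = FALSE)

  templates <- vapply(clusters, function(cl) as.numeric(labels == cl),
                      numeric(ncol(x)))
  sds <- apply(x, 1, stats::sd)
  usable <- sds > 0
  n_const <- sum(!usable)

  R <- suppressWarnings(stats::cor(t(x[usable, , drop = FALSE]), templates))
  best <- apply(R, 1, which.max)            # ties: lowest cluster index
  best_r <- R[cbind(seq_len(nrow(R)), best)]

  keep <- !is.na(best_r) & best_r >= cutoff
  tab <- data.frame(gene = rownames(x)[usable][keep],
                    assigned_cluster = clusters[best[keep]],
                    pearson_r = unname(best_r[keep]),
                    stringsAsFactors = FALSE)
  tab <- tab[order(tab$assigned_cluster, -tab$pearson_r, tab$gene), ,
             drop = FALSE]
  tab$rank <- stats::ave(tab$pearson_r, tab$assigned_cluster,
                         FUN = seq_along)
  rownames(tab) <- NULL
  structure(tab, cutoff = cutoff, n_constant_excluded = n_const,
            class = c("marker_table", "data.frame"))
}

#' Top-ranked markers per cluster
#'
#' @param table a [marker_finder()] result.
#' @param n markers to keep per cluster (default 10); clusters with fewer
#'   return all they have.
#' @return named list, one character vector of genes per cluster, in rank
#'   order.
#' @export
top_markers <- function(table, n = 10) {
  stopifnot(inherits(table, "marker_table"))
  if (n < 0) stop("'n' must be >= 0", call. = FALSE)
  out <- lapply(split(table, table$assigned_cluster), function(d)
    d$gene[d$rank <= n])
  out[order(names(out))]
}

#' @export
print.marker_table <- function(x, ...) {
  cat(sprintf("Marker table: %d markers across %d clusters (cutoff r >= %g)\n",
              nrow(x), length(unique(x$assigned_cluster)),
              attr(x, "cutoff")))
  NextMethod()
}
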