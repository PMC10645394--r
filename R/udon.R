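#' Parameters controlling cluster discovery
#'
#' Collects the tunable parameters of the discovery stage. Defaults follow the
#' published protocol: sparsity `rho = 0.3`, marker retention cutoff
#' `marker_pearson_cutoff = 0.2`, feature-selection fold threshold
#' `fold_diff = 2` (interpreted on the scale the folds were computed on:
#' `|raw fold| >= log(fold_diff, log_base)` with `log_base = 2`), and a
#' resolution sweep over `k_values = c(10, 15, 20, 30)`.
#'
#' @param rho L1 sparsity weight on the NMF coefficients, in (0, 1).
#' @param marker_pearson_cutoff template-correlation floor for retaining a
#'   cluster marker.
#' @param fold_diff minimum fold change (linear scale, > 1) for guide-gene
#'   selection.
#' @param log_base base of the log scale the expression input uses (2 by
#'   default; set `exp(1)` for natural-log input).
#' @param k_values candidate NMF resolutions to sweep.
#' @param min_columns minimum number of columns in which a guide gene must
#'   exceed the fold threshold.
#' @param guide_cor minimum Pearson correlation with at least one other
#'   selected gene for a guide gene to be kept.
#' @param max_genes cap on guide genes, by dynamic-range rank.
#' @param stability_margin sweep plateau tolerance: the smallest k whose final
#'   cluster count is within this margin of the next larger k's count is
#'   chosen. The default of 1 keeps an under-resolved k (which reports about
#'   k merged clusters, typically well below the next resolution's count)
#'   from masquerading as a plateau.
#' @param n_restarts NMF restarts per k.
#' @param max_iter,tol NMF iteration cap and convergence tolerance.
#' @param seed integer seed for the NMF restarts.
#' @return list of class `"udon_params"`.
#' @export
udon_params <- function(rho = 0.3, marker_pearson_cutoff = 0.2, fold_diff = 2,
                        log_base = 2, k_values = c(10, 15, 20, 30),
                        min_columns = 2, guide_cor = 0.4, max_genes = 5000,
                        stability_margin = 1, n_restarts = 10, max_iter = 300,
                        tol = 1e-5, seed = 42) {
  if (rho <= 0 || rho >= 1) stop("'rho' must be in (0, 1)", call. = FALSE)
  if (fold_diff <= 1) stop("'fold_diff' must be > 1", call. = FALSE)
  if (any(k_values < 2)) stop("all 'k_values' must be >= 2", call. = FALSE)
  structure(list(rho = rho, marker_pearson_cutoff = marker_pearson_cutoff,
                 fold_diff = fold_diff, log_base = log_base,
                 k_values = sort(unique(as.integer(k_values))),
                 min_columns = min_columns, guide_cor = guide_cor,
                 max_genes = max_genes, stability_margin = stability_margin,
                 n_restarts = n_restarts, max_iter = max_iter, tol = tol,
                 seed = as.integer(seed)),
            class = "udon_params")
}

#' Guide-gene selection
#'
#' Restricts clustering to genes that carry signal: a gene is kept when its
#' raw fold exceeds the fold threshold (in absolute value) in at least
#' `min_columns` columns and it correlates (Pearson `>= guide_cor`) with at
#' least one other such gene, capped at `max_genes` by dynamic range
#' (max minus min raw fold). The selection is deterministic.
#'
#' @param folds a [fold_differentials()] result.
#' @param params a [udon_params()] list.
#' @return character vector of selected gene identifiers.
#' @export
select_guide_genes <- function(folds, params = udon_params()) {
  stopifnot(inherits(folds, "fold_matrix"))
  raw <- folds$raw
  thr <- log(params$fold_diff, params$log_base)
  n_hit <- rowSums(abs(raw) >= thr)
  cand <- which(n_hit >= params$min_columns)
  dyn <- apply(raw, 1, max) - apply(raw, 1, min)
  # keep the correlation step tractable on very wide candidate sets
  if (length(cand) > 2L * params$max_genes)
    cand <- cand[order(dyn[cand], decreasing = TRUE)[seq_len(2L * params$max_genes)]]
  if (length(cand) >= 2) {
    R <- suppressWarnings(stats::cor(t(raw[cand, , drop = FALSE])))
    diag(R) <- NA
    has_partner <- apply(R, 1, function(r) any(r >= params$guide_cor,
                                               na.rm = TRUE))
    cand <- cand[has_partner]
  } else {
    cand <- integer(0)
  }
  if (length(cand) < 10)
    stop("fewer than 10 guide genes survive selection; consider relaxing ",
         "'fold_diff' or 'min_columns'", call. = FALSE)
  if (length(cand) > params$max_genes)
    cand <- cand[order(dyn[cand], decreasing = TRUE)[seq_len(params$max_genes)]]
  sort(rownames(raw)[cand])
}

# Marker-validated cluster finalization: iteratively drop provisional clusters
# without any unique marker at the cutoff, reassigning their columns to the
# surviving component with the largest coefficient (or leaving them
# unassigned when all surviving coefficients are ~0). Returns the final
# labels, marker table and the dropped component ids.
.finalize_labels <- function(fit, guide_shifted, cutoff) {
  labels <- fit$labels                         # integer component per column
  H <- fit$coefficients
  dropped <- integer(0)
  repeat {
    live <- sort(unique(labels[!is.na(labels)]))
    if (length(live) < 2)
      stop("no marker-supported structure: fewer than two clusters remain ",
           "after marker validation", call. = FALSE)
    lab_ok <- !is.na(labels)
    # zero-padded labels keep lexicographic == numeric component order
    mk <- marker_finder(guide_shifted[, lab_ok, drop = FALSE],
                        sprintf("%03d", labels[lab_ok]), cutoff = cutoff)
    supported <- as.integer(unique(mk$assigned_cluster))
    bad <- setdiff(live, supported)
    if (length(bad) == 0)
      return(list(labels = labels, markers = mk, dropped = sort(dropped)))
    dropped <- c(dropped, bad)
    survivors <- setdiff(live, bad)
    for (col in which(labels %in% bad)) {
      h <- H[survivors, col]
      labels[col] <- if (max(h) > 1e-8) survivors[which.max(h)] else NA_integer_
    }
  }
}

#' Discover patient-program clusters from fold differentials
#'
#' The main fitting function. Selects guide genes from the raw folds, runs
#' sparse NMF on the non-negative shifted folds restricted to those genes at
#' each candidate resolution `k`, validates every provisional cluster by
#' requiring at least one unique marker gene (template correlation `>=`
#' `marker_pearson_cutoff`), drops unsupported clusters (reassigning their
#' columns), and keeps the resolution whose final cluster count has stabilized
#' (smallest k within `stability_margin` of the next larger k's count, else
#' the largest tested k). Pass a single value in `k` to skip the sweep and fix
#' the resolution, as when reproducing a previously chosen model.
#'
#' @param folds a [fold_differentials()] (or [control_self_folds()]) result.
#' @param params a [udon_params()] list.
#' @param k optional explicit resolution overriding the sweep.
#'
#' @return Object of class `"udon"`: list with `labels` (named character
#'   vector, `"U1"`..`"Un"` or `NA` per column), `k_used`, `basis`,
#'   `coefficients`, `guide_genes`, `markers` (a [marker_finder()] table on
#'   final labels, cluster ids renamed), `centroids` (mean shifted fold of
#'   each cluster over its marker genes), `dropped_clusters`, `sweep`
#'   (per-k report), `meta` (column annotations), `params`.
#' @export
udon <- function(folds, params = udon_params(), k = NULL) {
  stopifnot(inherits(folds, "fold_matrix"))
  guides <- select_guide_genes(folds, params)
  gs <- folds$shifted[guides, , drop = FALSE]

  k_values <- if (is.null(k)) params$k_values else as.integer(k)
  k_values <- k_values[k_values < ncol(gs)]
  if (length(k_values) == 0)
    stop("all requested resolutions are >= the number of pseudobulk columns",
         call. = FALSE)

  per_k <- vector("list", length(k_values))
  for (i in seq_along(k_values)) {
    kk <- k_values[i]
    fit <- snmf_factorize(gs, kk, rho = params$rho,
                          n_restarts = params$n_restarts,
                          max_iter = params$max_iter, tol = params$tol,
                          seed = params$seed + kk)
    fin <- .finalize_labels(fit, gs, params$marker_pearson_cutoff)
    per_k[[i]] <- list(k = kk, fit = fit, fin = fin,
                       n_final = length(unique(fin$labels[!is.na(fin$labels)])))
  }
  counts <- vapply(per_k, `[[`, integer(1), "n_final")
  sweep_report <- data.frame(k = k_values, n_final_clusters = counts,
                             recon_error = vapply(per_k, function(p)
                               p$fit$recon_error, numeric(1)))

  pick <- length(k_values)
  if (length(k_values) > 1) {
    for (i in seq_len(length(k_values) - 1)) {
      if (abs(counts[i] - counts[i + 1]) <= params$stability_margin) {
        pick <- i
        break
      }
    }
  }
  chosen <- per_k[[pick]]

  # contiguous renumbering U1..Un in component-index order
  live <- sort(unique(chosen$fin$labels[!is.na(chosen$fin$labels)]))
  # zero-padded cluster ids ("U01") keep lexicographic sorting numeric
  newname <- stats::setNames(sprintf("U%02d", seq_along(live)),
                             sprintf("%03d", live))
  labels <- stats::setNames(rep(NA_character_, ncol(gs)), colnames(gs))
  ok <- !is.na(chosen$fin$labels)
  labels[ok] <- newname[sprintf("%03d", chosen$fin$labels[ok])]

  markers <- chosen$fin$markers
  markers$assigned_cluster <- unname(newname[markers$assigned_cluster])
  markers <- markers[order(markers$assigned_cluster, markers$rank), ,
                     drop = FALSE]
  rownames(markers) <- NULL

  centroids <- .marker_centroids(folds, labels, markers)

  structure(list(
    labels = labels, k_used = chosen$k,
    basis = chosen$fit$basis, coefficients = chosen$fit$coefficients,
    guide_genes = guides, markers = markers, centroids = centroids,
    dropped_clusters = chosen$fin$dropped, sweep = sweep_report,
    meta = folds$meta, params = params,
    recon_error = chosen$fit$recon_error), class = "udon")
}

# per-cluster mean shifted-fold vector over the model's marker genes
.marker_centroids <- function(folds, labels, markers) {
  genes <- sort(unique(markers$gene))
  cl <- sort(unique(labels[!is.na(labels)]))
  cen <- vapply(cl, function(u)
    rowMeans(folds$shifted[genes, which(labels == u), drop = FALSE]),
    numeric(length(genes)))
  cen <- matrix(cen, nrow = length(genes), dimnames = list(genes, cl))
  cen
}

#' @export
print.udon <- function(x, ...) {
  n_cl <- length(unique(x$labels[!is.na(x$labels)]))
  cat("UDON model of control-normalized pseudobulk differentials\n")
  cat(sprintf("  %d final clusters at k = %d (%d component(s) dropped without unique markers)\n",
              n_cl, x$k_used, length(x$dropped_clusters)))
  cat(sprintf("  %d pseudobulk columns (%d unassigned), %d guide genes, %d marker genes\n",
              length(x$labels), sum(is.na(x$labels)),
              length(x$guide_genes), nrow(x$markers)))
  invisible(x)
}

#' @export
summary.udon <- function(object, n_markers = 5, ...) {
  print(object)
  cat("\nResolution sweep:\n")
  print(object$sweep, row.names = FALSE)
  cat("\nCluster composition and top markers:\n")
  tm <- top_markers(object$markers, n_markers)
  for (u in sort(unique(object$labels[!is.na(object$labels)]))) {
    cols <- names(object$labels)[!is.na(object$labels) & object$labels == u]
    cts <- sort(unique(object$meta$cell_type[match(cols, object$meta$column)]))
    cat(sprintf("  %s: %d pseudobulks, cell types [%s]; markers: %s\n",
                u, length(cols), paste(cts, collapse = ", "),
                paste(tm[[u]], collapse = ", ")))
  }
  invisible(object)
}

#' @export
coef.udon <- function(object, ...) object$coefficients

#' Cluster membership heatmap
#'
#' Plots the shifted fold values of the model's marker genes across
#' pseudobulk columns, ordered by cluster, as a simple image heatmap.
#'
#' @param x an `"udon"` model.
#' @param folds the fold matrix the model was fit on.
#' @param ... passed to [graphics::image()].
#' @export
plot.udon <- function(x, folds, ...) {
  stopifnot(inherits(folds, "fold_matrix"))
  ord <- order(x$labels, na.last = TRUE)
  genes <- x$markers$gene[order(x$markers$assigned_cluster, x$markers$rank)]
  m <- folds$shifted[genes, ord, drop = FALSE]
  graphics::image(t(m), axes = FALSE, xlab = "pseudobulks (by cluster)",
                  ylab = "marker genes (by cluster)", ...)
  invisible(x)
}
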