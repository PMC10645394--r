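#' Project cluster labels onto a new cohort
#'
#' Assigns each new pseudobulk fold column to the training cluster whose
#' marker-gene centroid it correlates with best (Pearson, over the marker
#' genes shared between the model and the new cohort). Columns whose best
#' correlation falls below `min_r` stay unassigned. New-cohort folds must be
#' computed against the new cohort's own controls.
#'
#' @param model a fitted [udon()] model.
#' @param new_folds a `"fold_matrix"` for the new cohort.
#' @param min_r assignment correlation floor (default 0.2).
#' @param min_shared minimum shared marker genes required (default 20).
#' @return data.frame: column, projected_cluster (NA when unassigned),
#'   correlation.
#' @export
project_labels <- function(model, new_folds, min_r = 0.2, min_shared = 20) {
  stopifnot(inherits(model, "udon"), inherits(new_folds, "fold_matrix"))
  shared <- intersect(rownames(model$centroids), rownames(new_folds$shifted))
  if (length(shared) < min_shared)
    stop("only ", length(shared), " marker genes shared with the new cohort ",
         "(need >= ", min_shared, ")", call. = FALSE)
  shared <- sort(shared)
  cen <- model$centroids[shared, , drop = FALSE]
  x <- new_folds$shifted[shared, , drop = FALSE]
  R <- suppressWarnings(stats::cor(x, cen))
  best <- apply(R, 1, function(r) if (all(is.na(r))) NA_integer_ else
    which.max(r))
  best_r <- ifelse(is.na(best), NA_real_,
                   R[cbind(seq_len(nrow(R)), best)])
  assigned <- !is.na(best_r) & best_r >= min_r
  data.frame(
    column = colnames(x),
    projected_cluster = ifelse(assigned, colnames(cen)[best], NA_character_),
    correlation = as.numeric(best_r),
    stringsAsFactors = FALSE)
}

#' @describeIn udon projection of new fold columns onto the model's clusters
#'   (see [project_labels()]).
#' @param object an `"udon"` model.
#' @param newdata a `"fold_matrix"`; defaults to self-projection is not
#'   offered — pass the training folds explicitly to audit self-consistency.
#' @param ... passed to [project_labels()].
#' @export
predict.udon <- function(object, newdata, ...) {
  project_labels(object, newdata, ...)
}

#' Joint 2-D embedding of fold cohorts
#'
#' Fits a 2-D UMAP neighbor embedding on the reference fold columns over a
#' common gene space and transforms any further cohorts into the same
#' coordinates. Purely for visualization.
#'
#' @param reference a `"fold_matrix"` defining the embedding.
#' @param others optional list of `"fold_matrix"` objects to transform in.
#' @param genes gene space (default: the genes of `reference`; typically the
#'   model's marker genes).
#' @param n_neighbors UMAP neighborhood size (default 15, capped below the
#'   reference column count).
#' @param min_dist minimum embedded point spacing; 0 by default so identical
#'   or near-identical columns land coincident, which is the property a
#'   cohort-overlap plot relies on.
#' @param seed integer seed; the embedding is reproducible given it.
#' @return data.frame: column, cohort ("reference" or the list name/index),
#'   dim1, dim2.
#' @export
joint_embed <- function(reference, others = NULL,
                        genes = rownames(reference$shifted),
                        n_neighbors = 15, min_dist = 0, seed = 42) {
  stopifnot(inherits(reference, "fold_matrix"))
  genes <- intersect(genes, rownames(reference$shifted))
  if (!length(genes)) stop("empty shared gene space", call. = FALSE)
  ref <- t(reference$shifted[genes, , drop = FALSE])
  nn <- max(2, min(n_neighbors, nrow(ref) - 1))
  set.seed(seed)
  fit <- uwot::umap(ref, n_neighbors = nn, n_components = 2,
                    min_dist = min_dist, ret_model = TRUE, n_threads = 1,
                    n_sgd_threads = 1, batch = TRUE)
  out <- data.frame(column = rownames(ref), cohort = "reference",
                    dim1 = fit$embedding[, 1], dim2 = fit$embedding[, 2],
                    stringsAsFactors = FALSE)
  if (!is.null(others)) {
    if (inherits(others, "fold_matrix")) others <- list(others)
    nms <- names(others)
    if (is.null(nms)) nms <- paste0("cohort", seq_along(others))
    for (i in seq_along(others)) {
      miss <- setdiff(genes, rownames(others[[i]]$shifted))
      if (length(miss))
        stop("cohort '", nms[i], "' lacks ", length(miss),
             " embedding genes", call. = FALSE)
      nw <- t(others[[i]]$shifted[genes, , drop = FALSE])
      emb <- uwot::umap_transform(nw, fit, n_threads = 1, n_sgd_threads = 1)
      out <- rbind(out, data.frame(column = rownames(nw), cohort = nms[i],
                                   dim1 = emb[, 1], dim2 = emb[, 2],
                                   stringsAsFactors = FALSE))
    }
  }
  rownames(out) <- NULL
  out
}
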