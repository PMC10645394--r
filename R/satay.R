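#' One-sided Fisher exact test for positive enrichment
#'
#' Tests whether covariate-positive pseudobulks are over-represented inside a
#' cluster. With margins fixed, the in-cluster positive count Q is
#' hypergeometric; the one-sided p-value is the upper tail `P(X >= Q)`. The
#' odds ratio is the cross-product ratio `(Q*T)/(R*S)` (`NaN` when 0/0,
#' `Inf` when x/0).
#'
#' @param q,r,s,t contingency counts: positives in / not in the cluster (q, r)
#'   and negatives in / not in the cluster (s, t).
#' @return list with `p_value` and `odds_ratio`.
#' @export
fisher_one_sided <- function(q, r, s, t) {
  counts <- c(q, r, s, t)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("contingency counts must be non-negative integers", call. = FALSE)
  p <- stats::phyper(q - 1, m = q + r, n = s + t, k = q + s,
                     lower.tail = FALSE)
  or <- if (r * s == 0) {
    if (q * t == 0) NaN else Inf
  } else (q * t) / (r * s)
  list(p_value = min(1, p), odds_ratio = or)
}

#' Gated one-sided Cochran-Mantel-Haenszel test
#'
#' Pools 2x2 contingency tables across strata of a confounding variable.
#' Strata whose in-cluster positive count falls below `stratum_gate` are
#' dropped (logged via the returned `n_strata_used`). The chi-square statistic
#' uses the standard Mantel-Haenszel variance (continuity correction off by
#' default); the one-sided p-value follows the positive-enrichment direction:
#' half the two-sided chi-square p when the pooled association is positive,
#' `1 - p/2` otherwise. The Mantel-Haenszel odds ratio is
#' `sum(Q_i T_i / N_i) / sum(R_i S_i / N_i)`.
#'
#' @param strata data.frame (or list coercible to one) with columns
#'   `q, r, s, t`, one row per stratum.
#' @param stratum_gate minimum in-cluster positive count per retained stratum
#'   (default 2).
#' @param correct apply the 0.5 continuity correction (default FALSE).
#' @return list with `p_value`, `odds_ratio` (MH), `statistic`,
#'   `n_strata_used`, `testable`. When every stratum is dropped or the pooled
#'   variance is zero the result is flagged untestable (`p_value = NA`).
#' @export
cmh_test <- function(strata, stratum_gate = 2, correct = FALSE) {
  strata <- as.data.frame(strata)
  stopifnot(all(c("q", "r", "s", "t") %in% names(strata)))
  keep <- strata$q >= stratum_gate
  strata <- strata[keep, , drop = FALSE]
  if (nrow(strata) == 0)
    return(list(p_value = NA_real_, odds_ratio = NA_real_,
                statistic = NA_real_, n_strata_used = 0L, testable = FALSE))
  Q <- strata$q; R <- strata$r; S <- strata$s; T <- strata$t
  N <- Q + R + S + T
  E <- (Q + R) * (Q + S) / N
  V <- (Q + R) * (S + T) * (Q + S) * (R + T) / (N^2 * (N - 1))
  V[!is.finite(V)] <- 0
  num <- sum(Q - E)
  or_num <- sum(Q * T / N)
  or_den <- sum(R * S / N)
  or <- if (or_den == 0) {
    if (or_num == 0) NaN else Inf
  } else or_num / or_den
  if (sum(V) == 0)
    return(list(p_value = NA_real_, odds_ratio = or, statistic = NA_real_,
                n_strata_used = nrow(strata), testable = FALSE))
  cc <- if (correct) 0.5 else 0
  stat <- (max(abs(num) - cc, 0))^2 / sum(V)
  p2 <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  positive <- num > 0
  p <- if (positive) p2 / 2 else 1 - p2 / 2
  list(p_value = p, odds_ratio = or, statistic = stat,
       n_strata_used = nrow(strata), testable = TRUE)
}

#' Benjamini-Hochberg adjustment within covariate families
#'
#' Standard step-up false-discovery-rate adjustment, applied separately within
#' each family (one family per clinical covariate), so adding covariates never
#' perturbs the adjusted values of existing ones.
#'
#' @param p numeric p-values.
#' @param family grouping factor of the same length (covariate names).
#' @return adjusted p-values in the input order.
#' @export
bh_adjust <- function(p, family) {
  stopifnot(length(p) == length(family))
  out <- rep(NA_real_, length(p))
  for (f in unique(family)) {
    i <- which(family == f & !is.na(p))
    out[i] <- stats::p.adjust(p[i], method = "BH")
  }
  out
}

#' Contingency tables for cluster-covariate association
#'
#' For every (cluster, cell type, covariate) triple where the cell type occurs
#' in the cluster, counts all pseudobulks of that cell type inside/outside the
#' cluster by covariate status; columns left unassigned by the model count as
#' outside every cluster. Counts are non-redundant: each sample contributes at
#' most one pseudobulk to each cell of a table. Samples with a missing value
#' for a covariate are excluded from that covariate's tables only.
#'
#' @param model a fitted [udon()] model.
#' @param covariates data.frame with a `sample_id` column and one binary
#'   (1/0/NA) column per covariate; an optional stratum column may be present
#'   (named via `run_satay()`'s `confounder`) and is ignored here.
#' @param covariate_cols which columns to treat as covariates (default: all
#'   except `sample_id`).
#' @return data.frame with columns cluster, cell_type, covariate, q, r, s, t.
#' @export
build_contingencies <- function(model, covariates,
                                covariate_cols = setdiff(names(covariates),
                                                         "sample_id")) {
  stopifnot(inherits(model, "udon"), "sample_id" %in% names(covariates))
  meta <- model$meta
  labels <- model$labels[meta$column]   # NA = unassigned, outside any cluster

  unknown <- setdiff(unique(meta$sample_id), covariates$sample_id)
  if (length(unknown))
    stop("sample(s) missing from the covariate table: ",
         paste(unknown, collapse = ", "), call. = FALSE)

  rows <- list()
  for (cov in covariate_cols) {
    val <- stats::setNames(covariates[[cov]], covariates$sample_id)
    use <- !is.na(val[meta$sample_id])
    m <- meta[use, , drop = FALSE]
    l <- labels[use]
    pos <- val[m$sample_id] == 1
    for (ct in unique(m$cell_type)) {
      ict <- m$cell_type == ct
      for (u in sort(unique(l[ict & !is.na(l)]))) {
        inset <- ict & !is.na(l) & l == u
        # dedup: one pseudobulk per sample per table cell
        q <- length(unique(m$sample_id[inset & pos]))
        s <- length(unique(m$sample_id[inset & !pos]))
        r <- length(unique(m$sample_id[ict & !inset & pos]))
        t <- length(unique(m$sample_id[ict & !inset & !pos]))
        rows[[length(rows) + 1L]] <- data.frame(
          cluster = u, cell_type = ct, covariate = cov,
          q = q, r = r, s = s, t = t, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows))
    return(data.frame(cluster = character(), cell_type = character(),
                      covariate = character(), q = integer(), r = integer(),
                      s = integer(), t = integer()))
  do.call(rbind, rows)
}

#' Associate clusters with binary clinical covariates (SATAY)
#'
#' Runs the association stage over every (cluster, cell type, covariate)
#' triple. Without a confounder, a one-sided Fisher exact test is emitted for
#' triples with at least `min_positive` covariate-positive samples in the
#' cluster (the Q gate, default 4). With a `confounder` column named, tables
#' are built per stratum and pooled by the gated one-sided CMH test
#' (per-stratum Q gate of `stratum_gate`, default 2). Raw p-values are
#' BH-adjusted within each covariate family; both significance flags are
#' reported (raw p < `alpha`, adjusted p < `fdr_alpha`, defaults 0.1).
#'
#' @inheritParams build_contingencies
#' @param min_positive Fisher Q gate (default 4).
#' @param alpha raw one-sided p threshold (default 0.1).
#' @param fdr_alpha BH-adjusted threshold (default 0.1).
#' @param confounder optional name of the stratum column in `covariates`.
#' @param stratum_gate per-stratum Q gate for the CMH path (default 2).
#' @param correct CMH continuity correction flag.
#'
#' @return Object of class `"satay"`: a data.frame with cluster, cell_type,
#'   covariate, test, q/r/s/t (pooled), p_value, odds_ratio, fdr_adjusted_p,
#'   significant_raw, significant_fdr and (CMH) n_strata_used.
#' @export
run_satay <- function(model, covariates, min_positive = 4, alpha = 0.1,
                      fdr_alpha = 0.1, confounder = NULL, stratum_gate = 2,
                      correct = FALSE) {
  if (alpha <= 0 || alpha > 1 || fdr_alpha <= 0 || fdr_alpha > 1)
    stop("'alpha' and 'fdr_alpha' must lie in (0, 1]", call. = FALSE)
  cov_cols <- setdiff(names(covariates), c("sample_id", confounder))
  if (!length(cov_cols)) stop("no covariate columns found", call. = FALSE)

  if (is.null(confounder)) {
    tabs <- build_contingencies(model, covariates, cov_cols)
    tabs <- tabs[tabs$q >= min_positive, , drop = FALSE]
    res <- tabs
    if (nrow(tabs)) {
      ft <- mapply(fisher_one_sided, tabs$q, tabs$r, tabs$s, tabs$t,
                   SIMPLIFY = FALSE)
      res$test <- "fisher"
      res$p_value <- vapply(ft, `[[`, numeric(1), "p_value")
      res$odds_ratio <- vapply(ft, `[[`, numeric(1), "odds_ratio")
      res$n_strata_used <- NA_integer_
    }
  } else {
    if (!confounder %in% names(covariates))
      stop("confounder column '", confounder, "' not in the covariate table",
           call. = FALSE)
    strat <- stats::setNames(as.character(covariates[[confounder]]),
                             covariates$sample_id)
    res <- NULL
    for (sl in sort(unique(strat[!is.na(strat)]))) {
      sub <- covariates[!is.na(strat[covariates$sample_id]) &
                          strat[covariates$sample_id] == sl, , drop = FALSE]
      # keep model columns of this stratum only
      tabs <- tryCatch(
        build_contingencies(.restrict_model(model, sub$sample_id), sub,
                            cov_cols),
        error = function(e) NULL)
      if (is.null(tabs) || !nrow(tabs)) next
      tabs$stratum <- sl
      res <- rbind(res, tabs)
    }
    if (is.null(res)) res <- data.frame()
    if (nrow(res)) {
      keyed <- split(res, list(res$cluster, res$cell_type, res$covariate),
                     drop = TRUE)
      res <- do.call(rbind, lapply(keyed, function(d) {
        cm <- cmh_test(d[, c("q", "r", "s", "t")],
                       stratum_gate = stratum_gate, correct = correct)
        data.frame(cluster = d$cluster[1], cell_type = d$cell_type[1],
                   covariate = d$covariate[1],
                   q = sum(d$q), r = sum(d$r), s = sum(d$s), t = sum(d$t),
                   test = "cmh", p_value = cm$p_value,
                   odds_ratio = cm$odds_ratio,
                   n_strata_used = cm$n_strata_used,
                   stringsAsFactors = FALSE)
      }))
      rownames(res) <- NULL
    }
  }

  if (!nrow(res)) {
    res <- data.frame(cluster = character(), cell_type = character(),
                      covariate = character(), q = integer(), r = integer(),
                      s = integer(), t = integer(), test = character(),
                      p_value = numeric(), odds_ratio = numeric(),
                      n_strata_used = integer())
  }
  res$fdr_adjusted_p <- if (nrow(res))
    bh_adjust(res$p_value, res$covariate) else numeric(0)
  res$significant_raw <- !is.na(res$p_value) & res$p_value < alpha
  res$significant_fdr <- !is.na(res$fdr_adjusted_p) &
    res$fdr_adjusted_p < fdr_alpha
  res <- res[order(res$covariate, res$p_value), , drop = FALSE]
  rownames(res) <- NULL
  structure(res, alpha = alpha, fdr_alpha = fdr_alpha,
            confounder = confounder,
            class = c("satay", "data.frame"))
}

#' @rdname run_satay
#' @export
satay <- run_satay

# view of a model restricted to columns of the given samples (used for
# per-stratum contingency building)
.restrict_model <- function(model, sample_ids) {
  keep <- model$meta$sample_id %in% sample_ids
  model$meta <- model$meta[keep, , drop = FALSE]
  model$labels <- model$labels[model$meta$column]
  model
}

#' @export
print.satay <- function(x, ...) {
  cat(sprintf("SATAY associations: %d tested (cluster, cell type, covariate) triples\n",
              nrow(x)))
  cat(sprintf("  %d at raw p < %g; %d at FDR < %g%s\n",
              sum(x$significant_raw), attr(x, "alpha"),
              sum(x$significant_fdr), attr(x, "fdr_alpha"),
              if (!is.null(attr(x, "confounder")))
                paste0(" (CMH, stratified by ", attr(x, "confounder"), ")")
              else " (Fisher)"))
  invisible(x)
}

#' Dot-plot ready export of associations
#'
#' Reshapes a [run_satay()] result into one row per (cluster, covariate) with
#' the best p-value, its odds ratio and the cell types involved — the layout
#' used for association dot plots.
#'
#' @param results a `"satay"` object.
#' @return data.frame with cluster, covariate, min_p, fdr_adjusted_p,
#'   odds_ratio, cell_types, n_tests.
#' @export
satay_dotplot_data <- function(results) {
  stopifnot(inherits(results, "satay"))
  if (!nrow(results))
    return(data.frame(cluster = character(), covariate = character(),
                      min_p = numeric(), fdr_adjusted_p = numeric(),
                      odds_ratio = numeric(), cell_types = character(),
                      n_tests = integer()))
  out <- lapply(split(results, list(results$cluster, results$covariate),
                      drop = TRUE), function(d) {
    i <- which.min(d$p_value)
    data.frame(cluster = d$cluster[1], covariate = d$covariate[1],
               min_p = d$p_value[i], fdr_adjusted_p = d$fdr_adjusted_p[i],
               odds_ratio = d$odds_ratio[i],
               cell_types = paste(sort(unique(d$cell_type)), collapse = ";"),
               n_tests = nrow(d), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$covariate, out$min_p), , drop = FALSE]
}
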