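# Shared fixture builders and independent oracles for the test suite.
# Everything is generated in code under fixed seeds; nothing is read from disk.

`%||%` <- function(a, b) if (is.null(a)) b else a

# a small hand-built cohort: genes x cells with fully controlled values
tiny_cohort <- function() {
  # 2 disease samples, 2 controls, 2 cell types, 3 genes
  expr <- cbind(
    # S1/T1: two cells
    c(1, 2, 3), c(3, 2, 1),
    # S1/T2: one cell
    c(0, 1, 0),
    # S2/T1: two cells
    c(2, 2, 2), c(4, 4, 4),
    # C1/T1: two cells, C1/T2: one
    c(1, 1, 1), c(1, 3, 1), c(0, 0, 2),
    # C2/T1: one cell, C2/T2: two
    c(5, 1, 1), c(2, 0, 0), c(0, 2, 4))
  rownames(expr) <- paste0("g", 1:3)
  colnames(expr) <- paste0("cell", seq_len(ncol(expr)))
  cell_cohort(
    expr,
    cell_sample = c("S1", "S1", "S1", "S2", "S2", "C1", "C1", "C1", "C2",
                    "C2", "C2"),
    cell_type = c("T1", "T1", "T2", "T1", "T1", "T1", "T1", "T2", "T1",
                  "T2", "T2"),
    sample_condition = c(S1 = "disease", S2 = "disease",
                         C1 = "control", C2 = "control"))
}

# small simulated cohort used by most integration tests (light but
# realistic); program gene blocks shrink with the gene count so tiny
# cohorts stay valid
small_sim <- function(seed = 1, n_programs = 5, n_genes = 600,
                      cells = c(30, 60), ...) {
  programs <- if (n_programs > 0)
    default_programs(n_programs, n_genes = n_genes,
                     gene_count = min(40, n_genes %/% (n_programs + 1)))
  else list()
  simulate_cohort(sim_spec(n_genes = n_genes, programs = programs,
                           cells_per_pair = cells, ...), seed = seed)
}

# association-friendly layout: 3 programs x 5 member samples (Q >= 4 feasible)
assoc_sim <- function(seed = 1, n_genes = 600, cells = c(30, 60)) {
  spec <- sim_spec(n_genes = n_genes, cells_per_pair = cells,
                   programs = default_programs(3, samples_per_program = 5,
                                               n_genes = n_genes))
  simulate_cohort(spec, seed = seed)
}

disease_folds <- function(sim, min_cells = 10) {
  pb <- compute_pseudobulks(sim$cohort, min_cells = min_cells,
                            conditions = "disease")
  ref <- aggregate_control_reference(sim$cohort, min_cells = min_cells)
  fold_differentials(pb, ref)
}

fit_small <- function(sim, k_values = c(6, 8, 10), ...) {
  suppressWarnings(udon(disease_folds(sim),
                        udon_params(k_values = k_values, ...)))
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# independent one-sided hypergeometric tail by explicit combinatorial sums
oracle_fisher_p <- function(q, r, s, t) {
  m <- q + r; n <- s + t; k <- q + s
  xs <- q:min(m, k)
  sum(choose(m, xs) * choose(n, k - xs)) / choose(m + n, k)
}

# reference BH step-up with explicit sort/cummin
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  adj <- pmin(1, cummin(m / (m:1) * p[o]))
  adj[order(o)]
}

# textbook CMH statistic and MH odds ratio with explicit per-stratum loops
oracle_cmh <- function(strata, correct = FALSE) {
  num <- 0; var <- 0; orn <- 0; ord <- 0
  for (i in seq_len(nrow(strata))) {
    q <- strata$q[i]; r <- strata$r[i]; s <- strata$s[i]; t <- strata$t[i]
    N <- q + r + s + t
    num <- num + q - (q + r) * (q + s) / N
    v <- (q + r) * (s + t) * (q + s) * (r + t) / (N^2 * (N - 1))
    if (is.finite(v)) var <- var + v
    orn <- orn + q * t / N
    ord <- ord + r * s / N
  }
  cc <- if (correct) 0.5 else 0
  list(statistic = max(abs(num) - cc, 0)^2 / var, or = orn / ord,
       direction = num)
}

# random 2x2 tables with bounded N
random_tables <- function(n, max_n = 40, seed = 1) {
  set.seed(seed)
  data.frame(q = sample(0:10, n, TRUE), r = sample(0:10, n, TRUE),
             s = sample(0:10, n, TRUE), t = sample(0:10, n, TRUE))
}

# write a GMT collection to a temp file
write_gmt_tmp <- function(sets) {
  path <- tempfile(fileext = ".gmt")
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, "na", sets[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  path
}

expect_files_identical <- function(a, b) {
  expect_true(file.exists(a) && file.exists(b))
  expect_identical(readBin(a, "raw", file.size(a)),
                   readBin(b, "raw", file.size(b)))
}
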