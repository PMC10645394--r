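#' Specification of a synthetic single-cell cohort
#'
#' Describes a multi-patient, multi-cell-type cohort with planted disease
#' programs: log-scaled per-cell expression is a per-gene baseline plus a
#' cell-type offset plus (for member samples in member cell types) a planted
#' program shift, plus Gaussian noise. Binary clinical covariates can be tied
#' to program membership (with label-flip noise) or left independent.
#'
#' @param n_disease_samples,n_control_samples cohort arms (defaults 16 / 5).
#' @param n_cell_types number of annotated cell types (default 8).
#' @param cells_per_pair integer range of cells per (sample, cell type) pair
#'   (default `c(30, 200)`).
#' @param n_genes number of genes (default 2000).
#' @param programs list of planted programs, each a list with `genes`
#'   (identifiers), `effect` (mean log-fold shift), `member_samples`,
#'   `member_cell_types`. Use [default_programs()] or pass `n_programs`.
#' @param n_programs convenience: build this many [default_programs()]
#'   (default 5; 0 gives a null cohort).
#' @param covariates list of covariate specs, each
#'   `list(name=, linked_program= index or NA, flip_prob=)`. The default ties
#'   one covariate to each program (5% flips) plus one unlinked null
#'   covariate.
#' @param effect_size,noise_sd planted shift and per-cell Gaussian noise SD
#'   (defaults 1.5 and 0.4).
#' @param base_meanlog,base_sdlog lognormal location/scale of per-gene
#'   baseline expression.
#' @param celltype_sd SD of per-(gene, cell type) offsets.
#' @param flip_prob covariate label noise for the default covariates.
#' @return list of class `"sim_spec"`.
#' @export
sim_spec <- function(n_disease_samples = 16, n_control_samples = 5,
                     n_cell_types = 8, cells_per_pair = c(30, 200),
                     n_genes = 2000, n_programs = 5, programs = NULL,
                     covariates = NULL, effect_size = 1.5, noise_sd = 0.4,
                     base_meanlog = 0, base_sdlog = 0.5, celltype_sd = 0.5,
                     flip_prob = 0.05) {
  if (is.null(programs))
    programs <- default_programs(n_programs, n_disease_samples, n_cell_types,
                                 n_genes, effect_size)
  if (is.null(covariates)) {
    covariates <- lapply(seq_along(programs), function(p)
      list(name = paste0("cov_P", p), linked_program = p,
           flip_prob = flip_prob))
    covariates <- c(covariates, list(list(name = "cov_null",
                                          linked_program = NA,
                                          flip_prob = flip_prob)))
  }
  spec <- list(n_disease_samples = n_disease_samples,
               n_control_samples = n_control_samples,
               n_cell_types = n_cell_types, cells_per_pair = cells_per_pair,
               n_genes = n_genes, programs = programs,
               covariates = covariates, noise_sd = noise_sd,
               base_meanlog = base_meanlog, base_sdlog = base_sdlog,
               celltype_sd = celltype_sd)
  class(spec) <- "sim_spec"
  .validate_sim_spec(spec)
  spec
}

#' Default planted-program layout
#'
#' Programs receive disjoint gene blocks of `gene_count` genes, three member
#' disease samples each (in consecutive blocks), and four member cell types
#' (rotating windows over the available types), so that programs overlap in
#' cell types but not in samples or genes.
#'
#' @param n_programs number of programs.
#' @param n_disease_samples,n_cell_types,n_genes cohort dimensions.
#' @param effect_size mean log-fold shift of program genes.
#' @param gene_count genes per program (default 40).
#' @param samples_per_program member disease samples per program (default 3).
#' @param cell_types_per_program member cell types per program (default 4).
#' @return list of program specs (see [sim_spec()]).
#' @export
default_programs <- function(n_programs, n_disease_samples = 16,
                             n_cell_types = 8, n_genes = 2000,
                             effect_size = 1.5, gene_count = 40,
                             samples_per_program = 3,
                             cell_types_per_program = 4) {
  if (n_programs == 0) return(list())
  if (n_programs * gene_count > n_genes)
    stop("not enough genes for disjoint program blocks", call. = FALSE)
  if (n_programs * samples_per_program > n_disease_samples)
    stop("not enough disease samples for disjoint program membership",
         call. = FALSE)
  lapply(seq_len(n_programs), function(p) {
    gi <- ((p - 1) * gene_count + 1):(p * gene_count)
    si <- ((p - 1) * samples_per_program + 1):(p * samples_per_program)
    ct <- ((2 * (p - 1) + 0:(cell_types_per_program - 1)) %% n_cell_types) + 1
    list(genes = sprintf("G%04d", gi), effect = effect_size,
         member_samples = sprintf("D%02d", si),
         member_cell_types = sprintf("CT%d", sort(unique(ct))))
  })
}

.validate_sim_spec <- function(spec) {
  cts <- sprintf("CT%d", seq_len(spec$n_cell_types))
  dis <- sprintf("D%02d", seq_len(spec$n_disease_samples))
  genes <- sprintf("G%04d", seq_len(spec$n_genes))
  for (i in seq_along(spec$programs)) {
    p <- spec$programs[[i]]
    if (!all(p$member_cell_types %in% cts))
      stop("program ", i, " references unknown cell type(s): ",
           paste(setdiff(p$member_cell_types, cts), collapse = ", "),
           call. = FALSE)
    if (!all(p$member_samples %in% dis))
      stop("program ", i, " references unknown disease sample(s)",
           call. = FALSE)
    if (!all(p$genes %in% genes))
      stop("program ", i, " references unknown gene(s)", call. = FALSE)
  }
  invisible(spec)
}

#' Simulate an annotated cohort with planted programs
#'
#' Generates the cohort described by a [sim_spec()]: a [cell_cohort()] of
#' log-scaled expression, a per-sample binary covariate table, and the ground
#' truth (program membership per (sample, cell type) pair and the intended
#' covariate-program links). Identical seeds give bitwise-identical cohorts.
#'
#' @param spec a [sim_spec()].
#' @param seed integer RNG seed.
#' @return list with elements `cohort`, `covariates` (data.frame,
#'   `sample_id` + one column per covariate; controls are NA), `truth` (list:
#'   `membership` data.frame of planted (sample, cell_type, program) rows,
#'   `covariate_links`, `program_genes`).
#' @export
simulate_cohort <- function(spec = sim_spec(), seed = 1) {
  stopifnot(inherits(spec, "sim_spec"))
  set.seed(seed)
  genes <- sprintf("G%04d", seq_len(spec$n_genes))
  cts <- sprintf("CT%d", seq_len(spec$n_cell_types))
  dis <- sprintf("D%02d", seq_len(spec$n_disease_samples))
  ctl <- sprintf("H%02d", seq_len(spec$n_control_samples))
  samples <- c(dis, ctl)

  base <- stats::rlnorm(spec$n_genes, spec$base_meanlog, spec$base_sdlog)
  ct_off <- matrix(stats::rnorm(spec$n_genes * spec$n_cell_types, 0,
                                spec$celltype_sd),
                   spec$n_genes, spec$n_cell_types,
                   dimnames = list(genes, cts))

  # per-(sample, cell type) cell counts
  pairs <- expand.grid(sample_id = samples, cell_type = cts,
                       stringsAsFactors = FALSE)
  pairs <- pairs[order(pairs$sample_id, pairs$cell_type), , drop = FALSE]
  pairs$n <- sample(spec$cells_per_pair[1]:spec$cells_per_pair[2],
                    nrow(pairs), replace = TRUE)
  total <- sum(pairs$n)

  cell_sample <- rep(pairs$sample_id, pairs$n)
  cell_type <- rep(pairs$cell_type, pairs$n)
  cell_ids <- sprintf("cell%06d", seq_len(total))

  expr <- matrix(stats::rnorm(spec$n_genes * total, 0, spec$noise_sd),
                 spec$n_genes, total, dimnames = list(genes, cell_ids))
  expr <- expr + base
  expr <- expr + ct_off[, match(cell_type, cts), drop = FALSE]
  membership <- NULL
  for (p in seq_along(spec$programs)) {
    pr <- spec$programs[[p]]
    j <- which(cell_sample %in% pr$member_samples &
                 cell_type %in% pr$member_cell_types)
    if (length(j))
      expr[pr$genes, j] <- expr[pr$genes, j] + pr$effect
    membership <- rbind(membership, expand.grid(
      sample_id = pr$member_samples, cell_type = pr$member_cell_types,
      program = p, stringsAsFactors = FALSE))
  }

  cond <- stats::setNames(c(rep("disease", length(dis)),
                            rep("control", length(ctl))), samples)
  cohort <- cell_cohort(expr, cell_sample, cell_type, cond)

  covtab <- data.frame(sample_id = samples, stringsAsFactors = FALSE)
  links <- list()
  for (cv in spec$covariates) {
    val <- rep(NA_integer_, length(samples))
    isd <- samples %in% dis
    if (is.na(cv$linked_program)) {
      val[isd] <- stats::rbinom(sum(isd), 1, 0.5)
    } else {
      memb <- samples %in% spec$programs[[cv$linked_program]]$member_samples
      flip <- stats::rbinom(length(samples), 1, cv$flip_prob) == 1
      val[isd] <- as.integer(xor(memb[isd], flip[isd]))
    }
    covtab[[cv$name]] <- val
    links[[cv$name]] <- cv$linked_program
  }

  truth <- list(
    membership = if (is.null(membership))
      data.frame(sample_id = character(), cell_type = character(),
                 program = integer()) else membership,
    covariate_links = links,
    program_genes = lapply(spec$programs, `[[`, "genes"))

  list(cohort = cohort, covariates = covtab, truth = truth)
}

#' Planted program label per fold column
#'
#' Maps ground-truth program membership onto the columns of a fold matrix (or
#' pseudobulk meta table): each (sample, cell type) column gets its planted
#' program index, or `NA` for background columns.
#'
#' @param meta a fold/pseudobulk `meta` data.frame (column, sample_id,
#'   cell_type).
#' @param truth the `truth` element of [simulate_cohort()].
#' @return integer vector named by column.
#' @export
planted_labels <- function(meta, truth) {
  key <- paste(meta$sample_id, meta$cell_type, sep = "|")
  mkey <- paste(truth$membership$sample_id, truth$membership$cell_type,
                sep = "|")
  stats::setNames(truth$membership$program[match(key, mkey)], meta$column)
}

#' Write the canned fixture cohorts
#'
#' Writes three cohorts in the package's file formats (dense expression TSV,
#' cell annotation TSV, covariate TSV) with a ground-truth JSON sidecar:
#' `null` (no planted programs), `separated` (the default five well-separated
#' programs), and `confounded` (a covariate driven entirely by a two-level
#' stratum that overlaps program 1).
#'
#' @param out_dir writable output directory (created if missing).
#' @param seed integer seed.
#' @param n_genes gene count for the fixtures (default 600, kept small so the
#'   files stay light; programs use [default_programs()] layouts).
#' @return invisibly, the named list of per-fixture directories.
#' @export
make_fixture_suite <- function(out_dir, seed = 1, n_genes = 600) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  gc5 <- min(40, n_genes %/% 6)          # keep program blocks disjoint
  gc3 <- min(40, n_genes %/% 4)
  specs <- list(
    null = sim_spec(n_programs = 0, n_genes = n_genes,
                    cells_per_pair = c(30, 60)),
    separated = sim_spec(n_genes = n_genes, cells_per_pair = c(30, 60),
                         programs = default_programs(
                           5, n_genes = n_genes, gene_count = gc5)),
    # confounded associations need clusters that can pass the Q >= 4 gate
    confounded = sim_spec(n_genes = n_genes, cells_per_pair = c(30, 60),
                          programs = default_programs(
                            3, samples_per_program = 5, n_genes = n_genes,
                            gene_count = gc3)))
  out <- list()
  for (nm in names(specs)) {
    sim <- simulate_cohort(specs[[nm]], seed = seed + match(nm, names(specs)))
    if (nm == "confounded") {
      # stratum = program-1 members plus three bystanders; covariate == stratum
      memb <- specs[[nm]]$programs[[1]]$member_samples
      extra <- setdiff(grep("^D", sim$covariates$sample_id, value = TRUE),
                       memb)[1:2]
      strA <- sim$covariates$sample_id %in% c(memb, extra)
      isd <- grepl("^D", sim$covariates$sample_id)
      sim$covariates$stratum <- ifelse(isd, ifelse(strA, "A", "B"), NA)
      sim$covariates$cov_confounded <- ifelse(isd, as.integer(strA),
                                              NA_integer_)
    }
    d <- file.path(out_dir, nm)
    dir.create(d, showWarnings = FALSE)
    write_cohort(sim$cohort, d)
    utils::write.table(sim$covariates, file.path(d, "covariates.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(sim$truth, file.path(d, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
    out[[nm]] <- d
  }
  invisible(out)
}
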