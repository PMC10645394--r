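---
title: "Discovering patient programs from control-normalized pseudobulk differentials"
author: "udon package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering patient programs from control-normalized pseudobulk differentials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(udon)
```

## The problem

Clinically defined disease subgroups (active/inactive disease, treatment
categories) are often poor proxies for the underlying biology: in
heterogeneous inflammatory diseases, different patients can run entirely
different transcriptional programs in different immune compartments. Given an
annotated single-cell cohort of cases and controls, this package asks the
unsupervised version of the question: *which groups of (patient, cell type)
expression shifts recur across the cohort, and which patients share them?*

Working at the level of single cells confounds cell-type identity with
disease state and lets deeply sampled patients dominate. The package
therefore works with **pseudobulks** — for patient $i$ and cell type $j$, the
mean log-scaled expression vector $P_{ij}$ over that patient's $n_{ij}$ cells
of that type — and, crucially, with their **control-normalized
differentials**

$$F_{ij} = P_{ij} - P_j,$$

where $P_j$ aggregates all control samples for the same cell type (computed
per batch when batch labels are supplied). Subtracting $P_j$ removes
cell-type identity, so that the columns $F_{ij}$ cluster by shared *disease
program* rather than by lineage. Because the inputs are log-scaled, this
difference of means is a log fold change.

### Assumptions on the input

The package validates what it can and documents the rest:

* expression is QC'd, normalized and **log-scaled** (a heuristic warning
  fires when the maximum value looks like a raw count); values must be
  finite;
* every cell carries a sample and a cell-type annotation (annotation is an
  upstream task — no clustering of cells happens here);
* every batch containing disease samples contains at least one control
  (enforced at construction);
* controls are reasonably homogeneous — the aggregate $P_j$ is meaningful
  only then;
* binary clinical covariates are thresholded by the user beforehand; the
  package refuses non-binary covariate columns.

### Aggregating controls

The exact aggregate used for $P_j$ is a genuine design choice. Two modes are
offered:

* `mean_of_sample_pseudobulks` (default): the unweighted mean of the
  per-control-sample pseudobulks. Each control donor counts once, so one
  deeply sequenced control cannot dominate the reference.
* `pooled_cells`: the mean over all pooled control cells, i.e. a
  cell-count-weighted aggregate.

Both coincide for a single control. Cohorts of controls only (population
cohorts without a disease arm) are handled by `control_self_folds()`: each
control is normalized against the collective control average, yielding
per-donor deviation profiles.

### Non-negativity shift

Sparse NMF requires non-negative input. Each gene row of the fold matrix is
shifted by its minimum over **all columns of the run**, $F'_{g\cdot} =
F_{g\cdot} - \min_c F_{gc}$, so row minima are exactly zero and one shared
shift applies to every column. The shift is idempotent and preserved
alongside the raw folds (`gene_min`), so the raw log-fold scale is always
recoverable. Shifting per-run (rather than per-column-subset) means a column
added later would change the shift; projection therefore correlates profiles,
which is insensitive to the per-column effect of a gene-wise shift only
through the centroid — new cohorts are shifted with their own minima and
compared by correlation, which tolerates this.

## Cluster discovery

Discovery has three stages, run by `udon()`:

1. **Guide genes.** Only genes that move are clustered: a gene qualifies
   when its raw fold exceeds the fold threshold (`fold_diff = 2`, i.e.
   $|F| \ge \log_2 2 = 1$ on log2 data) in at least `min_columns = 2`
   columns, and it correlates at $r \ge 0.4$ with at least one other
   qualifying gene (a lone spiky gene is usually an artifact). Selection is
   capped at `max_genes = 5000` by dynamic range. On null data this gate
   typically leaves almost nothing — the fit refuses to continue rather than
   cluster noise, which is the package's first line of defence against
   reporting spurious structure.
2. **Sparse NMF.** The shifted folds restricted to guide genes are
   factorized as $X \approx WH$ with an L1 penalty $\rho = 0.3$ on the
   coefficients $H$ and unit-norm basis columns, by multiplicative updates
   (best of `n_restarts = 10` initializations: one non-negative double-SVD
   start plus seeded random restarts, judged by reconstruction error). Each
   column's provisional cluster is the argmax of its coefficient vector,
   ties to the lowest component index.
3. **Marker validation.** A cluster is only believable if genes
   specifically mark it. `marker_finder()` correlates every gene with each
   cluster's membership indicator template and assigns it to its
   best-matching cluster; a cluster with no unique marker at
   $r \ge 0.2$ (`marker_pearson_cutoff`) is dropped and its columns
   reassigned to the surviving component with the largest coefficient
   (columns with all-zero surviving coefficients stay unassigned). The drop
   loop iterates until every surviving cluster is marker-supported, then
   clusters are renumbered `U01..Un`.

The 1/0 indicator template follows the MarkerFinder convention; a
median-centred variant was considered and not used — with indicator
templates, correlations are invariant to adding a constant to a gene row,
which is the property the validation relies on.

### Choosing the resolution

`k` is swept over `k_values = c(10, 15, 20, 30)` by default. Because marker
validation prunes unsupported components, the *final* cluster count is much
flatter in `k` than `k` itself; the sweep keeps the smallest `k` whose final
count is within `stability_margin = 1` of the next larger `k`'s count (else
the largest tested `k`). The margin is deliberately tight: an
under-resolved run reports roughly `k` merged clusters, which typically
sits 1–2 below the next resolution's count, and a looser margin would
accept that as a plateau and return merged programs. The full per-`k`
report is retained in the fit, and an explicit `k` can be passed to
reproduce a previously chosen model.

## Association testing (SATAY)

Given a fitted model and a table of per-sample binary covariates,
`run_satay()` tests every (cluster, cell type, covariate) triple for
**positive enrichment** of covariate-positive pseudobulks inside the
cluster. Counts are sample-level (each sample contributes at most one
pseudobulk per table cell — relevant when a user concatenates runs); all
pseudobulks of the cell type are scored, with columns the model left
unassigned counting as outside every cluster; and a missing covariate value
removes that sample from that covariate's tables only.

* **Fisher path** (no confounder): one-sided hypergeometric upper tail
  $P(X \ge Q)$; tested only when the in-cluster positive count satisfies
  $Q \ge 4$ (`min_positive`). With fewer than four supporting samples an
  association is considered anecdotal and is not reported at all.
* **CMH path** (confounder given): per-stratum tables pooled by the
  Cochran–Mantel–Haenszel statistic, continuity correction off by default.
  Strata with in-cluster positive count below `stratum_gate = 2` are
  dropped; a design whose strata are all dropped, or whose pooled variance
  is zero (covariate constant within every stratum), is reported as
  *untestable* rather than significant — this is exactly what happens to a
  covariate that is an artifact of the stratification itself. Sidedness:
  the two-sided chi-square p is halved when the pooled association is
  positive, else reported as $1 - p/2$, matching the positive-enrichment
  direction of the Fisher path.
* **Multiplicity**: Benjamini–Hochberg within each covariate family, never
  across covariates, so adding a covariate cannot change existing adjusted
  values. Both flags are reported: raw $p < 0.1$ and adjusted $p < 0.1$.

The Mantel–Haenszel odds ratio $\sum_i Q_iT_i/N_i \,/\, \sum_i R_iS_i/N_i$
reduces to $QT/RS$ for one stratum; $0/0$ is reported as undefined and
$x/0$ as $+\infty$ rather than silently clamped.

## Projection onto new cohorts

`project_labels()` (also available as `predict()` on the fit) assigns new
fold columns to the cluster whose **marker-gene centroid** (mean shifted
fold of the cluster's columns over the model's marker genes) they correlate
with best, requiring $r \ge 0.2$ and at least 20 shared marker genes. A
nearest-centroid-by-correlation rule was chosen over a trained classifier
for transparency: the assignment is a single interpretable number per
cluster. New cohorts must be normalized against **their own controls** —
projecting folds computed against another cohort's controls would mix
cohort effects into every column.

`joint_embed()` fits a 2-D UMAP on a reference fold set and transforms
further cohorts into the same coordinates. The embedding is for
visualization only; no downstream decision consumes it.

## The synthetic cohort generator

`simulate_cohort()` emulates the structure the method assumes, at the log
scale it consumes: per-cell expression = per-gene lognormal baseline
(+ a per-(gene, cell type) offset giving cell types an identity) + a planted
program shift + Gaussian noise, with

* 16 disease and 5 control samples, 8 cell types, 2000 genes,
  30–200 cells per (sample, cell type), noise SD 0.4 — the default cohort
  scale;
* 5 planted programs by default: disjoint 40-gene blocks with a +1.5
  log-fold shift, 3 member disease samples each (sample `D16` stays
  background) and 4 member cell types in rotating windows, so programs
  overlap in cell types but not in samples or genes;
* covariates tied to program membership with 5% label flips, plus one
  independent covariate; controls carry `NA`.

Because each program has 3 member samples, the default cohort's planted
covariates sit *below* the $Q \ge 4$ Fisher gate — deliberately: the default
cohort exercises discovery. Association checks use
`default_programs(3, samples_per_program = 5)`, whose five member samples
survive the gate with 5% flips. The generator simulates at the log scale
directly (no count-level dropout or library-size variation); passing tests
therefore demonstrate the algebra and the statistics, not robustness to
count noise or imperfect normalization, which real data adds on top.
Simulated log values can dip below zero since noise is Gaussian around a
positive baseline; the pipeline only requires finiteness.

## Numerical choices

* NMF runs at most 300 multiplicative iterations per restart and stops when
  the penalized objective changes by less than `tol = 1e-5` (checked every
  10 iterations); non-convergence is a warning and the best iterate is
  kept.
* Basis columns are renormalized to unit Euclidean norm every iteration so
  the L1 penalty on the coefficients has a fixed scale.
* Argmax ties (labels), max-correlation ties (marker assignment) and rank
  ties (equal $r$) break to the lowest component index, the smaller cluster
  id, and lexicographic gene order respectively — all deterministic.
* Constant gene rows have undefined template correlation and are excluded
  from the marker table with a logged count, not an error.
* Degenerate association tables return $p = 1$ (Fisher) or *untestable*
  (CMH), never an error, so screening loops don't die on sparse cells.
* All randomness (NMF restarts, the generator, the embedding) is governed
  by explicit integer seeds; identical configuration and seed reproduce
  every artifact byte-for-byte, through the library and the command line
  alike.

## Problem sizes used in the checks

The test suite and the acceptance script verify recovery on cohorts of the
default scale (2000 genes, ~19k cells) for the headline recovery check, and
on reduced cohorts (600 genes, 30–60 cells per pair, sweep over
$k \in \{6, 8, 10\}$) for the association and projection properties, sizes
at which each property is already fully expressed; the exact test oracles
(hypergeometric enumeration, textbook CMH loops, step-up BH) run on hundreds
of random tables.

## Known limitations

* The guide-gene gate means cohorts with weak or very rare programs (fewer
  than `min_columns` affected columns) are reported as structureless rather
  than tentatively clustered; relax `fold_diff`/`min_columns` deliberately
  if that trade-off is wrong for a given cohort.
* Marker validation can retain noise clusters when many columns are pure
  noise *and* guide genes were selected on true signal elsewhere; the
  unassigned-column mechanism absorbs most of this, but cluster counts on
  very noisy cohorts should be read together with their marker
  correlations.
* The CMH path protects against a single categorical confounder; crossed or
  continuous confounders need a different design (explicitly out of scope).
* Pathway annotation is over-representation against a user-supplied GMT;
  it inherits that collection's coverage and redundancy.

## A minimal run

```{r example, eval = FALSE}
sim <- simulate_cohort(sim_spec(), seed = 1)
pb <- compute_pseudobulks(sim$cohort, min_cells = 10,
                          conditions = "disease")
ref <- aggregate_control_reference(sim$cohort, min_cells = 10)
folds <- fold_differentials(pb, ref)
fit <- udon(folds)
summary(fit)
associations <- run_satay(fit, sim$covariates)
print(associations)
```
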