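Package: udon
Title: Patient Subtype Discovery from Control-Normalized Pseudobulk Differentials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovers shared disease gene-expression programs across patients
    and cell types from annotated single-cell cohorts. Per-sample per-cell-type
    pseudobulks are normalized against aggregate (optionally batch-specific)
    control pseudobulks to form fold differentials, which are clustered by
    sparse non-negative matrix factorization over a resolution sweep; only
    clusters supported by unique marker genes (template-correlation
    MarkerFinder) are reported. The companion SATAY association stage links
    clusters to binary clinical covariates per cell type with one-sided Fisher
    exact tests, confounder-stratified Cochran-Mantel-Haenszel tests, and
    per-covariate Benjamini-Hochberg adjustment. Includes marker-centroid label
    projection onto new cohorts, a joint 2-D embedding, a synthetic-cohort
    generator with planted programs and covariates, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    utils,
    graphics,
    jsonlite,
    uwot
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    mclust,
    cluster,
    withr
Config/testthat/edition: 3
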