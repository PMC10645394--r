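# minimal hand-built model: labels/metadata only, enough for contingencies
toy_model <- function(labels, meta) {
  structure(list(labels = labels, meta = meta,
                 markers = data.frame(), centroids = matrix(0, 0, 0),
                 params = udon_params()), class = "udon")
}

ten_sample_model <- function() {
  samples <- sprintf("S%02d", 1:10)
  meta <- data.frame(column = paste0(samples, "|X"), sample_id = samples,
                     cell_type = "X", condition = "disease",
                     batch = "default", n_cells = 50,
                     stringsAsFactors = FALSE)
  labels <- setNames(c(rep("U01", 4), rep("U02", 6)), meta$column)
  toy_model(labels, meta)
}

test_that("one-sided Fisher matches hand-derived and enumerated values", {
  expect_equal(fisher_one_sided(0, 5, 5, 0)$p_value, 1)
  f <- fisher_one_sided(5, 0, 0, 5)
  expect_equal(f$p_value, 1 / 252, tolerance = 1e-15)
  expect_true(is.infinite(f$odds_ratio))
  expect_true(is.nan(fisher_one_sided(0, 5, 0, 5)$odds_ratio))
  expect_equal(fisher_one_sided(3, 2, 1, 4)$odds_ratio, 6)
  expect_error(fisher_one_sided(-1, 0, 0, 0), "non-negative")

  tabs <- random_tables(200, seed = 42)
  for (i in seq_len(nrow(tabs))) {
    expect_equal(
      fisher_one_sided(tabs$q[i], tabs$r[i], tabs$s[i], tabs$t[i])$p_value,
      oracle_fisher_p(tabs$q[i], tabs$r[i], tabs$s[i], tabs$t[i]),
      tolerance = 1e-12)
  }
})

test_that("Fisher p is invariant to transposing the 2x2 table", {
  tabs <- random_tables(50, seed = 7)
  for (i in seq_len(nrow(tabs))) {
    expect_equal(
      fisher_one_sided(tabs$q[i], tabs$r[i], tabs$s[i], tabs$t[i])$p_value,
      fisher_one_sided(tabs$q[i], tabs$s[i], tabs$r[i], tabs$t[i])$p_value,
      tolerance = 1e-12)
  }
})

test_that("CMH reduces to QT/RS on a single stratum and is null on balanced tables", {
  one <- cmh_test(data.frame(q = 5, r = 2, s = 3, t = 4), stratum_gate = 2)
  expect_equal(one$odds_ratio, (5 * 4) / (2 * 3))
  null2 <- cmh_test(data.frame(q = c(2, 2), r = c(2, 2), s = c(2, 2),
                               t = c(2, 2)), stratum_gate = 2)
  expect_equal(null2$odds_ratio, 1)
  expect_gte(null2$p_value, 0.5)
})

test_that("CMH matches an explicit-loop textbook oracle and mantelhaen.test", {
  set.seed(11)
  for (rep in 1:50) {
    ns <- sample(2:4, 1)
    st <- data.frame(q = sample(2:8, ns, TRUE), r = sample(0:8, ns, TRUE),
                     s = sample(0:8, ns, TRUE), t = sample(1:8, ns, TRUE))
    got <- cmh_test(st, stratum_gate = 0)
    ora <- oracle_cmh(st)
    expect_equal(got$statistic, ora$statistic, tolerance = 1e-12)
    expect_equal(got$odds_ratio, ora$or, tolerance = 1e-12)
    # two-sided chi-square agrees with stats::mantelhaen.test
    arr <- array(0, c(2, 2, ns))
    for (i in seq_len(ns))
      arr[, , i] <- matrix(c(st$q[i], st$s[i], st$r[i], st$t[i]), 2)
    mh <- suppressWarnings(stats::mantelhaen.test(arr, correct = FALSE))
    p2 <- if (ora$direction > 0) 2 * got$p_value else 2 * (1 - got$p_value)
    expect_equal(p2, mh$p.value, tolerance = 1e-8)
    expect_equal(got$odds_ratio, unname(mh$estimate), tolerance = 1e-8)
  }
})

test_that("CMH drops gated strata and flags fully gated designs untestable", {
  st <- data.frame(q = c(5, 1), r = c(1, 5), s = c(2, 2), t = c(4, 4))
  got <- cmh_test(st, stratum_gate = 2)
  expect_equal(got$n_strata_used, 1L)
  expect_equal(got$odds_ratio, (5 * 4) / (1 * 2))
  none <- cmh_test(data.frame(q = 1, r = 5, s = 5, t = 5), stratum_gate = 2)
  expect_false(none$testable)
  expect_true(is.na(none$p_value))
})

test_that("replicating a consistent effect across strata gains power over one table", {
  tabs <- data.frame(q = c(5, 6, 4), r = c(2, 1, 3), s = c(2, 3, 1),
                     t = c(6, 5, 7))
  for (i in seq_len(nrow(tabs))) {
    single <- fisher_one_sided(tabs$q[i], tabs$r[i], tabs$s[i], tabs$t[i])
    rep3 <- cmh_test(tabs[rep(i, 3), ], stratum_gate = 2)
    expect_lte(rep3$p_value, single$p_value + 1e-12)
  }
})

test_that("the continuity correction matches mantelhaen.test when enabled", {
  st <- data.frame(q = c(6, 5), r = c(2, 3), s = c(3, 2), t = c(5, 6))
  got <- cmh_test(st, stratum_gate = 0, correct = TRUE)
  arr <- array(0, c(2, 2, 2))
  for (i in 1:2) arr[, , i] <- matrix(c(st$q[i], st$s[i], st$r[i], st$t[i]), 2)
  mh <- stats::mantelhaen.test(arr, correct = TRUE)
  expect_equal(2 * got$p_value, mh$p.value, tolerance = 1e-10)
})

test_that("BH adjustment matches the step-up oracle and respects families", {
  expect_equal(bh_adjust(0.03, "a"), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04), rep("a", 4)),
               rep(0.04, 4))
  set.seed(12)
  p <- runif(1000)
  fam <- sample(letters[1:4], 1000, TRUE)
  got <- bh_adjust(p, fam)
  for (f in letters[1:4]) {
    i <- fam == f
    expect_equal(got[i], oracle_bh(p[i]), tolerance = 1e-12)
  }
  # family separation: adding a covariate never changes existing families
  p2 <- c(p, runif(100)); fam2 <- c(fam, rep("e", 100))
  expect_equal(bh_adjust(p2, fam2)[seq_along(p)], got)
  expect_equal(bh_adjust(numeric(0), character(0)), numeric(0))
})

test_that("contingency tables count deduplicated sample-level membership", {
  m <- ten_sample_model()
  cov <- data.frame(sample_id = sprintf("S%02d", 1:10),
                    flag = c(rep(1, 4), rep(0, 6)))
  tab <- build_contingencies(m, cov)
  u1 <- tab[tab$cluster == "U01", ]
  expect_equal(unlist(u1[, c("q", "r", "s", "t")], use.names = FALSE),
               c(4L, 0L, 0L, 6L))

  # a sample with two pseudobulks of one cell type in one cluster counts once
  m2 <- m
  extra <- data.frame(column = "S01|X-bis", sample_id = "S01",
                      cell_type = "X", condition = "disease",
                      batch = "default", n_cells = 50)
  m2$meta <- rbind(m2$meta, extra)
  m2$labels <- c(m2$labels, setNames("U01", "S01|X-bis"))
  tab2 <- build_contingencies(m2, cov)
  expect_equal(tab2$q[tab2$cluster == "U01"], 4L)

  # missing covariate values drop the sample from that covariate only
  cov$flag[10] <- NA
  cov$other <- 1
  tab3 <- build_contingencies(m, cov)
  expect_equal(sum(tab3[tab3$cluster == "U01" & tab3$covariate == "flag",
                        c("q", "r", "s", "t")]), 9)
  expect_equal(sum(tab3[tab3$cluster == "U01" & tab3$covariate == "other",
                        c("q", "r", "s", "t")]), 10)
  expect_error(build_contingencies(
    m, data.frame(sample_id = "S01", flag = 1)), "missing from")
})

test_that("contingency tables equal a brute-force tally over random designs", {
  set.seed(13)
  samples <- sprintf("S%02d", 1:12)
  meta <- expand.grid(sample_id = samples, cell_type = c("X", "Y"),
                      stringsAsFactors = FALSE)
  meta$column <- paste(meta$sample_id, meta$cell_type, sep = "|")
  meta$condition <- "disease"; meta$batch <- "default"; meta$n_cells <- 30
  labels <- setNames(sample(c("U01", "U02", "U03"), nrow(meta), TRUE),
                     meta$column)
  cov <- data.frame(sample_id = samples, v = sample(c(0, 1), 12, TRUE))
  tab <- build_contingencies(toy_model(labels, meta), cov)
  val <- setNames(cov$v, cov$sample_id)
  for (i in seq_len(nrow(tab))) {
    q <- r <- s <- t <- character(0)
    for (j in seq_len(nrow(meta))) {
      if (meta$cell_type[j] != tab$cell_type[i]) next
      inside <- labels[meta$column[j]] == tab$cluster[i]
      pos <- val[meta$sample_id[j]] == 1
      if (inside && pos) q <- union(q, meta$sample_id[j])
      if (!inside && pos) r <- union(r, meta$sample_id[j])
      if (inside && !pos) s <- union(s, meta$sample_id[j])
      if (!inside && !pos) t <- union(t, meta$sample_id[j])
    }
    expect_equal(unlist(tab[i, c("q", "r", "s", "t")], use.names = FALSE),
                 lengths(list(q, r, s, t)))
  }
})

test_that("run_satay applies the Q gate and flags perfect separation", {
  m <- ten_sample_model()
  cov <- data.frame(sample_id = sprintf("S%02d", 1:10),
                    hit = c(rep(1, 4), rep(0, 6)),
                    thin = c(rep(1, 3), rep(0, 7)))
  res <- run_satay(m, cov)
  hit <- res[res$covariate == "hit" & res$cluster == "U01", ]
  expect_equal(nrow(hit), 1)
  expect_equal(hit$p_value, 1 / choose(10, 4), tolerance = 1e-12)
  expect_true(hit$significant_raw)
  # only 3 positives in the cluster: gated out
  expect_false(any(res$covariate == "thin" & res$cluster == "U01"))
  expect_error(run_satay(m, cov, alpha = 1.5), "alpha")
})

test_that("stratified run_satay pools per-stratum tables with the CMH", {
  samples <- sprintf("S%02d", 1:16)
  meta <- data.frame(column = paste0(samples, "|X"), sample_id = samples,
                     cell_type = "X", condition = "disease",
                     batch = "default", n_cells = 40,
                     stringsAsFactors = FALSE)
  labels <- setNames(rep(c("U01", "U02"), each = 8), meta$column)
  m <- toy_model(labels, meta)
  # two identical strata, each with table (q, r, s, t) = (2, 1, 2, 3) for U01
  cov <- data.frame(
    sample_id = samples,
    v = c(1, 1, 0, 0, 1, 1, 0, 0, 1, 0, 0, 0, 1, 0, 0, 0),
    stratum = c(rep("a", 4), rep("b", 4), rep("a", 4), rep("b", 4)))
  res <- run_satay(m, cov, confounder = "stratum", stratum_gate = 2)
  u1 <- res[res$cluster == "U01", ]
  expect_equal(u1$test, "cmh")
  expect_equal(u1$n_strata_used, 2L)
  expect_equal(u1$q, 4L)
  ora <- oracle_cmh(data.frame(q = c(2, 2), r = c(1, 1), s = c(2, 2),
                               t = c(3, 3)))
  expect_equal(u1$odds_ratio, ora$or, tolerance = 1e-12)
  one_sided <- pchisq(ora$statistic, 1, lower.tail = FALSE) / 2
  expect_equal(u1$p_value, one_sided, tolerance = 1e-12)
})

test_that("a stratum-driven covariate is flagged by Fisher but cleared by the CMH", {
  sim <- assoc_sim(seed = 31)
  m <- fit_small(sim)
  memb <- sprintf("D%02d", 1:5)                 # program 1 members
  extra <- sprintf("D%02d", 6:7)
  cv <- sim$covariates["sample_id"]
  isd <- grepl("^D", cv$sample_id)
  strA <- cv$sample_id %in% c(memb, extra)
  cv$conf <- ifelse(isd, as.integer(strA), NA_integer_)
  cv$stratum <- ifelse(isd, ifelse(strA, "A", "B"), NA)
  fis <- run_satay(m, cv[, c("sample_id", "conf")])
  expect_true(any(fis$significant_raw))
  cmh <- run_satay(m, cv, confounder = "stratum")
  expect_false(any(cmh$significant_raw, na.rm = TRUE))
})
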