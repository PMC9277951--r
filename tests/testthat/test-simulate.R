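test_that("planted means satisfy the pattern geometry exactly", {
  cfg <- sim_config(n_genes = 2000, seed = 11)
  sim <- simulate_trio_counts(cfg)
  tr <- sim$truth
  expect_setequal(tr$gene_id, rownames(sim$counts$counts))
  expect_equal(anyDuplicated(tr$gene_id), 0L)

  is_pat <- function(p) tr$true_pattern %in% p
  # overdominant: hybrid strictly outside the parental range
  up <- is_pat(paste0("P", 10:12))
  expect_true(all(tr$mu_hybrid[up] > pmax(tr$mu_female, tr$mu_male)[up]))
  dn <- is_pat(paste0("P", 7:9))
  expect_true(all(tr$mu_hybrid[dn] < pmin(tr$mu_female, tr$mu_male)[dn]))
  # additive: hybrid exactly at the mid-parent, parents distinct
  ad <- is_pat(c("P1", "P2"))
  expect_equal(tr$mu_hybrid[ad], (tr$mu_female[ad] + tr$mu_male[ad]) / 2)
  expect_true(all(tr$mu_female[ad] != tr$mu_male[ad]))
  # dominant: hybrid equals exactly one parent
  dom <- is_pat(paste0("P", 3:6))
  eqf <- tr$mu_hybrid[dom] == tr$mu_female[dom]
  eqm <- tr$mu_hybrid[dom] == tr$mu_male[dom]
  expect_true(all(xor(eqf, eqm)))
  # null: all three equal
  nu <- tr$true_pattern == "null"
  expect_true(all(tr$mu_female[nu] == tr$mu_male[nu] &
                    tr$mu_male[nu] == tr$mu_hybrid[nu]))
})

test_that("trio counts are seeded-deterministic and near-Poisson at tiny dispersion", {
  cfg <- sim_config(n_genes = 500, dispersion = 1e-8,
                    base_mean_log_range = c(log(1000), log(1000)),
                    pattern_proportions = c(null = 1), seed = 5)
  a <- simulate_trio_counts(cfg)
  b <- simulate_trio_counts(cfg)
  expect_identical(a$counts$counts, b$counts$counts)
  expect_identical(a$truth, b$truth)

  # Poisson limit: sample mean of mu = 1000 within 5 * sqrt(1000/3) of 1000
  fm <- rowMeans(a$counts$counts[, 1:3])
  expect_gt(mean(abs(fm - 1000) <= 5 * sqrt(1000 / 3)), 0.99)
})

test_that("replicate variance reflects NB overdispersion at scale", {
  sim <- null_trio(5000, dispersion = 0.1, seed = 2)
  cm <- sim$counts$counts[, 1:3]
  v <- apply(cm, 1, var)
  m <- rowMeans(cm)
  expect_gt(mean(v - m), 0)  # variance exceeds mean on average
})

test_that("simulator rejects invalid configurations", {
  expect_error(sim_config(n_reps = 1), "n_reps")
  expect_error(sim_config(dispersion = 0), "dispersion")
  expect_error(sim_config(pattern_proportions = c(null = 0.5)), "sum to 1")
  expect_error(sim_config(pattern_proportions = c(bogus = 1)), "named")
})

test_that("phenotype generator plants exact MPH and errors on unknown parents", {
  ph <- simulate_phenotype(c("A", "B", "AxB"), timepoints = c(50, 70),
                           target_mph = c(AxB = 9.93), noise_sd = 0, seed = 3)
  mph <- heterosis_table(ph)
  expect_equal(mph$mph_percent, rep(9.93, 2), tolerance = 1e-9)

  ph0 <- simulate_phenotype(c("A", "B", "AxB"), 70, target_mph = c(AxB = 0),
                            noise_sd = 0, seed = 3)
  expect_equal(heterosis_table(ph0)$mph_percent, 0, tolerance = 1e-12)

  expect_error(simulate_phenotype(c("A", "AxB"), 70, noise_sd = 0),
               "unknown parent")
})

test_that("noisy phenotype MPH is unbiased over many seeds", {
  target <- 8.4
  est <- vapply(1:300, function(s) {
    ph <- simulate_phenotype(c("A", "B", "AxB"), 70,
                             target_mph = c(AxB = target),
                             noise_sd = 0.1, seed = s)
    heterosis_table(ph)$mph_percent
  }, numeric(1))
  se <- sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - target), 3 * se + 1e-12)
})

test_that("GO annotation simulator plants enrichment only when asked", {
  genes <- sprintf("g%03d", 1:100)
  tgt <- genes[1:10]
  ann <- simulate_go_annotation(genes, n_terms = 50,
                                enriched_term_fraction = 0.1,
                                target_set = tgt, seed = 9)
  expect_length(ann$enriched_terms, 5)
  expect_true(all(table(ann$annotation$term_id) >= 1))
  # enriched terms over-cover the target set
  enr_ann <- ann$annotation[ann$annotation$term_id %in% ann$enriched_terms, ]
  cov_in <- mean(tgt %in% enr_ann$gene_id)
  expect_gt(cov_in, 0.5)
  # determinism
  ann2 <- simulate_go_annotation(genes, 50, 0.1, tgt, seed = 9)
  expect_identical(ann$annotation, ann2$annotation)
  expect_error(simulate_go_annotation(genes, 0, 0), "n_terms")
  expect_error(simulate_go_annotation(genes, 5, 0, target_set = "nope"),
               "subset")
})

test_that("null annotation gives uniform enrichment p-values over seeds", {
  genes <- sprintf("g%03d", 1:80)
  tgt <- genes[1:10]
  pvals <- unlist(lapply(1:150, function(s) {
    ann <- simulate_go_annotation(genes, n_terms = 6,
                                  enriched_term_fraction = 0,
                                  target_set = tgt, seed = s,
                                  base_prob = 0.3)
    enrich(tgt, ann$annotation, genes)$p
  }))
  # discrete p-values are stochastically >= uniform; check no excess of
  # small values (the over-representation direction)
  expect_lt(mean(pvals <= 0.05), 0.07)
  expect_gt(mean(pvals <= 0.5), 0.35)
})

test_that("homology and Ct simulators are deterministic and well-formed", {
  hom <- simulate_homology_hits(c(Q1 = "KAT/AKT", Q2 = "NHX"), seed = 4)
  expect_identical(hom$hits,
                   simulate_homology_hits(c(Q1 = "KAT/AKT", Q2 = "NHX"),
                                          seed = 4)$hits)
  expect_true(all(hom$hits$q_end <= hom$q_len[hom$hits$query_id]))
  expect_true(all(hom$hits$q_start >= 1))

  ct <- simulate_ct_table(c(geneA = 2, geneB = -1), noise_sd = 0, seed = 1)
  r <- ddct_table(ct)
  expect_equal(r$log2_ratio[match(c("geneA", "geneB"), r$gene_id)], c(2, -1),
               tolerance = 1e-12)
})
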