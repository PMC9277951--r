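calls3 <- c("up", "down", "ns")

test_that("forced single-combination assignments follow the rule table", {
  expect_equal(classify_gene("up", "up", "up", "ns")$pattern, "P11")
  expect_equal(classify_gene("up", "up", "up", "ns")$category, "overdominant_up")
  expect_equal(classify_gene("down", "down", "down", "up")$pattern, "P7")
  expect_equal(classify_gene("ns", "ns", "ns", "up")$pattern, "unclassified")
  expect_equal(classify_gene("down", "up", "ns", "down")$pattern, "P1")
  expect_equal(classify_gene("up", "down", "ns", "up")$pattern, "P2")
  expect_equal(classify_gene("ns", "up", "up", "up")$pattern, "P3")
  expect_equal(classify_gene("up", "ns", "up", "down")$pattern, "P5")
  # additive-shaped but off the mid-parent -> conflicting
  expect_equal(classify_gene("down", "up", "up", "down")$pattern, "conflicting")
  expect_error(classify_gene("sideways", "ns", "ns", "ns"), "invalid call")
})

test_that("classification partitions all 81 call combinations like the brute-force table", {
  grid <- expand.grid(p1 = calls3, p2 = calls3, mp = calls3, pp = calls3,
                      stringsAsFactors = FALSE)
  got <- classify_gene(grid$p1, grid$p2, grid$mp, grid$pp)
  want <- mapply(brute_pattern, grid$p1, grid$p2, grid$mp, grid$pp)
  expect_equal(got$pattern, unname(want))
  # total and single-valued: every combination got exactly one valid label
  expect_true(all(got$pattern %in%
                    c(paste0("P", 1:12), "unclassified", "conflicting")))
  # category is consistent with the pattern everywhere
  expect_equal(got$category, pattern_category(got$pattern))
})

test_that("grouped summaries re-derive from pattern counts", {
  pats <- c(rep("P10", 632), rep("P11", 617), rep("P12", 1498),
            rep("P7", 317), rep("P8", 1350), rep("P9", 429))
  s <- summarize_patterns(data.frame(pattern = pats))
  expect_equal(unname(s$grouped["overdominant_up"] +
                        s$grouped["overdominant_down"]), 4843L)
  expect_equal(sum(s$counts), length(pats))
  expect_equal(sum(s$grouped), sum(s$counts))
  expect_equal(s$overdominant_fraction_of_nonadditive, 1)  # no dominant here

  mix <- data.frame(pattern = c(rep("P3", 50), rep("P10", 50)))
  expect_equal(summarize_patterns(mix)$overdominant_fraction_of_nonadditive, 0.5)

  onlyadd <- data.frame(pattern = rep("P1", 10))
  expect_true(is.na(summarize_patterns(onlyadd)$overdominant_fraction_of_nonadditive))
  empty <- summarize_patterns(data.frame(pattern = character()))
  expect_equal(sum(empty$counts), 0L)
  expect_true(is.na(empty$overdominant_fraction_of_nonadditive))
})

test_that("noiseless planted means give an exactly diagonal confusion matrix", {
  # dispersion -> 0 limit: replicates equal the rounded planted means;
  # 40% nulls anchor the median-of-ratios reference
  pp <- c(stats::setNames(rep(0.05, 12), paste0("P", 1:12)), null = 0.4)
  cfg <- sim_config(n_genes = 1000, dispersion = 1e-6,
                    base_mean_log_range = c(log(5000), log(20000)),
                    effect_log2fc = 3, pattern_proportions = pp, seed = 51)
  sim <- simulate_trio_counts(cfg)
  mus <- as.matrix(sim$truth[, c("mu_female", "mu_male", "mu_hybrid")])
  m <- round(mus[, c(1, 1, 1, 2, 2, 2, 3, 3, 3)])
  dimnames(m) <- list(sim$truth$gene_id, colnames(sim$counts$counts))
  storage.mode(m) <- "integer"
  ctr <- run_trio_contrasts(count_matrix(m), sim$design)
  rec <- recover_proportions(sim$truth, classify_trio(ctr))
  expect_true(all(rec$per_pattern$recall == 1))
  expect_true(all(rec$per_pattern$precision == 1))
})

test_that("strengthening thresholds never flips overdominant direction", {
  sim <- simulate_trio_counts(sim_config(n_genes = 1500, seed = 61))
  ctr <- run_trio_contrasts(sim$counts, sim$design)
  loose <- classify_trio(ctr, p_max = 0.05, lfc_min = 0)
  strict <- classify_trio(ctr, p_max = 0.01, lfc_min = 0.5)
  lc <- pattern_category(loose$pattern)
  sc <- pattern_category(strict$pattern)
  expect_false(any(lc == "overdominant_up" & sc == "overdominant_down"))
  expect_false(any(lc == "overdominant_down" & sc == "overdominant_up"))
})

test_that("all-null simulations leak only weakly into the pattern classes", {
  sim <- null_trio(2000, seed = 71)
  ctr <- run_trio_contrasts(sim$counts, sim$design)
  # raw p, no fc filter: roughly the two-test false-positive rate classifies
  raw <- classify_trio(ctr, lfc_min = 0, use_adjusted = FALSE)
  frac_raw <- mean(raw$pattern %in% paste0("P", 1:12))
  expect_lt(frac_raw, 0.12)
  expect_gt(frac_raw, 0.005)
  # fold-change filter at 1 cuts the leakage hard
  strict <- classify_trio(ctr, lfc_min = 1, use_adjusted = FALSE)
  expect_lt(mean(strict$pattern %in% paste0("P", 1:12)), frac_raw / 2)
})

test_that("recover_proportions validates the gene universe", {
  sim <- simulate_trio_counts(sim_config(n_genes = 100, seed = 81))
  ctr <- run_trio_contrasts(sim$counts, sim$design)
  a <- classify_trio(ctr)
  expect_error(recover_proportions(sim$truth[-1, ], a), "gene sets")
})
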