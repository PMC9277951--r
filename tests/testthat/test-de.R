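test_that("median-of-ratios size factors match hand computation", {
  # identical samples -> unit factors
  m <- matrix(rep(c(10L, 50L, 200L), 2), ncol = 2,
              dimnames = list(paste0("g", 1:3), c("a", "b")))
  expect_equal(normalize_counts(count_matrix(m))$size_factors,
               c(a = 1, b = 1))

  # doubling one sample doubles its factor relative to the other
  m2 <- m; m2[, 2] <- 2L * m2[, 2]
  sf <- normalize_counts(count_matrix(m2))$size_factors
  expect_equal(unname(sf[2] / sf[1]), 2)
  expect_equal(exp(mean(log(sf))), 1)  # geometric mean 1

  # hand-computed median of ratios on an asymmetric toy matrix
  m3 <- matrix(c(100L, 200L, 10L, 20L, 1000L, 4000L), nrow = 3, byrow = TRUE,
               dimnames = list(paste0("g", 1:3), c("a", "b")))
  ref <- exp(rowMeans(log(m3)))
  raw <- apply(m3 / ref, 2, median)
  expected <- raw / exp(mean(log(raw)))
  expect_equal(normalize_counts(count_matrix(m3))$size_factors, expected)

  # all-zero sample is named in the error
  m4 <- m; m4[, 2] <- 0L
  expect_error(normalize_counts(count_matrix(m4)), "b")
})

test_that("normalization is idempotent on an already-balanced matrix", {
  sim <- null_trio(300, seed = 8)
  x1 <- normalize_counts(sim$counts)
  # renormalizing the normalized (rounded) values gives factors ~ 1
  renorm <- normalize_counts(count_matrix(round(normalized_counts(x1))))
  expect_equal(unname(renorm$size_factors), rep(1, 9), tolerance = 0.05)
  # and exact idempotence when the matrix is already on a common scale
  even <- normalize_counts(count_matrix(sim$counts$counts))
  again <- normalize_counts(count_matrix(sim$counts$counts))
  expect_equal(even$size_factors, again$size_factors, tolerance = 1e-9)
})

test_that("size-factor distortions are recovered by normalization", {
  sf_true <- c(rep(0.5, 3), rep(1, 3), rep(2, 3))
  cfg <- sim_config(n_genes = 2000, size_factors = sf_true, seed = 12)
  sim <- simulate_trio_counts(cfg)
  sf_est <- normalize_counts(sim$counts)$size_factors
  sf_expect <- sf_true / exp(mean(log(sf_true)))
  expect_equal(unname(sf_est), sf_expect, tolerance = 0.05)
})

test_that("virtual mid-parent samples average paired parent replicates", {
  m <- matrix(c(100L, 200L, 100L, 200L, 100L, 200L,   # female reps of g1,g2
                10L, 20L, 30L, 30L, 20L, 10L), byrow = TRUE, nrow = 2)
  # build a 2-gene matrix: g1 rows female (100) male (200); use explicit layout
  counts <- matrix(c(100L, 100L, 100L, 200L, 200L, 200L, 150L, 150L, 150L,
                     10L, 20L, 30L, 30L, 20L, 10L, 20L, 20L, 20L),
                   byrow = TRUE, nrow = 2,
                   dimnames = list(c("g1", "g2"),
                                   c("F1s", "F2s", "F3s", "M1s", "M2s", "M3s",
                                     "H1s", "H2s", "H3s")))
  des <- trio_design("X", list(female = c("F1s", "F2s", "F3s"),
                               male = c("M1s", "M2s", "M3s"),
                               hybrid = c("H1s", "H2s", "H3s")))
  x <- count_matrix(counts, size_factors = rep(1, 9))
  mp <- build_mid_parent(x, des)
  expect_equal(mp$mp_samples, paste0("MP_rep", 1:3))
  expect_equal(unname(mp$counts$counts["g1", mp$mp_samples]), rep(150L, 3))
  expect_equal(unname(mp$counts$counts["g2", mp$mp_samples]), rep(20L, 3))

  # identical parents -> MP equals the parents
  counts2 <- counts; counts2[, 4:6] <- counts2[, 1:3]
  mp2 <- build_mid_parent(count_matrix(counts2, size_factors = rep(1, 9)), des)
  expect_equal(mp2$counts$counts[, mp2$mp_samples],
               counts2[, 1:3, drop = FALSE],
               ignore_attr = TRUE)

  expect_error(build_mid_parent(count_matrix(counts), des), "normalize")
})

test_that("NB Wald test is antisymmetric and null on identical groups", {
  sim <- null_trio(400, seed = 21)
  x <- normalize_counts(sim$counts)
  g1 <- sim$design$samples$female
  g2 <- sim$design$samples$male
  r12 <- nb_test(x, g1, g2)
  r21 <- nb_test(x, g2, g1)
  expect_equal(r12$log2fc, -r21$log2fc, tolerance = 1e-12)
  expect_equal(r12$p, r21$p, tolerance = 1e-12)

  # same samples on both sides: exactly zero lfc, nothing called
  dup <- x$counts
  colnames(dup) <- paste0(colnames(dup), "_b")
  both <- count_matrix(cbind(x$counts, dup),
                       size_factors = c(x$size_factors,
                                        stats::setNames(x$size_factors,
                                                        colnames(dup))))
  ri <- call_degs(nb_test(both, colnames(x$counts), colnames(dup)))
  expect_equal(ri$log2fc, rep(0, nrow(ri)))
  expect_true(all(ri$call == "ns"))
})

test_that("low-count genes are excluded from testing but kept in output", {
  m <- rbind(g_low = c(1L, 0L, 2L, 0L, 1L, 0L),
             g_hi = c(500L, 520L, 480L, 510L, 490L, 505L))
  colnames(m) <- paste0("s", 1:6)
  x <- count_matrix(m, size_factors = rep(1, 6))
  r <- nb_test(x, paste0("s", 1:3), paste0("s", 4:6))
  expect_equal(nrow(r), 2)
  expect_true(is.na(r$p[r$gene_id == "g_low"]))
  expect_false(is.na(r$p[r$gene_id == "g_hi"]))
  expect_equal(call_degs(r)$call[r$gene_id == "g_low"], "ns")
})

test_that("DEG calls respect both thresholds", {
  r <- data.frame(gene_id = paste0("g", 1:3), contrast = "A_vs_B",
                  base_meanA = 1, base_meanB = 1,
                  log2fc = c(1.5, 0.5, 3), se = 1,
                  p = c(0.01, 0.01, 0.2), padj = c(0.03, 0.03, 0.6),
                  call = "ns")
  expect_equal(call_degs(r)$call, c("up", "ns", "ns"))
  expect_equal(call_degs(r, lfc_min = 0.4)$call, c("up", "up", "ns"))
  expect_equal(call_degs(r, use_adjusted = TRUE)$call, c("up", "ns", "ns"))
  expect_error(call_degs(r, p_max = 0), "p_max")
})

test_that("planted two-fold-squared effects are detected with high power", {
  # planted |log2fc| = 2 at mu = 500, dispersion 0.05, n = 3
  hits <- 0; tot <- 0
  for (s in 1:10) {
    set.seed(1000 + s)
    ng <- 300; neff <- 60
    mu <- rep(500, ng); muA <- mu; muA[seq_len(neff)] <- 2000
    m <- cbind(matrix(rnbinom(ng * 3, mu = rep(muA, 3), size = 20), ncol = 3),
               matrix(rnbinom(ng * 3, mu = rep(mu, 3), size = 20), ncol = 3))
    dimnames(m) <- list(sprintf("g%03d", 1:ng), paste0("s", 1:6))
    x <- normalize_counts(count_matrix(m))
    r <- call_degs(nb_test(x, paste0("s", 1:3), paste0("s", 4:6)))
    hits <- hits + sum(r$call[seq_len(neff)] != "ns")
    tot <- tot + neff
  }
  expect_gte(hits / tot, 0.9)
})

test_that("trio contrasts run end to end with sensible direction", {
  cfg <- sim_config(n_genes = 800,
                    pattern_proportions = c(P11 = 0.2, null = 0.8), seed = 31)
  sim <- simulate_trio_counts(cfg)
  ctr <- run_trio_contrasts(sim$counts, sim$design)
  expect_named(ctr, c("H_vs_P1", "H_vs_P2", "H_vs_MP", "P1_vs_P2"))
  p11 <- sim$truth$true_pattern == "P11"
  # hybrid is planted above both parents: H_vs_P1 lfc positive
  expect_gt(mean(ctr$H_vs_P1$log2fc[p11] > 1), 0.95)
  expect_gt(mean(ctr$H_vs_MP$log2fc[p11] > 1), 0.95)
  # parents equal for P11
  expect_lt(mean(ctr$P1_vs_P2$call[p11] != "ns"), 0.12)
})

test_that("DE results round-trip through TSV", {
  sim <- null_trio(50, seed = 41)
  x <- normalize_counts(sim$counts)
  r <- nb_test(x, sim$design$samples$female, sim$design$samples$male)
  tf <- tempfile(fileext = ".tsv")
  write_de_tsv(r, tf)
  back <- read_de_tsv(tf)
  expect_equal(back$gene_id, r$gene_id)
  expect_equal(back$log2fc, r$log2fc, tolerance = 1e-9)
  expect_s3_class(back, "de_result")
})
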