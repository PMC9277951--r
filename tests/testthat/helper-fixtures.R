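# Small builders shared across test files.

toy_count_matrix <- function(m = NULL) {
  if (is.null(m)) {
    m <- matrix(c(100L, 200L, 10L, 20L, 1000L, 2000L), nrow = 3, byrow = TRUE,
                dimnames = list(paste0("g", 1:3), paste0("s", 1:2)))
  }
  count_matrix(m)
}

# Null trio matrix: every gene at the same mean in all samples.
null_trio <- function(n_genes, n_reps = 3, dispersion = 0.05, seed = 1) {
  cfg <- sim_config(n_genes = n_genes, n_reps = n_reps,
                    pattern_proportions = c(null = 1), dispersion = dispersion,
                    seed = seed)
  simulate_trio_counts(cfg)
}

# 20-row toy homology-hit table with known pass/fail status per row.
toy_hits <- function() {
  q_len <- c(Q1 = 100, Q2 = 200, Q3 = 400)
  hits <- data.frame(
    query_id = rep(c("Q1", "Q2", "Q3"), times = c(7, 7, 6)),
    subject_id = c("s1", "s1", "s2", "s3", "s4", "s5", "s6",
                   "s1", "s2", "s2", "s3", "s7", "s8", "s9",
                   "s2", "s3", "s5", "s7", "s9", "s10"),
    percent_identity = c(45, 45, 29, 30, 45, 80, 45,
                         55, 31, 90, 45, 45, 28, 60,
                         45, 45, 30.0001, 45, 12, 75),
    alignment_length = 50, mismatches = 5L, gap_opens = 0L,
    q_start = c(1, 1, 1, 1, 1, 60, 1,
                1, 1, 101, 1, 140, 1, 1,
                1, 1, 1, 380, 1, 1),
    q_end = c(60, 60, 60, 60, 29, 100, 31,
              120, 120, 200, 120, 200, 120, 60,
              240, 121, 240, 400, 240, 240),
    s_start = 1L, s_end = 50L,
    evalue = c(1e-30, 1e-20, 1e-30, 1e-30, 1e-30, 1e-40, 1e-30,
               1e-30, 1e-30, 1e-50, 1e-25, 1e-30, 1e-30, 1e-26,
               1e-60, 1e-30, 1e-30, 1e-35, 1e-30, 1e-30),
    bit_score = c(200, 300, 150, 150, 150, 180, 150,
                  150, 150, 250, 150, 140, 150, 90,
                  220, 160, 150, 130, 150, 210),
    stringsAsFactors = FALSE)
  list(hits = hits, q_len = q_len,
       map = c(Q1 = "KAT/AKT", Q2 = "NHX", Q3 = "KEA"))
}

# Independent brute-force upper-tail hypergeometric probability: sums the
# pmf written from binomial coefficients in log space. Never calls phyper.
brute_hyper_upper <- function(k, n, K, N) {
  xs <- k:min(n, K)
  if (length(xs) == 0) return(0)
  lp <- lchoose(K, xs) + lchoose(N - K, n - xs) - lchoose(N, n)
  mx <- max(lp)
  exp(mx) * sum(exp(lp - mx))
}

# Independent nested-if reading of the 12-pattern rule table, written
# deliberately without reuse of classify_gene's vectorized logic.
brute_pattern <- function(p1, p2, mp, pp) {
  if (p1 == "ns" && p2 == "ns") return("unclassified")
  if (p1 == "up" && p2 == "up") {
    if (pp == "down") return("P10")
    if (pp == "ns") return("P11")
    return("P12")
  }
  if (p1 == "down" && p2 == "down") {
    if (pp == "up") return("P7")
    if (pp == "ns") return("P8")
    return("P9")
  }
  if (p1 != "ns" && p2 != "ns") {           # opposite directions
    if (mp != "ns") return("conflicting")
    if (p1 == "down") return("P1") else return("P2")
  }
  # exactly one of p1/p2 is ns
  if (mp == "ns") return("conflicting")
  if (p1 == "ns") {
    if (p2 == "up") return("P3") else return("P4")
  }
  if (p1 == "up") return("P5") else return("P6")
}
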