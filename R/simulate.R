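#' Simulation configuration for parent-hybrid trio counts
#'
#' Bundles and validates the parameters of the negative-binomial trio
#' simulator. Counts are drawn per gene and replicate from
#' \code{NB(mu, size = 1/dispersion)}, so the variance is
#' \code{mu + mu^2 * dispersion}. Each gene is planted in one of the twelve
#' additive/dominant/overdominant expression patterns (or in the null, no
#' parental difference) with the given proportions.
#'
#' The default proportions put 70\% of genes in the null and split the rest so
#' that the planted overdominant fraction of non-additive genes
#' (P7--P12 over P3--P12) is 0.70.
#'
#' @param n_genes number of genes to simulate.
#' @param n_reps replicates per role (female parent, male parent, hybrid);
#'   at least 2 so downstream tests have within-group variance.
#' @param pattern_proportions named numeric vector over
#'   \code{c("P1".."P12","null")}, non-negative, summing to 1.
#' @param base_mean_log_range length-2 numeric: bounds of the uniform
#'   natural-log distribution of baseline expected counts.
#' @param dispersion common negative-binomial dispersion (> 0).
#' @param effect_log2fc magnitude (log2) of planted parental/hybrid shifts.
#' @param size_factors optional per-sample library-size multipliers
#'   (length \code{3 * n_reps}); default all 1.
#' @param seed integer seed; identical configs give bit-identical output.
#' @return an object of class \code{sim_config}.
#' @export
sim_config <- function(n_genes = 5000,
                       n_reps = 3,
                       pattern_proportions = default_pattern_proportions(),
                       base_mean_log_range = c(log(30), log(3000)),
                       dispersion = 0.05,
                       effect_log2fc = 2.0,
                       size_factors = NULL,
                       seed = 1L) {
  stopifnot(n_genes >= 1, length(base_mean_log_range) == 2,
            base_mean_log_range[1] <= base_mean_log_range[2])
  if (n_reps < 2) {
    stop("n_reps must be >= 2: downstream tests need within-group variance")
  }
  if (!(dispersion > 0)) stop("dispersion must be > 0")
  if (!(effect_log2fc > 0)) stop("effect_log2fc must be > 0")
  pp <- pattern_proportions
  lev <- c(paste0("P", 1:12), "null")
  if (is.null(names(pp)) || !all(names(pp) %in% lev)) {
    stop("pattern_proportions must be named with P1..P12 and 'null'")
  }
  full <- stats::setNames(numeric(length(lev)), lev)
  full[names(pp)] <- pp
  if (any(full < 0) || abs(sum(full) - 1) > 1e-9) {
    stop("pattern_proportions must be >= 0 and sum to 1")
  }
  if (!is.null(size_factors)) {
    stopifnot(length(size_factors) == 3 * n_reps, all(size_factors > 0))
  }
  structure(list(n_genes = as.integer(n_genes), n_reps = as.integer(n_reps),
                 pattern_proportions = full,
                 base_mean_log_range = base_mean_log_range,
                 dispersion = dispersion, effect_log2fc = effect_log2fc,
                 size_factors = size_factors, seed = as.integer(seed)),
            class = "sim_config")
}

#' Default planted-pattern proportions
#'
#' 70\% null genes; the non-null mass is split 0.06 additive (P1--P2),
#' 0.072 dominant (P3--P6) and 0.168 overdominant (P7--P12), so the planted
#' overdominant fraction among non-additive genes is 0.168/0.240 = 0.70.
#' @return named numeric vector over P1..P12 and "null".
#' @export
default_pattern_proportions <- function() {
  c(stats::setNames(rep(0.03, 2), paste0("P", 1:2)),
    stats::setNames(rep(0.018, 4), paste0("P", 3:6)),
    stats::setNames(rep(0.028, 6), paste0("P", 7:12)),
    null = 0.70)
}

# Expected counts (mu_female, mu_male, mu_hybrid) for one gene given its
# pattern, baseline mu and parental fold f = 2^effect_log2fc.
# P1/P2 additive (hybrid at mid-parent, parents differ); P3-P6 dominant
# (hybrid equals one parent); P7-P9 below both parents; P10-P12 above both,
# sub-indexed by the parent-vs-parent relation.
planted_means <- function(pattern, mu, f) {
  hi <- mu * f
  lo <- mu / f
  switch(pattern,
    null = c(mu, mu, mu),
    P1  = c(hi, lo, (hi + lo) / 2),       # female high, hybrid mid
    P2  = c(lo, hi, (hi + lo) / 2),       # male high, hybrid mid
    P3  = c(hi, lo, hi),                  # hybrid = female, female > male
    P4  = c(lo, hi, lo),                  # hybrid = female, female < male
    P5  = c(lo, hi, hi),                  # hybrid = male, male > female
    P6  = c(hi, lo, lo),                  # hybrid = male, male < female
    P7  = c(hi, lo, lo / f),              # below both, female > male
    P8  = c(mu, mu, mu / f),              # below both, parents equal
    P9  = c(lo, hi, lo / f),              # below both, female < male
    P10 = c(lo, hi, hi * f),              # above both, female < male
    P11 = c(mu, mu, mu * f),              # above both, parents equal
    P12 = c(hi, lo, hi * f),              # above both, female > male
    stop("unknown pattern: ", pattern))
}

#' Simulate a parent-parent-hybrid count matrix with planted patterns
#'
#' Draws gene-level counts for one trio (female parent, male parent, F1
#' hybrid, \code{n_reps} replicates each) from a negative binomial with
#' planted role means and a common dispersion, and returns the counts, the
#' trio design, and the per-gene planted truth.
#'
#' @param config a \code{\link{sim_config}}.
#' @param hybrid_id identifier used for the trio (default "H").
#' @return list with elements \code{counts} (a \code{\link{count_matrix}}),
#'   \code{design} (a \code{\link{trio_design}}) and \code{truth}
#'   (data.frame: gene_id, true_pattern, mu_female, mu_male, mu_hybrid).
#' @export
simulate_trio_counts <- function(config, hybrid_id = "H") {
  stopifnot(inherits(config, "sim_config"))
  withr_seed(config$seed, {
    n <- config$n_genes
    lev <- names(config$pattern_proportions)
    pattern <- sample(lev, n, replace = TRUE,
                      prob = config$pattern_proportions)
    mu0 <- exp(stats::runif(n, config$base_mean_log_range[1],
                            config$base_mean_log_range[2]))
    f <- 2^config$effect_log2fc
    mus <- t(vapply(seq_len(n),
                    function(i) planted_means(pattern[i], mu0[i], f),
                    numeric(3)))
    colnames(mus) <- c("mu_female", "mu_male", "mu_hybrid")

    k <- config$n_reps
    roles <- rep(c("female", "male", "hybrid"), each = k)
    sample_ids <- paste0(rep(c("F", "M", "H"), each = k), "_rep", rep(seq_len(k), 3))
    sf <- config$size_factors
    if (is.null(sf)) sf <- rep(1, 3 * k)
    size <- 1 / config$dispersion
    counts <- matrix(0L, nrow = n, ncol = 3 * k,
                     dimnames = list(sprintf("g%05d", seq_len(n)), sample_ids))
    for (j in seq_len(3 * k)) {
      mu_j <- mus[, c(female = 1, male = 2, hybrid = 3)[roles[j]]] * sf[j]
      counts[, j] <- stats::rnbinom(n, mu = mu_j, size = size)
    }
    design <- trio_design(
      hybrid_id = hybrid_id,
      samples = list(female = sample_ids[roles == "female"],
                     male = sample_ids[roles == "male"],
                     hybrid = sample_ids[roles == "hybrid"]))
    truth <- data.frame(gene_id = rownames(counts), true_pattern = pattern,
                        mus, stringsAsFactors = FALSE)
    list(counts = count_matrix(counts), design = design, truth = truth)
  })
}

# Evaluate expr with a locally-scoped RNG seed, restoring the global state.
withr_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Simulate a K+ phenotype time series with planted mid-parent heterosis
#'
#' Inbred genotypes get smooth baseline trait trajectories; each hybrid
#' (named \code{"<female>x<male>"}) gets a noiseless F1 value of
#' \code{MP * (1 + target_mph/100)} at every timepoint, where MP is the
#' parents' mid-parent mean. Replicate noise is additive Gaussian.
#'
#' @param genotypes character vector; hybrids encode their parents as
#'   \code{"P1xP2"} and both parents must also appear in \code{genotypes}.
#' @param timepoints integer vector (days after transplant).
#' @param target_mph named numeric, percent MPH per hybrid (genes absent
#'   default to 0). A scalar named vector or full map.
#' @param noise_sd replicate standard deviation (>= 0), trait units.
#' @param seed integer seed.
#' @param n_reps replicates per genotype x timepoint.
#' @param trait trait label, default \code{"k_content_percent"}.
#' @param parent_base optional named numeric of baseline trait values for the
#'   inbred genotypes; defaults are drawn once from Uniform(1.8, 2.8)
#'   (typical leaf K+ percent of dry weight).
#' @return data.frame: genotype, female_parent, male_parent, timepoint,
#'   trait, rep1..repK.
#' @export
simulate_phenotype <- function(genotypes, timepoints, target_mph = numeric(),
                               noise_sd = 0, seed = 1L, n_reps = 3,
                               trait = "k_content_percent",
                               parent_base = NULL) {
  stopifnot(noise_sd >= 0, n_reps >= 1, length(genotypes) >= 1)
  parsed <- parse_hybrid_names(genotypes)
  inbreds <- genotypes[is.na(parsed$female)]
  for (i in which(!is.na(parsed$female))) {
    for (p in c(parsed$female[i], parsed$male[i])) {
      if (!(p %in% inbreds)) {
        stop("hybrid '", genotypes[i], "' references unknown parent '", p, "'")
      }
    }
  }
  withr_seed(seed, {
    if (is.null(parent_base)) {
      parent_base <- stats::setNames(stats::runif(length(inbreds), 1.8, 2.8),
                                     inbreds)
    }
    tp <- sort(unique(as.integer(timepoints)))
    # mild shared rise-then-plateau over time so trajectories look biological
    t_eff <- 1 + 0.1 * tanh((tp - mean(tp)) / max(1, diff(range(tp)) / 2))
    base_val <- function(g, ti) parent_base[[g]] * t_eff[ti]
    rows <- list()
    for (g in genotypes) {
      i <- match(g, genotypes)
      for (ti in seq_along(tp)) {
        if (is.na(parsed$female[i])) {
          truthv <- base_val(g, ti)
        } else {
          mp <- (base_val(parsed$female[i], ti) + base_val(parsed$male[i], ti)) / 2
          mph <- if (g %in% names(target_mph)) target_mph[[g]] else 0
          truthv <- mp * (1 + mph / 100)
        }
        reps <- truthv + stats::rnorm(n_reps, 0, noise_sd)
        rows[[length(rows) + 1L]] <- data.frame(
          genotype = g,
          female_parent = ifelse(is.na(parsed$female[i]), "", parsed$female[i]),
          male_parent = ifelse(is.na(parsed$male[i]), "", parsed$male[i]),
          timepoint = tp[ti], trait = trait,
          t(stats::setNames(reps, paste0("rep", seq_len(n_reps)))),
          stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows)
  })
}

# Split "AxB" hybrid names (also accepts the multiplication sign) into
# parents; inbreds (no separator) give NA.
parse_hybrid_names <- function(genotypes) {
  parts <- strsplit(genotypes, "[x×]")
  female <- vapply(parts, function(p) if (length(p) == 2) p[1] else NA_character_,
                   character(1))
  male <- vapply(parts, function(p) if (length(p) == 2) p[2] else NA_character_,
                 character(1))
  list(female = female, male = male)
}

#' Simulate a gene-to-GO-term annotation with planted enrichment
#'
#' Every gene receives each term independently with a base probability;
#' a designated fraction of terms is "enriched": members of
#' \code{target_set} receive those terms with an elevated probability.
#' Terms that end up annotating no gene are given one random gene so every
#' term is represented.
#'
#' @param gene_ids background gene universe.
#' @param n_terms number of GO-like terms (>= 1).
#' @param enriched_term_fraction fraction of terms planted as enriched in
#'   \code{target_set}; 0 makes assignment independent of set membership.
#' @param target_set subset of \code{gene_ids} carrying the enrichment.
#' @param seed integer seed.
#' @param base_prob per-gene probability of a non-enriched term (default 0.05).
#' @param enriched_prob probability that an enriched term annotates a
#'   target-set gene (default 0.6).
#' @return list: \code{annotation} (data.frame gene_id, term_id) and
#'   \code{enriched_terms} (character vector of planted term ids).
#' @export
simulate_go_annotation <- function(gene_ids, n_terms, enriched_term_fraction,
                                   target_set = character(), seed = 1L,
                                   base_prob = 0.05, enriched_prob = 0.6) {
  if (n_terms < 1) stop("n_terms must be >= 1")
  stopifnot(enriched_term_fraction >= 0, enriched_term_fraction <= 1)
  if (!all(target_set %in% gene_ids)) {
    stop("target_set must be a subset of gene_ids")
  }
  withr_seed(seed, {
    terms <- sprintf("GO:%07d", seq_len(n_terms))
    n_enr <- floor(enriched_term_fraction * n_terms)
    enriched <- terms[seq_len(n_enr)]
    in_set <- gene_ids %in% target_set
    out <- vector("list", n_terms)
    for (t in seq_len(n_terms)) {
      p <- rep(base_prob, length(gene_ids))
      if (terms[t] %in% enriched) p[in_set] <- enriched_prob
      hit <- stats::runif(length(gene_ids)) < p
      if (!any(hit)) hit[sample.int(length(gene_ids), 1)] <- TRUE
      out[[t]] <- data.frame(gene_id = gene_ids[hit], term_id = terms[t],
                             stringsAsFactors = FALSE)
    }
    list(annotation = do.call(rbind, out), enriched_terms = enriched)
  })
}

#' Simulate a homology-hit table in BLAST tabular layout
#'
#' Builds a small hit table for a set of reference query proteins (each
#' mapped to a gene family) against synthetic subject genes. A configurable
#' fraction of hits is planted to pass the stringent filter
#' (E-value, identity, query coverage); the rest fail at least one threshold.
#'
#' @param query_families named character: query_id -> family label.
#' @param n_subjects number of subject gene models.
#' @param pass_fraction fraction of hits planted to pass the default filter.
#' @param seed integer seed.
#' @return list: \code{hits} (data.frame in outfmt-6 column order),
#'   \code{q_len} (named integer query lengths), \code{family_map}
#'   (data.frame query_id, family).
#' @export
simulate_homology_hits <- function(query_families, n_subjects = 12,
                                   pass_fraction = 0.5, seed = 1L) {
  stopifnot(length(query_families) >= 1, !is.null(names(query_families)))
  withr_seed(seed, {
    queries <- names(query_families)
    q_len <- stats::setNames(sample(250:900, length(queries), replace = TRUE),
                             queries)
    subjects <- sprintf("Nt_gene%03d", seq_len(n_subjects))
    rows <- list()
    for (q in queries) {
      hit_sub <- sample(subjects, min(n_subjects, sample(2:4, 1)))
      for (s in hit_sub) {
        pass <- stats::runif(1) < pass_fraction
        if (pass) {
          pid <- stats::runif(1, 35, 90)
          span <- ceiling(q_len[[q]] * stats::runif(1, 0.45, 0.98))
          ev <- 10^stats::runif(1, -120, -30)
        } else {
          # fail one threshold at random
          fail <- sample(3, 1)
          pid <- if (fail == 1) stats::runif(1, 10, 28) else stats::runif(1, 35, 90)
          span <- if (fail == 2) ceiling(q_len[[q]] * stats::runif(1, 0.05, 0.25))
                  else ceiling(q_len[[q]] * stats::runif(1, 0.45, 0.98))
          ev <- if (fail == 3) 10^stats::runif(1, -20, -3) else 10^stats::runif(1, -120, -30)
        }
        q_start <- sample.int(q_len[[q]] - span + 1L, 1)
        rows[[length(rows) + 1L]] <- data.frame(
          query_id = q, subject_id = s,
          percent_identity = round(pid, 1), alignment_length = span,
          mismatches = round(span * (1 - pid / 100)), gap_opens = sample(0:5, 1),
          q_start = q_start, q_end = q_start + span - 1L,
          s_start = 1L, s_end = span,
          evalue = signif(ev, 2), bit_score = round(span * pid / 250, 1),
          stringsAsFactors = FALSE)
      }
    }
    list(hits = do.call(rbind, rows), q_len = q_len,
         family_map = data.frame(query_id = queries,
                                 family = unname(query_families),
                                 stringsAsFactors = FALSE))
  })
}

#' Simulate a qPCR Ct table consistent with given log2 fold changes
#'
#' Produces technical-replicate Ct values for target genes and a reference
#' gene in a test and a control condition such that the noiseless
#' 2^-ddCt ratio of each target equals \code{2^log2fc[gene]}.
#'
#' @param log2fc named numeric: per-gene log2 fold change (test over control).
#' @param n_reps technical replicates per gene x condition.
#' @param noise_sd Gaussian Ct noise in cycles (>= 0).
#' @param seed integer seed.
#' @param ref_gene reference (housekeeping) gene id, default "Actin".
#' @param base_ct mean target Ct in the control condition.
#' @return data.frame: sample_id, condition, gene_id, ct, is_reference.
#' @export
simulate_ct_table <- function(log2fc, n_reps = 3, noise_sd = 0, seed = 1L,
                              ref_gene = "Actin", base_ct = 24) {
  stopifnot(!is.null(names(log2fc)), noise_sd >= 0, n_reps >= 1)
  withr_seed(seed, {
    rows <- list()
    for (cond in c("control", "test")) {
      for (r in seq_len(n_reps)) {
        sid <- paste0(cond, "_rep", r)
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = sid, condition = cond, gene_id = ref_gene,
          ct = 18 + stats::rnorm(1, 0, noise_sd), is_reference = TRUE,
          stringsAsFactors = FALSE)
        for (g in names(log2fc)) {
          # one extra cycle = half the expression: test Ct drops by log2fc
          ct <- base_ct - if (cond == "test") log2fc[[g]] else 0
          rows[[length(rows) + 1L]] <- data.frame(
            sample_id = sid, condition = cond, gene_id = g,
            ct = ct + stats::rnorm(1, 0, noise_sd), is_reference = FALSE,
            stringsAsFactors = FALSE)
        }
      }
    }
    do.call(rbind, rows)
  })
}
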