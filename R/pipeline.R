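#' Pipeline configuration
#'
#' Thresholds, seed and output location for a full synthetic end-to-end run.
#'
#' @param out_dir output directory (created if absent).
#' @param seed integer seed driving every stochastic stage.
#' @param p_max,lfc_min,use_adjusted DEG thresholds.
#' @param pattern_lfc_min fold-change gate for the pattern-classifier calls
#'   (default 0; see \code{\link{classify_trio}}).
#' @param bonferroni_alpha enrichment significance level.
#' @param evalue_max,identity_min,coverage_min family-filter thresholds.
#' @param sim a \code{\link{sim_config}} for the count simulation; its seed
#'   is overridden by \code{seed}.
#' @param skip character vector of stage names to omit, from
#'   \{"phenotype","de","patterns","enrichment","family","qpcr"\}.
#' @return an object of class \code{pipeline_config}.
#' @export
pipeline_config <- function(out_dir, seed = 1L, p_max = 0.05, lfc_min = 1.0,
                            use_adjusted = FALSE, pattern_lfc_min = 0,
                            bonferroni_alpha = 0.05, evalue_max = 1e-25,
                            identity_min = 30, coverage_min = 30,
                            sim = sim_config(), skip = character()) {
  stopifnot(p_max > 0, p_max <= 1, lfc_min >= 0, pattern_lfc_min >= 0,
            bonferroni_alpha > 0, bonferroni_alpha <= 1)
  bad <- setdiff(skip, c("phenotype", "de", "patterns", "enrichment",
                         "family", "qpcr"))
  if (length(bad)) stop("unknown stage(s) in skip: ", paste(bad, collapse = ", "))
  sim$seed <- as.integer(seed)
  structure(list(out_dir = out_dir, seed = as.integer(seed), p_max = p_max,
                 lfc_min = lfc_min, use_adjusted = use_adjusted,
                 pattern_lfc_min = pattern_lfc_min,
                 bonferroni_alpha = bonferroni_alpha,
                 evalue_max = evalue_max, identity_min = identity_min,
                 coverage_min = coverage_min, sim = sim, skip = skip),
            class = "pipeline_config")
}

config_hash <- function(config) {
  flat <- unlist(config[setdiff(names(config), "out_dir")])
  txt <- paste(names(flat), flat, sep = "=", collapse = ";")
  # small rolling hash; enough to detect any threshold/seed change
  h <- 0
  for (ch in utf8ToInt(txt)) h <- (h * 131 + ch) %% 2147483647
  sprintf("%08x", h)
}

stage_log <- function(quiet, ...) if (!quiet) message("[heterosisK] ", ...)

#' Run the full synthetic heterosis pipeline
#'
#' Generates phenotype and trio-count data with planted truth, then runs,
#' in order: MPH screening, the four trio DE contrasts, 12-pattern
#' classification and recovery, GO enrichment of the overdominant-up set,
#' family filtering of a toy homology table, and ddCt validation against
#' the RNA-seq fold changes. Writes one TSV per stage plus a JSON summary;
#' every output carries a provenance header (package version, config hash,
#' seed). Deterministic given config + seed.
#'
#' @param config a \code{\link{pipeline_config}}.
#' @param quiet suppress stage messages.
#' @return the summary list, invisibly; also written to
#'   \code{summary.json} under \code{config$out_dir}.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  prov <- c(sprintf("# heterosisK %s",
                    as.character(utils::packageVersion("heterosisK"))),
            sprintf("# config_hash %s", config_hash(config)),
            sprintf("# seed %d", config$seed))
  write_stage <- function(df, file) {
    path <- file.path(config$out_dir, file)
    writeLines(prov, path)
    suppressWarnings(utils::write.table(df, path, sep = "\t", quote = FALSE,
                                        row.names = FALSE, append = TRUE))
    path
  }
  run <- function(stage) !(stage %in% config$skip)
  summary <- list(version = as.character(utils::packageVersion("heterosisK")),
                  config_hash = config_hash(config), seed = config$seed)

  if (run("phenotype")) {
    stage_log(quiet, "phenotype: simulating K+ series and screening MPH")
    pheno <- simulate_phenotype(
      genotypes = c("G70", "GDH11", "K326", "G70xGDH11", "K326xGDH11"),
      timepoints = seq(50, 90, 10),
      target_mph = c("G70xGDH11" = 9.93, "K326xGDH11" = 3.98),
      noise_sd = 0, seed = config$seed)
    mph <- heterosis_table(pheno)
    screened <- screen_hybrids(mph, timepoint = 70)
    write_stage(mph, "mph.tsv")
    day70 <- mph[mph$timepoint == 70, ]
    summary$phenotype <- list(
      n_hybrids = length(unique(mph$hybrid)),
      strongest = screened$strongest, weakest = screened$weakest,
      mph_day70 = stats::setNames(as.list(day70$mph_percent), day70$hybrid))
  }

  sim <- NULL
  if (run("de") || run("patterns") || run("qpcr")) {
    stage_log(quiet, "simulate: trio counts with planted patterns (",
              config$sim$n_genes, " genes)")
    sim <- simulate_trio_counts(config$sim)
  }

  contrasts <- NULL
  if (run("de")) {
    stage_log(quiet, "de: four trio contrasts")
    contrasts <- run_trio_contrasts(sim$counts, sim$design,
                                    p_max = config$p_max,
                                    lfc_min = config$lfc_min,
                                    use_adjusted = config$use_adjusted)
    deg_counts <- lapply(contrasts, function(r)
      list(up = sum(r$call == "up"), down = sum(r$call == "down")))
    for (nm in names(contrasts)) {
      write_stage(contrasts[[nm]], paste0("de_", nm, ".tsv"))
    }
    summary$de <- list(n_genes_tested = sum(!is.na(contrasts[[1]]$p)),
                       deg_counts = deg_counts)
  }

  assignments <- NULL
  if (run("patterns")) {
    if (is.null(contrasts)) stop("patterns stage requires the de stage")
    stage_log(quiet, "patterns: 12-way classification and recovery")
    assignments <- classify_trio(contrasts, p_max = config$p_max,
                                 lfc_min = config$pattern_lfc_min,
                                 use_adjusted = config$use_adjusted)
    summ <- summarize_patterns(assignments)
    rec <- recover_proportions(sim$truth, assignments)
    write_stage(assignments, "patterns.tsv")
    summary$patterns <- list(
      counts = as.list(summ$counts), grouped = as.list(summ$grouped),
      overdominant_percent = summ$overdominant_percent,
      planted_od_fraction = rec$planted_od_fraction,
      estimated_od_fraction = rec$estimated_od_fraction)
  }

  if (run("enrichment")) {
    if (is.null(assignments)) stop("enrichment stage requires the patterns stage")
    stage_log(quiet, "enrichment: GO over-representation of overdominant-up set")
    od_up <- assignments$gene_id[assignments$category == "overdominant_up"]
    background <- assignments$gene_id
    ann <- simulate_go_annotation(background, n_terms = 200,
                                  enriched_term_fraction = 0.05,
                                  target_set = od_up, seed = config$seed)
    enr <- enrich(od_up, ann$annotation, background)
    sig <- enr[enr$p_bonferroni <= config$bonferroni_alpha, , drop = FALSE]
    write_stage(enr, "enrichment.tsv")
    summary$enrichment <- list(
      n_terms_tested = nrow(enr), n_significant = nrow(sig),
      planted_terms_recovered = sum(ann$enriched_terms %in% sig$term_id),
      n_planted_terms = length(ann$enriched_terms))
  }

  if (run("family")) {
    stage_log(quiet, "family: homology filtering and family assignment")
    fams <- c(AtKAT1 = "KAT/AKT", AtAKT2 = "KAT/AKT", AtGORK = "GORK",
              AtTPK1 = "TPK", AtTPC1 = "TPC", AtNHX1 = "NHX",
              AtKEA3 = "KEA", AtCIPK6 = "CBL/CIPK")
    hom <- simulate_homology_hits(fams, seed = config$seed)
    kept <- filter_hits(hom$hits, hom$q_len, evalue_max = config$evalue_max,
                        identity_min = config$identity_min,
                        coverage_min = config$coverage_min)
    asg <- assign_families(kept, hom$family_map)
    write_stage(asg, "families.tsv")
    summary$family <- list(n_hits_in = nrow(hom$hits),
                           n_hits_kept = nrow(kept),
                           n_subjects_assigned = nrow(asg),
                           n_families = length(unique(asg$family)))
  }

  if (run("qpcr")) {
    if (is.null(contrasts)) stop("qpcr stage requires the de stage")
    stage_log(quiet, "qpcr: ddCt validation of sampled DEGs")
    hvf <- contrasts$H_vs_P1
    deg <- hvf[hvf$call != "ns", , drop = FALSE]
    pick <- utils::head(deg[order(deg$p), "gene_id"], 9)
    lfc <- stats::setNames(hvf$log2fc[match(pick, hvf$gene_id)], pick)
    ct <- simulate_ct_table(lfc, noise_sd = 0.1, seed = config$seed)
    ratios <- ddct_table(ct)
    conc <- concordance(stats::setNames(ratios$log2_ratio, ratios$gene_id), lfc)
    write_stage(ratios, "qpcr.tsv")
    summary$qpcr <- list(n_genes = length(pick),
                         sign_agreement = conc$sign_agreement,
                         rank_correlation = conc$rank_correlation)
  }

  jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}
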