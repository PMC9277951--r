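#' Classify one gene into the twelve trio expression patterns
#'
#' Given the four per-gene DEG calls of a trio — hybrid vs female parent
#' (\code{callP1}), hybrid vs male parent (\code{callP2}), hybrid vs virtual
#' mid-parent (\code{callMP}) and female vs male parent (\code{callPP}),
#' with "up" meaning the first member is higher — assigns one of:
#' \itemize{
#'   \item \strong{P1, P2} (additive): hybrid between parents at the
#'     mid-parent level — parent calls significant in opposite directions
#'     and \code{callMP} ns. P1 when the female parent is the high one
#'     (\code{callP1 = down}), P2 when the male parent is.
#'   \item \strong{P3--P6} (dominant): hybrid matches one parent
#'     (that call ns) and differs from the mid-parent. Indexed by which
#'     parent is matched and the direction vs the other parent: P3 = like
#'     female, above male; P4 = like female, below male; P5 = like male,
#'     above female; P6 = like male, below female.
#'   \item \strong{P7--P9} (overdominant, down): hybrid below both parents
#'     (both calls down), split by the parent-parent relation
#'     \code{callPP} in \{up, ns, down\}. \code{callMP} is ignored:
#'     transgressive status is decided by the two parent comparisons alone.
#'   \item \strong{P10--P12} (overdominant, up): hybrid above both parents,
#'     split by \code{callPP} in \{down, ns, up\}.
#'   \item \strong{unclassified}: both parent calls ns (not a trio DEG).
#'   \item \strong{conflicting}: any remaining combination (e.g.
#'     additive-shaped but significantly off the mid-parent).
#' }
#'
#' @param callP1,callP2,callMP,callPP character vectors over
#'   \{"up","down","ns"\} (recycled to a common length).
#' @return data.frame: pattern, category with category in
#'   \{additive, dominant, overdominant_down, overdominant_up, none\}.
#' @export
classify_gene <- function(callP1, callP2, callMP, callPP) {
  calls <- cbind(callP1, callP2, callMP, callPP)  # recycles and checks
  bad <- !(calls %in% c("up", "down", "ns"))
  if (any(bad)) stop("invalid call token: ", paste(unique(calls[bad]), collapse = ", "))
  p1 <- calls[, 1]; p2 <- calls[, 2]; mp <- calls[, 3]; pp <- calls[, 4]

  pat <- rep("conflicting", nrow(calls))
  pat[p1 == "ns" & p2 == "ns"] <- "unclassified"

  od_up <- p1 == "up" & p2 == "up"
  pat[od_up & pp == "down"] <- "P10"
  pat[od_up & pp == "ns"] <- "P11"
  pat[od_up & pp == "up"] <- "P12"
  od_dn <- p1 == "down" & p2 == "down"
  pat[od_dn & pp == "up"] <- "P7"
  pat[od_dn & pp == "ns"] <- "P8"
  pat[od_dn & pp == "down"] <- "P9"

  opp <- (p1 == "up" & p2 == "down") | (p1 == "down" & p2 == "up")
  pat[opp & mp == "ns" & p1 == "down"] <- "P1"
  pat[opp & mp == "ns" & p1 == "up"] <- "P2"

  one_ns <- xor(p1 == "ns", p2 == "ns")
  dom <- one_ns & mp != "ns"
  pat[dom & p1 == "ns" & p2 == "up"] <- "P3"
  pat[dom & p1 == "ns" & p2 == "down"] <- "P4"
  pat[dom & p2 == "ns" & p1 == "up"] <- "P5"
  pat[dom & p2 == "ns" & p1 == "down"] <- "P6"

  data.frame(pattern = pat, category = pattern_category(pat),
             stringsAsFactors = FALSE)
}

#' Grouped category of a pattern label
#' @param pattern character vector over P1..P12, unclassified, conflicting.
#' @return character vector of grouped categories.
#' @export
pattern_category <- function(pattern) {
  cat <- rep("none", length(pattern))
  cat[pattern %in% c("P1", "P2")] <- "additive"
  cat[pattern %in% paste0("P", 3:6)] <- "dominant"
  cat[pattern %in% paste0("P", 7:9)] <- "overdominant_down"
  cat[pattern %in% paste0("P", 10:12)] <- "overdominant_up"
  cat
}

#' Classify every gene of a trio from its four contrast results
#'
#' Re-derives the four calls at the given thresholds and applies
#' \code{\link{classify_gene}}. The classifier defaults differ from DEG
#' counting in two deliberate ways: no fold-change gate
#' (\code{lfc_min = 0}), because the hybrid-vs-midparent shift of a
#' dominant gene is below one log2 unit by construction, so a gate on that
#' contrast would empty the dominant class; and BH-adjusted significance
#' (\code{use_adjusted = TRUE}), because the pattern assignment intersects
#' four correlated per-gene calls and raw-p calls at 5\% leak null genes
#' into the dominant class.
#'
#' @param contrasts named list of \code{de_result} data.frames with elements
#'   H_vs_P1, H_vs_P2, H_vs_MP, P1_vs_P2 (as from
#'   \code{\link{run_trio_contrasts}}), over a common gene order.
#' @param p_max,lfc_min,use_adjusted call thresholds
#'   (see \code{\link{call_degs}}).
#' @return data.frame: gene_id, pattern, category.
#' @export
classify_trio <- function(contrasts, p_max = 0.05, lfc_min = 0,
                          use_adjusted = TRUE) {
  need <- c("H_vs_P1", "H_vs_P2", "H_vs_MP", "P1_vs_P2")
  stopifnot(all(need %in% names(contrasts)))
  g <- contrasts[[need[1]]]$gene_id
  for (nm in need[-1]) {
    if (!identical(contrasts[[nm]]$gene_id, g)) {
      stop("contrast results must cover the same genes in the same order")
    }
  }
  calls <- lapply(need, function(nm) {
    call_degs(contrasts[[nm]], p_max = p_max, lfc_min = lfc_min,
              use_adjusted = use_adjusted)$call
  })
  cls <- classify_gene(calls[[1]], calls[[2]], calls[[3]], calls[[4]])
  data.frame(gene_id = g, cls, stringsAsFactors = FALSE)
}

#' Summarize pattern assignments
#'
#' Counts per pattern, grouped category totals, and the overdominant
#' fraction of non-additive genes (P7--P12 over P3--P12; conflicting and
#' unclassified genes are excluded from all proportions).
#'
#' @param assignments data.frame with a \code{pattern} column.
#' @return list: \code{counts} (named integer over the 14 labels),
#'   \code{grouped} (named integer over categories),
#'   \code{overdominant_fraction_of_nonadditive} (NA when no non-additive
#'   genes), \code{overdominant_percent} (the same as percent, 2 dp).
#' @export
summarize_patterns <- function(assignments) {
  lev <- c(paste0("P", 1:12), "unclassified", "conflicting")
  counts <- table(factor(assignments$pattern, levels = lev))
  counts <- stats::setNames(as.integer(counts), lev)
  grouped <- vapply(split(counts, pattern_category(lev)), sum, integer(1))
  od <- sum(counts[paste0("P", 7:12)])
  nonadd <- sum(counts[paste0("P", 3:12)])
  frac <- if (nonadd > 0) od / nonadd else NA_real_
  list(counts = counts, grouped = grouped,
       overdominant_fraction_of_nonadditive = frac,
       overdominant_percent = if (is.na(frac)) NA_real_ else round(100 * frac, 2))
}

#' Compare recovered pattern assignments with the planted truth
#'
#' @param truth data.frame (gene_id, true_pattern) from
#'   \code{\link{simulate_trio_counts}}.
#' @param assignments data.frame (gene_id, pattern) from
#'   \code{\link{classify_trio}}.
#' @return list: \code{confusion} (true x assigned table),
#'   \code{per_pattern} (data.frame pattern, n_true, precision, recall),
#'   \code{planted_od_fraction} and \code{estimated_od_fraction}
#'   (overdominant fraction of non-additive, planted vs recovered).
#' @export
recover_proportions <- function(truth, assignments) {
  if (!setequal(truth$gene_id, assignments$gene_id)) {
    stop("truth and assignments cover different gene sets")
  }
  a <- assignments[match(truth$gene_id, assignments$gene_id), ]
  conf <- table(true = truth$true_pattern, assigned = a$pattern)
  pats <- paste0("P", 1:12)
  per <- do.call(rbind, lapply(pats, function(p) {
    tp <- sum(truth$true_pattern == p & a$pattern == p)
    n_true <- sum(truth$true_pattern == p)
    n_called <- sum(a$pattern == p)
    data.frame(pattern = p, n_true = n_true,
               precision = if (n_called > 0) tp / n_called else NA_real_,
               recall = if (n_true > 0) tp / n_true else NA_real_,
               stringsAsFactors = FALSE)
  }))
  planted_frac <- od_fraction(truth$true_pattern)
  est_frac <- od_fraction(a$pattern)
  list(confusion = conf, per_pattern = per,
       planted_od_fraction = planted_frac, estimated_od_fraction = est_frac)
}

od_fraction <- function(pattern) {
  od <- sum(pattern %in% paste0("P", 7:12))
  nonadd <- sum(pattern %in% paste0("P", 3:12))
  if (nonadd > 0) od / nonadd else NA_real_
}
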