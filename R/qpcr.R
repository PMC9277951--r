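#' Relative expression by the 2^-ddCt method
#'
#' ddCt = (Ct_target,test - Ct_ref,test) - (Ct_target,ctrl - Ct_ref,ctrl);
#' the relative expression of the target in the test condition over the
#' control is 2^-ddCt. Replicate Ct values are averaged on the Ct scale
#' before differencing. Amplification efficiency is assumed perfect
#' (doubling per cycle).
#'
#' @param ct_target_test,ct_ref_test Ct values (scalar or replicate vector)
#'   of the target and reference gene in the test condition.
#' @param ct_target_ctrl,ct_ref_ctrl the same in the control condition.
#' @return the fold change 2^-ddCt.
#' @examples
#' ddct_ratio(24, 18, 26, 18)  # ddCt = -2 -> 4
#' @export
ddct_ratio <- function(ct_target_test, ct_ref_test,
                       ct_target_ctrl, ct_ref_ctrl) {
  vals <- c(ct_target_test, ct_ref_test, ct_target_ctrl, ct_ref_ctrl)
  if (!all(is.finite(vals))) stop("all Ct values must be finite")
  ddct <- (mean(ct_target_test) - mean(ct_ref_test)) -
    (mean(ct_target_ctrl) - mean(ct_ref_ctrl))
  2^(-ddct)
}

#' 2^-ddCt ratios for every target gene of a Ct table
#'
#' @param ct data.frame with columns sample_id, condition, gene_id, ct,
#'   is_reference (as produced by \code{\link{simulate_ct_table}}); exactly
#'   one reference gene per condition is expected.
#' @param test,control condition labels.
#' @return data.frame: gene_id, ratio, log2_ratio.
#' @export
ddct_table <- function(ct, test = "test", control = "control") {
  stopifnot(all(c("condition", "gene_id", "ct", "is_reference") %in% names(ct)))
  for (cond in c(test, control)) {
    if (!any(ct$condition == cond & ct$is_reference)) {
      stop("no reference-gene record in condition '", cond, "'")
    }
  }
  ref_t <- ct$ct[ct$condition == test & ct$is_reference]
  ref_c <- ct$ct[ct$condition == control & ct$is_reference]
  genes <- unique(ct$gene_id[!ct$is_reference])
  out <- do.call(rbind, lapply(genes, function(g) {
    tt <- ct$ct[ct$condition == test & ct$gene_id == g & !ct$is_reference]
    tc <- ct$ct[ct$condition == control & ct$gene_id == g & !ct$is_reference]
    r <- ddct_ratio(tt, ref_t, tc, ref_c)
    data.frame(gene_id = g, ratio = r, log2_ratio = log2(r),
               stringsAsFactors = FALSE)
  }))
  out
}

#' Concordance between qPCR and RNA-seq fold changes
#'
#' Over the genes shared by the two maps: the fraction whose log2 fold
#' changes agree in sign (values within 1e-9 of zero agree with anything)
#' and the Spearman rank correlation.
#'
#' @param qpcr_log2 named numeric: per-gene qPCR log2 fold change.
#' @param rnaseq_log2fc named numeric: per-gene RNA-seq log2 fold change.
#' @return list: n_shared, sign_agreement, rank_correlation.
#' @export
concordance <- function(qpcr_log2, rnaseq_log2fc) {
  shared <- intersect(names(qpcr_log2), names(rnaseq_log2fc))
  if (length(shared) < 3) stop("need >= 3 shared genes, got ", length(shared))
  a <- qpcr_log2[shared]
  b <- rnaseq_log2fc[shared]
  tol <- 1e-9
  agree <- abs(a) <= tol | abs(b) <= tol | sign(a) == sign(b)
  list(n_shared = length(shared),
       sign_agreement = mean(agree),
       rank_correlation = stats::cor(a, b, method = "spearman"))
}
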