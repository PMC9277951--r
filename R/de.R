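#' Median-of-ratios library-size normalization
#'
#' Computes one size factor per sample as the median, over genes with
#' all-positive counts, of the ratio of the sample's count to the gene's
#' geometric mean across samples; size factors are then rescaled to
#' geometric mean 1. Normalized values are count / size factor.
#'
#' @param x a \code{\link{count_matrix}}.
#' @return the same \code{count_matrix} with \code{size_factors} set.
#' @export
normalize_counts <- function(x) {
  stopifnot(inherits(x, "count_matrix"))
  m <- x$counts
  zero_samples <- colnames(m)[colSums(m) == 0]
  if (length(zero_samples)) {
    stop("sample(s) with all-zero counts: ",
         paste(zero_samples, collapse = ", "))
  }
  pos <- rowSums(m > 0) == ncol(m)
  if (!any(pos)) stop("no gene has positive counts in every sample")
  logm <- log(m[pos, , drop = FALSE])
  log_ref <- rowMeans(logm)                       # log geometric mean
  sf <- exp(apply(logm - log_ref, 2, stats::median))
  sf <- sf / exp(mean(log(sf)))                   # geometric mean 1
  count_matrix(m, size_factors = sf)
}

#' Append virtual mid-parent samples to a normalized trio matrix
#'
#' Pairs the female and male parent replicates by index (up to the shorter
#' list) and appends, per pair, a virtual mid-parent (MP) sample whose value
#' is the arithmetic mean of the two parents' normalized counts, rounded
#' half-to-even back to integers. MP samples get size factor 1 (they are
#' built on the normalized scale).
#'
#' @param x a normalized \code{\link{count_matrix}}.
#' @param design a \code{\link{trio_design}} over the samples of \code{x}.
#' @return list: \code{counts} (matrix with MP columns appended),
#'   \code{mp_samples} (the new sample ids).
#' @export
build_mid_parent <- function(x, design) {
  stopifnot(inherits(x, "count_matrix"), inherits(design, "trio_design"))
  if (is.null(x$size_factors)) {
    stop("normalize the matrix before building mid-parent samples")
  }
  norm <- normalized_counts(x)
  f <- design$samples$female
  m <- design$samples$male
  n_mp <- min(length(f), length(m))
  if (n_mp < 2) stop("fewer than 2 constructible mid-parent replicates")
  mp_ids <- paste0("MP_rep", seq_len(n_mp))
  mp <- vapply(seq_len(n_mp),
               function(i) round((norm[, f[i]] + norm[, m[i]]) / 2),
               numeric(nrow(norm)))
  colnames(mp) <- mp_ids
  newc <- cbind(x$counts, mp)
  storage.mode(newc) <- "integer"
  out <- count_matrix(newc,
                      size_factors = c(x$size_factors,
                                       stats::setNames(rep(1, n_mp), mp_ids)))
  list(counts = out, mp_samples = mp_ids)
}

#' Per-gene negative-binomial Wald test between two sample groups
#'
#' For each gene, the log2 fold change of group A over group B is
#' \code{log2((meanA + c) / (meanB + c))} on normalized counts with
#' pseudo-count c = 0.5. The NB dispersion is estimated per gene by method
#' of moments (pooled within-group variance), floored at 1e-8, and shrunk
#' 50\% toward a trended mean-dispersion fit
#' \code{alpha(mu) = a0 + a1/mu}. The Wald statistic log2fc / SE(log2fc)
#' uses the delta-method standard error under the NB variance
#' \code{mu + alpha mu^2}; two-sided p-values come from the normal
#' reference, and adjusted p-values from Benjamini-Hochberg over tested
#' genes. Genes with total raw count < \code{min_total} across both groups
#' are reported but not tested (p = NA, call "ns").
#'
#' @param x a normalized \code{\link{count_matrix}}.
#' @param groupA,groupB character vectors of sample ids (>= 2 each).
#' @param contrast label stored with the result (e.g. "H_vs_P1").
#' @param min_total low-count filter on the summed raw counts (default 10).
#' @return data.frame of class \code{de_result}: gene_id, contrast,
#'   base_meanA, base_meanB, log2fc, se, p, padj, call (all "ns" until
#'   \code{\link{call_degs}}).
#' @export
nb_test <- function(x, groupA, groupB, contrast = "A_vs_B", min_total = 10) {
  stopifnot(inherits(x, "count_matrix"))
  if (length(groupA) < 2 || length(groupB) < 2) {
    stop("each group needs >= 2 samples")
  }
  stopifnot(all(c(groupA, groupB) %in% colnames(x$counts)))
  norm <- normalized_counts(x)
  a <- norm[, groupA, drop = FALSE]
  b <- norm[, groupB, drop = FALSE]
  nA <- length(groupA); nB <- length(groupB)
  meanA <- rowMeans(a); meanB <- rowMeans(b)
  varA <- apply(a, 1, stats::var); varB <- apply(b, 1, stats::var)

  # method-of-moments dispersion from the pooled within-group variance
  pool_var <- ((nA - 1) * varA + (nB - 1) * varB) / (nA + nB - 2)
  pool_mean <- (nA * meanA + nB * meanB) / (nA + nB)
  alpha_mom <- pmax((pool_var - pool_mean) / pool_mean^2, 1e-8)
  alpha <- 0.5 * alpha_mom +
    0.5 * dispersion_trend(pool_mean, alpha_mom)(pool_mean)

  c0 <- 0.5
  log2fc <- log2((meanA + c0) / (meanB + c0))
  # delta-method variance of log2(mean + c0); the pseudo-count enters the
  # NB variance as well, which keeps the statistic calibrated at low counts
  v_log <- function(mu, n) {
    ((mu + c0) + alpha * (mu + c0)^2) / n / ((mu + c0)^2 * log(2)^2)
  }
  se <- sqrt(v_log(meanA, nA) + v_log(meanB, nB))
  z <- log2fc / se
  p <- 2 * stats::pnorm(-abs(z))

  total <- rowSums(x$counts[, c(groupA, groupB), drop = FALSE])
  tested <- total >= min_total
  p[!tested] <- NA_real_
  padj <- rep(NA_real_, length(p))
  padj[tested] <- stats::p.adjust(p[tested], method = "BH")

  res <- data.frame(gene_id = rownames(norm), contrast = contrast,
                    base_meanA = meanA, base_meanB = meanB,
                    log2fc = log2fc, se = se, p = p, padj = padj,
                    call = "ns", stringsAsFactors = FALSE, row.names = NULL)
  class(res) <- c("de_result", class(res))
  res
}

# Fit alpha(mu) = a0 + a1/mu over genes with informative moment estimates;
# returns a prediction function. Falls back to the median dispersion when
# the regression is degenerate.
dispersion_trend <- function(mu, alpha_mom) {
  keep <- is.finite(alpha_mom) & alpha_mom > 1e-8 & mu > 0
  med <- stats::median(alpha_mom[keep])
  if (sum(keep) < 10) {
    if (!is.finite(med)) med <- 0.1
    return(function(m) rep(med, length(m)))
  }
  fit <- try(stats::lm(alpha_mom[keep] ~ I(1 / mu[keep])), silent = TRUE)
  if (inherits(fit, "try-error")) return(function(m) rep(med, length(m)))
  a0 <- max(stats::coef(fit)[1], 0)
  a1 <- max(stats::coef(fit)[2], 0)
  if (a0 == 0 && a1 == 0) return(function(m) rep(med, length(m)))
  function(m) a0 + a1 / pmax(m, 1e-8)
}

#' Call differentially expressed genes on a test result
#'
#' Sets \code{call} to "up" when significant with log2fc >= \code{lfc_min},
#' "down" when significant with log2fc <= -\code{lfc_min}, else "ns".
#' Significance uses raw p by default (adjusted p with
#' \code{use_adjusted = TRUE}). Untested genes stay "ns".
#'
#' @param results a \code{de_result} data.frame from \code{\link{nb_test}}.
#' @param p_max significance threshold in (0, 1].
#' @param lfc_min minimum absolute log2 fold change (>= 0).
#' @param use_adjusted use BH-adjusted p instead of raw p.
#' @return the results with \code{call} filled in.
#' @export
call_degs <- function(results, p_max = 0.05, lfc_min = 1.0,
                      use_adjusted = FALSE) {
  if (!(p_max > 0 && p_max <= 1)) stop("p_max must be in (0, 1]")
  if (lfc_min < 0) stop("lfc_min must be >= 0")
  pv <- if (use_adjusted) results$padj else results$p
  sig <- !is.na(pv) & pv <= p_max
  results$call <- ifelse(sig & results$log2fc >= lfc_min, "up",
                         ifelse(sig & results$log2fc <= -lfc_min, "down", "ns"))
  results
}

#' Run the four trio contrasts for one cross
#'
#' Normalizes, builds virtual mid-parent samples, and tests hybrid vs
#' female parent (H_vs_P1), hybrid vs male parent (H_vs_P2), hybrid vs
#' mid-parent (H_vs_MP) and female vs male parent (P1_vs_P2), each with
#' "up" meaning the first group is higher.
#'
#' @param x a raw \code{\link{count_matrix}}.
#' @param design a \code{\link{trio_design}}.
#' @param p_max,lfc_min,use_adjusted DEG thresholds passed to
#'   \code{\link{call_degs}}.
#' @return named list of called \code{de_result} data.frames
#'   (H_vs_P1, H_vs_P2, H_vs_MP, P1_vs_P2).
#' @export
run_trio_contrasts <- function(x, design, p_max = 0.05, lfc_min = 1.0,
                               use_adjusted = FALSE) {
  xn <- normalize_counts(x)
  mp <- build_mid_parent(xn, design)
  h <- design$samples$hybrid
  f <- design$samples$female
  m <- design$samples$male
  specs <- list(H_vs_P1 = list(h, f), H_vs_P2 = list(h, m),
                H_vs_MP = list(h, mp$mp_samples), P1_vs_P2 = list(f, m))
  lapply(stats::setNames(names(specs), names(specs)), function(nm) {
    r <- nb_test(mp$counts, specs[[nm]][[1]], specs[[nm]][[2]], contrast = nm)
    call_degs(r, p_max = p_max, lfc_min = lfc_min, use_adjusted = use_adjusted)
  })
}

#' @rdname heterosis_io
#' @export
write_de_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname heterosis_io
#' @export
read_de_tsv <- function(path) {
  res <- utils::read.delim(path, stringsAsFactors = FALSE)
  class(res) <- c("de_result", class(res))
  res
}
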