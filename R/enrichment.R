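#' Upper-tail hypergeometric over-representation p-value
#'
#' P(X >= k) for X ~ Hypergeometric(N, K, n): the chance of drawing at
#' least \code{k} annotated genes when \code{n} genes are sampled without
#' replacement from a background of \code{N} genes of which \code{K} carry
#' the term. Evaluated through the regularized tail in log space
#' (\code{stats::phyper}).
#'
#' @param k observed hits in the set (vectorized with the rest).
#' @param n set size.
#' @param K background hits (genes annotated with the term).
#' @param N background size.
#' @return upper-tail probability in [0, 1].
#' @export
hypergeom_test <- function(k, n, K, N) {
  bad <- k < 0 | k > n | n > N | k > K | K > N
  if (any(bad)) stop("inconsistent hypergeometric counts (need 0 <= k <= n <= N, k <= K <= N)")
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Propagate an annotation up an ontology parent map
#'
#' Adds, for every gene-term pair, all ancestor terms reachable through the
#' (acyclic) is_a/part_of parent map.
#'
#' @param annotation data.frame (gene_id, term_id).
#' @param parents data.frame (term_id, parent_id) or NULL for no-op.
#' @return the transitively closed annotation, deduplicated.
#' @export
propagate_annotation <- function(annotation, parents = NULL) {
  if (is.null(parents) || nrow(parents) == 0) return(unique(annotation))
  pmap <- split(parents$parent_id, parents$term_id)
  ancestors <- function(term) {
    seen <- character()
    queue <- term
    while (length(queue)) {
      t <- queue[[1]]; queue <- queue[-1]
      for (p in pmap[[t]]) {
        if (p %in% seen) next
        if (p == term) stop("cycle in ontology parent map at ", term)
        seen <- c(seen, p); queue <- c(queue, p)
      }
    }
    seen
  }
  anc <- lapply(stats::setNames(unique(annotation$term_id),
                                unique(annotation$term_id)), ancestors)
  extra <- do.call(rbind, lapply(seq_len(nrow(annotation)), function(i) {
    a <- anc[[annotation$term_id[i]]]
    if (!length(a)) return(NULL)
    data.frame(gene_id = annotation$gene_id[i], term_id = a,
               stringsAsFactors = FALSE)
  }))
  unique(rbind(annotation, extra))
}

#' GO-term over-representation of a gene set
#'
#' Tests every annotated term with at least one hit in the set against the
#' whole-background universe with the upper-tail hypergeometric test and
#' applies Bonferroni control, with m = number of tested terms.
#'
#' @param set_genes character vector, must be a subset of \code{background}.
#' @param annotation data.frame (gene_id, term_id); genes outside the
#'   background are ignored.
#' @param background character vector: the gene universe (N = its size).
#' @param parents optional ontology parent map for propagation first.
#' @param min_K,max_K_frac term-size bounds: only terms with
#'   \code{min_K <= K <= max_K_frac * N} are tested.
#' @return data.frame sorted by p: term_id, set_hits, set_size,
#'   background_hits, background_size, p, p_bonferroni.
#' @export
enrich <- function(set_genes, annotation, background, parents = NULL,
                   min_K = 2, max_K_frac = 0.5) {
  set_genes <- unique(set_genes)
  background <- unique(background)
  missing <- setdiff(set_genes, background)
  if (length(missing)) {
    stop("set gene(s) absent from background: ",
         paste(utils::head(missing, 5), collapse = ", "),
         if (length(missing) > 5) " ...")
  }
  ann <- propagate_annotation(annotation, parents)
  if (any(!nzchar(ann$term_id))) stop("empty term ids in annotation")
  ann <- unique(ann[ann$gene_id %in% background, , drop = FALSE])
  if (nrow(ann) == 0) {
    return(data.frame(term_id = character(), set_hits = integer(),
                      set_size = integer(), background_hits = integer(),
                      background_size = integer(), p = numeric(),
                      p_bonferroni = numeric(), stringsAsFactors = FALSE))
  }
  N <- length(background)
  n <- length(set_genes)
  K_all <- table(ann$term_id)
  in_set <- ann[ann$gene_id %in% set_genes, , drop = FALSE]
  k_all <- table(in_set$term_id)
  terms <- names(k_all)                                   # >= 1 set hit
  K <- as.integer(K_all[terms])
  keep <- K >= min_K & K <= max_K_frac * N
  terms <- terms[keep]
  if (!length(terms)) {
    return(data.frame(term_id = character(), set_hits = integer(),
                      set_size = integer(), background_hits = integer(),
                      background_size = integer(), p = numeric(),
                      p_bonferroni = numeric(), stringsAsFactors = FALSE))
  }
  K <- K[keep]
  k <- as.integer(k_all[terms])
  p <- hypergeom_test(k, n, K, N)
  m <- length(terms)
  out <- data.frame(term_id = terms, set_hits = k, set_size = n,
                    background_hits = K, background_size = N, p = p,
                    p_bonferroni = pmin(1, p * m), stringsAsFactors = FALSE,
                    row.names = NULL)
  out[order(out$p, out$term_id), , drop = FALSE]
}

#' Sorted, deduplicated intersection of two gene sets
#' @param a,b character vectors.
#' @return sorted character vector of the common genes.
#' @export
intersect_sets <- function(a, b) {
  sort(intersect(unique(a), unique(b)))
}

#' @rdname heterosis_io
#' @export
read_annotation_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, header = TRUE)
  if (ncol(df) < 2) stop("annotation needs two columns: gene_id, term_id")
  names(df)[1:2] <- c("gene_id", "term_id")
  df[, 1:2]
}
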