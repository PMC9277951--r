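#' Gene x sample count matrix with library-size metadata
#'
#' A light container for gene-level counts: an integer-valued matrix with
#' unique gene rownames and sample colnames, plus optional per-sample size
#' factors (set by \code{\link{normalize_counts}}, not supplied by the user).
#'
#' @param counts numeric matrix, non-negative and integral, with unique
#'   dimnames.
#' @param size_factors optional positive numeric, one per sample.
#' @return an object of class \code{count_matrix}.
#' @export
count_matrix <- function(counts, size_factors = NULL) {
  stopifnot(is.matrix(counts), !is.null(rownames(counts)),
            !is.null(colnames(counts)))
  if (anyDuplicated(rownames(counts)) || anyDuplicated(colnames(counts))) {
    stop("duplicate gene or sample ids")
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers")
  }
  if (!is.null(size_factors)) {
    stopifnot(length(size_factors) == ncol(counts), all(size_factors > 0))
    size_factors <- stats::setNames(as.numeric(size_factors), colnames(counts))
  }
  structure(list(counts = counts, size_factors = size_factors),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix:", nrow(x$counts), "genes x", ncol(x$counts), "samples;",
      if (is.null(x$size_factors)) "not normalized" else "normalized", "\n")
  invisible(x)
}

#' Normalized (counts / size factor) values of a count matrix
#' @param x a \code{count_matrix}; size factors default to 1 if unset.
#' @return numeric matrix on the common scale.
#' @export
normalized_counts <- function(x) {
  stopifnot(inherits(x, "count_matrix"))
  sf <- x$size_factors
  if (is.null(sf)) sf <- rep(1, ncol(x$counts))
  sweep(x$counts, 2, sf, "/")
}

#' Trio design: sample-to-role mapping for one cross
#'
#' @param hybrid_id identifier of the cross (e.g. "G70xGDH11").
#' @param samples named list with character elements \code{female},
#'   \code{male}, \code{hybrid}; each role needs >= 2 replicates and the
#'   lists must be disjoint.
#' @return an object of class \code{trio_design}.
#' @export
trio_design <- function(hybrid_id, samples) {
  stopifnot(is.list(samples),
            all(c("female", "male", "hybrid") %in% names(samples)))
  if (any(lengths(samples[c("female", "male", "hybrid")]) < 2)) {
    stop("every role needs >= 2 replicate samples")
  }
  all_s <- unlist(samples, use.names = FALSE)
  if (anyDuplicated(all_s)) stop("sample lists must be disjoint")
  structure(list(hybrid_id = hybrid_id, samples = samples),
            class = "trio_design")
}

#' Write / read the pipeline's TSV formats
#'
#' Counts are written as \code{gene_id} plus one column per sample; the
#' design as (sample_id, genotype, role, replicate); annotation as
#' (gene_id, term_id). Readers invert the writers (column order aside).
#'
#' @param x object to write (see details per function).
#' @param path file path.
#' @name heterosis_io
NULL

#' @rdname heterosis_io
#' @export
write_counts_tsv <- function(x, path) {
  stopifnot(inherits(x, "count_matrix"))
  df <- data.frame(gene_id = rownames(x$counts), x$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname heterosis_io
#' @export
read_counts_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$gene_id
  storage.mode(m) <- "integer"
  count_matrix(m)
}

#' @rdname heterosis_io
#' @param design a \code{trio_design}.
#' @export
write_design_tsv <- function(design, path) {
  stopifnot(inherits(design, "trio_design"))
  rows <- do.call(rbind, lapply(c("female", "male", "hybrid"), function(r) {
    s <- design$samples[[r]]
    data.frame(sample_id = s, genotype = design$hybrid_id, role = r,
               replicate = seq_along(s), stringsAsFactors = FALSE)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname heterosis_io
#' @export
read_design_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  trio_design(hybrid_id = df$genotype[1],
              samples = split(df$sample_id, df$role)[c("female", "male", "hybrid")])
}
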