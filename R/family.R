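#' Read a homology-hit table in BLAST tabular layout (outfmt 6)
#'
#' Twelve standard columns: query id, subject id, percent identity,
#' alignment length, mismatches, gap opens, query start/end, subject
#' start/end, E-value, bit score. Coordinates are 1-based inclusive.
#'
#' @param path TSV file without header (standard tabular output), or with a
#'   header naming the columns as below.
#' @return data.frame with the package's column names.
#' @export
read_blast_tab <- function(path) {
  cols <- c("query_id", "subject_id", "percent_identity", "alignment_length",
            "mismatches", "gap_opens", "q_start", "q_end", "s_start", "s_end",
            "evalue", "bit_score")
  first <- readLines(path, n = 1)
  has_header <- grepl("query_id", first, fixed = TRUE)
  df <- utils::read.delim(path, header = has_header, stringsAsFactors = FALSE)
  if (!has_header) {
    if (ncol(df) != 12) stop("expected 12 tabular columns, got ", ncol(df))
    names(df) <- cols
  }
  df
}

#' Filter homology hits by E-value, identity and query coverage
#'
#' Keeps hits with \code{evalue < evalue_max}, \code{percent_identity >
#' identity_min} and query coverage \code{> coverage_min}, where coverage =
#' 100 (q_end - q_start + 1) / q_len. All three inequalities are strict.
#' Idempotent and order-preserving.
#'
#' @param hits data.frame of hits (see \code{\link{read_blast_tab}}).
#' @param q_len named numeric: query lengths; every query in \code{hits}
#'   must be present.
#' @param evalue_max,identity_min,coverage_min stringency thresholds
#'   (defaults 1e-25, 30, 30).
#' @return the surviving hits with a \code{query_coverage} column appended.
#' @export
filter_hits <- function(hits, q_len, evalue_max = 1e-25, identity_min = 30,
                        coverage_min = 30) {
  missing <- setdiff(unique(hits$query_id), names(q_len))
  if (length(missing)) {
    stop("missing query length for: ", paste(missing, collapse = ", "))
  }
  ql <- as.numeric(q_len[hits$query_id])
  hits$query_coverage <- 100 * (hits$q_end - hits$q_start + 1) / ql
  keep <- hits$evalue < evalue_max &
    hits$percent_identity > identity_min &
    hits$query_coverage > coverage_min
  hits[keep, , drop = FALSE]
}

#' Assign filtered hits to gene families
#'
#' Each subject gene is assigned to the family of its best surviving hit:
#' highest bit score, ties broken by lower E-value, then by lexicographic
#' query id. One row per subject, sorted by family then subject.
#'
#' @param hits filtered hit data.frame (see \code{\link{filter_hits}}).
#' @param query_family_map named character (query_id -> family) or a
#'   data.frame with columns query_id, family.
#' @return data.frame: subject_id, family, query_id, bit_score, evalue.
#' @export
assign_families <- function(hits, query_family_map) {
  if (is.data.frame(query_family_map)) {
    query_family_map <- stats::setNames(query_family_map$family,
                                        query_family_map$query_id)
  }
  if (nrow(hits) == 0) {
    return(data.frame(subject_id = character(), family = character(),
                      query_id = character(), bit_score = numeric(),
                      evalue = numeric(), stringsAsFactors = FALSE))
  }
  unmapped <- setdiff(unique(hits$query_id), names(query_family_map))
  if (length(unmapped)) {
    stop("query without family mapping: ", paste(unmapped, collapse = ", "))
  }
  ord <- order(hits$subject_id, -hits$bit_score, hits$evalue, hits$query_id)
  h <- hits[ord, , drop = FALSE]
  best <- h[!duplicated(h$subject_id), , drop = FALSE]
  out <- data.frame(subject_id = best$subject_id,
                    family = unname(query_family_map[best$query_id]),
                    query_id = best$query_id, bit_score = best$bit_score,
                    evalue = best$evalue, stringsAsFactors = FALSE,
                    row.names = NULL)
  out[order(out$family, out$subject_id), , drop = FALSE]
}
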