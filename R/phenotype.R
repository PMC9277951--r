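#' K+ content from a flame-photometer reading
#'
#' Converts an emission-photometry reading of a digest into potassium content
#' as percent of dry sample weight:
#' \deqn{K^+ \% = \frac{C \times V}{G \times 10^6} \times 100}
#' where \code{C} is the K+ concentration of the assay liquid in ppm,
#' \code{V} the liquid volume in mL and \code{G} the dry sample weight in g.
#'
#' @param C K+ concentration (ppm), >= 0. Vectorized.
#' @param V liquid volume (mL), > 0.
#' @param G dry sample weight (g), > 0.
#' @return K+ content in percent of dry weight.
#' @examples
#' k_content_percent(10, 100, 0.5)  # 0.2
#' @export
k_content_percent <- function(C, V, G) {
  if (any(G <= 0)) stop("dry sample weight G must be > 0")
  if (any(V <= 0)) stop("liquid volume V must be > 0")
  if (any(C < 0)) stop("concentration C must be >= 0")
  (C * V) / (G * 1e6) * 100
}

#' Mid-parent heterosis of a hybrid
#'
#' MPH(\%) = 100 (F1 - MP) / MP with MP = (P1 + P2) / 2, where F1, P1 and P2
#' are the replicate means of the hybrid and its parents for one trait at
#' one timepoint. Symmetric in the parents.
#'
#' @param f1,p1,p2 one-row slices of a phenotype table (as produced by
#'   \code{\link{simulate_phenotype}} or \code{\link{read_phenotype_tsv}}),
#'   or plain numeric vectors of replicate values. Rows must agree on
#'   \code{trait} and \code{timepoint}.
#' @return list: hybrid, timepoint, f1_mean, mp, mph_percent.
#' @export
mid_parent_heterosis <- function(f1, p1, p2) {
  pick <- function(x) {
    if (is.numeric(x)) return(list(vals = x, tp = NA, trait = NA, id = NA))
    stopifnot(is.data.frame(x), nrow(x) == 1)
    list(vals = as.numeric(x[grep("^rep", names(x))]),
         tp = x$timepoint, trait = x$trait, id = x$genotype)
  }
  a <- pick(f1); b <- pick(p1); c <- pick(p2)
  metas <- rbind(c(a$tp, b$tp, c$tp), c(a$trait, b$trait, c$trait))
  for (i in 1:2) {
    known <- metas[i, !is.na(metas[i, ])]
    if (length(unique(known)) > 1) {
      stop("timepoint/trait mismatch between F1 and parent records")
    }
  }
  f1_mean <- mean(a$vals)
  mp <- (mean(b$vals) + mean(c$vals)) / 2
  if (mp == 0) stop("mid-parent mean is zero: MPH undefined")
  if (mp < 0) stop("negative mid-parent mean: MPH not interpretable")
  list(hybrid = a$id, timepoint = if (is.na(a$tp[1])) NA else a$tp[1],
       f1_mean = f1_mean, mp = mp,
       mph_percent = 100 * (f1_mean - mp) / mp)
}

#' Mid-parent heterosis for every hybrid x timepoint of a phenotype table
#'
#' @param pheno phenotype data.frame with columns genotype, female_parent,
#'   male_parent, timepoint, trait, rep1..repK; hybrids are rows with
#'   non-empty parent columns.
#' @param trait restrict to one trait (default: all present).
#' @return data.frame: hybrid, timepoint, trait, f1_mean, mp, mph_percent.
#' @export
heterosis_table <- function(pheno, trait = NULL) {
  stopifnot(all(c("genotype", "female_parent", "male_parent",
                  "timepoint", "trait") %in% names(pheno)))
  if (!is.null(trait)) pheno <- pheno[pheno$trait %in% trait, , drop = FALSE]
  hy <- pheno[pheno$female_parent != "" & !is.na(pheno$female_parent), ,
              drop = FALSE]
  out <- lapply(seq_len(nrow(hy)), function(i) {
    r <- hy[i, , drop = FALSE]
    p1 <- pheno[pheno$genotype == r$female_parent &
                  pheno$timepoint == r$timepoint & pheno$trait == r$trait, ,
                drop = FALSE]
    p2 <- pheno[pheno$genotype == r$male_parent &
                  pheno$timepoint == r$timepoint & pheno$trait == r$trait, ,
                drop = FALSE]
    if (nrow(p1) != 1 || nrow(p2) != 1) {
      stop("missing parent record for hybrid '", r$genotype,
           "' at timepoint ", r$timepoint)
    }
    h <- mid_parent_heterosis(r, p1, p2)
    data.frame(hybrid = h$hybrid, timepoint = h$timepoint, trait = r$trait,
               f1_mean = h$f1_mean, mp = h$mp, mph_percent = h$mph_percent,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Screen the strongest and weakest heterosis hybrids at one timepoint
#'
#' @param results data.frame as returned by \code{\link{heterosis_table}}.
#' @param timepoint day to screen at.
#' @return list: strongest (argmax MPH), weakest (argmin MPH); ties broken
#'   by lexicographic hybrid id (the smaller id wins either slot).
#' @export
screen_hybrids <- function(results, timepoint) {
  r <- results[results$timepoint == timepoint, , drop = FALSE]
  if (nrow(r) == 0) stop("no heterosis results at timepoint ", timepoint)
  if (length(unique(r$hybrid)) < 2) {
    stop("need >= 2 hybrids at timepoint ", timepoint)
  }
  r <- r[order(r$hybrid), , drop = FALSE]  # lexicographic tie-break
  list(strongest = r$hybrid[which.max(r$mph_percent)],
       weakest = r$hybrid[which.min(r$mph_percent)])
}

#' One-way ANOVA p-values per timepoint (convenience)
#'
#' Plain one-way ANOVA of trait ~ genotype over replicates, offered as a
#' rough group-difference screen. This is \emph{not} a multiple-range test;
#' post-hoc pairwise separation is out of scope here.
#'
#' @param pheno phenotype data.frame (see \code{\link{heterosis_table}}).
#' @return data.frame: timepoint, trait, p_anova.
#' @export
phenotype_anova <- function(pheno) {
  repcols <- grep("^rep", names(pheno), value = TRUE)
  combos <- unique(pheno[, c("timepoint", "trait")])
  out <- lapply(seq_len(nrow(combos)), function(i) {
    sub <- pheno[pheno$timepoint == combos$timepoint[i] &
                   pheno$trait == combos$trait[i], , drop = FALSE]
    long <- data.frame(
      genotype = rep(sub$genotype, each = length(repcols)),
      value = as.numeric(t(as.matrix(sub[, repcols]))))
    p <- if (length(unique(long$genotype)) < 2) NA_real_ else {
      stats::anova(stats::aov(value ~ genotype, data = long))[["Pr(>F)"]][1]
    }
    data.frame(timepoint = combos$timepoint[i], trait = combos$trait[i],
               p_anova = p)
  })
  do.call(rbind, out)
}

#' @rdname heterosis_io
#' @export
write_phenotype_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname heterosis_io
#' @export
read_phenotype_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c(female_parent = "character",
                                   male_parent = "character"))
}
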