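#!/usr/bin/env Rscript
# Step 6 — 2^-ddCt validation of RNA-seq fold changes.
#
# Picks nine strong DEGs from the strong cross's hybrid-vs-female contrast,
# simulates a Ct table whose noiseless ratios equal the RNA-seq fold
# changes (0.1-cycle technical noise), and measures concordance.

suppressMessages(library(heterosisK))
dir.create("results", showWarnings = FALSE)

hvf <- read_de_tsv("results/02_de_H_H_vs_P1.tsv")
deg <- hvf[hvf$call != "ns", ]
pick <- utils::head(deg[order(deg$p), "gene_id"], 9)
lfc <- stats::setNames(hvf$log2fc[match(pick, hvf$gene_id)], pick)

ct <- simulate_ct_table(lfc, n_reps = 3, noise_sd = 0.1, seed = 601)
ratios <- ddct_table(ct)
utils::write.table(ratios, "results/06_qpcr_ratios.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

conc <- concordance(stats::setNames(ratios$log2_ratio, ratios$gene_id), lfc)
cat(sprintf("qPCR vs RNA-seq over %d genes: sign agreement %.2f, Spearman %.3f\n",
            conc$n_shared, conc$sign_agreement, conc$rank_correlation))
cat("Wrote results/06_qpcr_ratios.tsv\n")
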