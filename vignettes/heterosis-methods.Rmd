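---
title: "Methods: mid-parent heterosis and trio expression-pattern analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mid-parent heterosis and trio expression-pattern analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(heterosisK)
```

## The problem

Heterosis — the superiority of an F1 hybrid over its parents — is screened
phenotypically and then dissected at the transcriptome level by comparing a
hybrid with both of its parents and with an in-silico *mid-parent* that
represents purely additive inheritance. This package implements that whole
chain for a potassium-content phenotype in a hybrid crop: K+ content from
flame-photometer readings, mid-parent heterosis (MPH) per hybrid and
timepoint, trio differential expression, classification of genes into
twelve additive/dominant/overdominant expression patterns, GO
over-representation of the resulting gene sets, homology-based
identification of K+ channel and transporter families, and 2^-ddCt
validation of fold changes. Because the real sequencing data are not
desk-scale reproducible, every stage is exercised on synthetic data with
planted ground truth; the generators are first-class, tested code.

## Phenotype stage

K+ content in percent of dry weight is
$K^+\% = \frac{C \cdot V}{G \cdot 10^6} \cdot 100$
with $C$ the K+ concentration of the assay liquid (ppm), $V$ its volume
(mL) and $G$ the dry sample weight (g). Mid-parent heterosis is
$\mathrm{MPH}(\%) = 100\,(F_1 - \mathrm{MP})/\mathrm{MP}$, with
$\mathrm{MP} = (P_1 + P_2)/2$. Replicates are aggregated by arithmetic
mean *before* the formula; how the original field measurements were pooled
is not documented, and replicate means are the conservative reading. A
zero or negative mid-parent mean raises an error rather than a sign flip —
unreachable for a non-negative trait, but explicit. `screen_hybrids()`
takes the arg-max and arg-min of MPH at a timepoint with a lexicographic
tie-break so results are reproducible under permutation of the input.

Group-difference testing of the phenotype uses plain one-way ANOVA
(`phenotype_anova()`), offered as a convenience; a multiple-range post-hoc
separation of genotype means is deliberately out of scope.

## Trio differential expression

The DE stage is self-contained and documented by its own contract rather
than delegating to an external DE package:

* **Normalization** is median-of-ratios: per sample, the median over
  all-positive genes of the ratio to the gene's geometric mean, rescaled
  so the size factors have geometric mean 1.
* **Virtual mid-parent samples** are built per parent-replicate pair as
  the arithmetic mean of the two parents' normalized counts, rounded
  half-to-even back to integers so the NB machinery sees integer counts.
  Modelling the mid-parent as an explicit sample set (rather than a model
  contrast) keeps the hybrid-vs-midparent comparison structurally
  identical to the other three contrasts.
* **Testing** is per-gene Wald: `log2fc = log2((meanA + 0.5)/(meanB + 0.5))`
  on normalized counts; NB dispersion by method of moments from the pooled
  within-group variance, floored at 1e-8 and shrunk 50% toward a trended
  fit `alpha(mu) = a0 + a1/mu`; the standard error comes from the delta
  method under the NB variance `mu + alpha mu^2`, with the pseudo-count
  entering the variance as well (this keeps the statistic calibrated at
  low counts); two-sided p-values from the normal reference and BH
  adjustment over tested genes. Genes with total raw count below 10 across
  the two groups are reported untested. The normal-reference Wald test was
  chosen over a likelihood-ratio test for transparency; its calibration is
  verified by simulation (all-null type-I rate and KS distance to uniform
  in the test suite) rather than assumed.
* **DEG calling** defaults to raw p <= 0.05 and |log2FC| >= 1. The
  fold-change cut of 1 matches the scale on which the study's DEG counts
  are framed; the stricter cut of 2 that appears in its methods text is
  available through `lfc_min`. Raw p is the default because the reported
  thresholds are phrased as "P"; `use_adjusted = TRUE` switches to BH.

## The twelve expression patterns

For each gene the four calls — hybrid vs female parent, hybrid vs male
parent, hybrid vs mid-parent, parent vs parent — define the pattern:

| pattern | meaning | rule |
|---|---|---|
| P1, P2 | additive | parent calls opposite, mid-parent call ns |
| P3–P6 | dominant | one parent call ns, mid-parent call significant |
| P7–P9 | overdominant, down | both parent calls down; split by parent-vs-parent |
| P10–P12 | overdominant, up | both parent calls up; split by parent-vs-parent |

Genes with both parent calls ns are *unclassified*; every remaining
combination (for example additive-shaped but significantly off the
mid-parent) is *conflicting* and excluded from all proportions. The
mid-parent call is intentionally ignored for P7–P12: transgressive status
is determined by the two parent comparisons alone. The rule table is total
over all 81 call combinations and is checked exhaustively against an
independently written brute-force table.

The headline statistic is the overdominant share of non-additive genes,
(P7–P12)/(P3–P12).

**Classifier call thresholds.** The calls feeding the classifier default
to BH-adjusted p <= 0.05 with *no* fold-change gate, which deliberately
differs from DEG counting, for two structural reasons. First, a dominant
gene whose expression equals one parent sits at most
$\log_2\!\frac{2f}{1+f} < 1$ log2 units from the mid-parent regardless of
the parental fold $f$, so a fold-change gate of 1 on the mid-parent
contrast makes the dominant class unreachable. Second, the four calls are
computed from overlapping sample sets and are therefore positively
correlated; with raw-p calls at 5% a sizeable slice of null genes passes
one parent contrast *and* the mid-parent contrast together and lands in
the dominant class, biasing the overdominant share downward. Adjusted
calls suppress that leakage while the planted effects (2 log2 units)
remain comfortably detectable at three replicates.

## Synthetic data: what it emulates and what it does not

`simulate_trio_counts()` draws counts per gene and replicate from a
negative binomial with variance `mu + mu^2 * dispersion` and plants each
gene in one of the twelve patterns or in the null. Defaults, chosen once
as a realistic bulk RNA-seq scenario for inbred lines and fixed:

* 5000 genes, 3 replicates per role — three replicates is the standard
  minimal design for crop RNA-seq, and 5000 genes keeps every simulation
  in the test suite within seconds while leaving enough genes per pattern
  for stable proportions;
* common dispersion 0.05 — typical biological variability between
  replicates of inbred material (roughly a 22% CV above shot noise);
* baseline means log-uniform on [30, 3000] — the range of moderately to
  highly expressed genes after low-count filtering;
* planted effect 2 log2 units — large enough to be detectable at n = 3
  without making recovery trivial;
* 70% null genes, and the non-null mass split so the planted
  overdominant share of non-additive genes is 0.70 (additive 0.06,
  dominant 0.072, overdominant 0.168).

The phenotype generator produces smooth parental trajectories and plants
the hybrid exactly at `MP * (1 + MPH/100)` before adding Gaussian
replicate noise, so at zero noise the phenotype stage must recover the
planted MPH to machine precision. The replicate-level variability of the
original K+ measurements is not documented anywhere, so `noise_sd` is a
free parameter, not an estimate of the study's error.

Not emulated: read-level artifacts (GC/length bias, mapping ambiguity),
per-gene dispersion heterogeneity, and correlated gene modules. Passing
tests therefore demonstrate the pipeline's statistical behavior under a
clean NB world, not robustness to alignment or batch pathologies.

## Enrichment, families, qPCR

GO over-representation is the one-sided hypergeometric upper tail
(`stats::phyper`) of a set against the whole background, Bonferroni
corrected with m = the number of terms actually tested (terms with at
least one set hit and 2 <= K <= N/2; both bounds configurable). Bonferroni
rather than FDR matches the stated control of the original screen; the
background defaults to all genes of the count matrix present in the
annotation. When an ontology parent map is supplied the annotation is
transitively propagated first.

The family stage filters homology hits with the stringent thresholds
E-value < 1e-25, identity > 30%, query coverage > 30% — all strict
inequalities, as printed. Query coverage is the query alignment span over
query length: the queries are the characterized reference proteins, so
coverage of the known protein is the meaningful quantity. Multiple HSPs
per query-subject pair are not merged; a best single HSP must pass. Each
subject then takes the family of its highest-bit-score surviving hit
(ties: lower E-value, then lexicographic query).

qPCR validation is the textbook 2^-ddCt model: replicate Cts averaged on
the Ct scale, amplification efficiency fixed at 2, and concordance with
RNA-seq reported as sign agreement (near-zero values agree with anything)
plus Spearman correlation.

## Numerical choices and degenerate inputs

* Size factors of an all-zero sample are undefined; the sample is named in
  the error. The geometric-mean reference uses only genes positive in all
  samples.
* Mid-parent rounding is half-to-even (R's `round`), so the virtual counts
  are unbiased integers.
* The dispersion floor of 1e-8 keeps the Wald SE finite for genes whose
  moment estimate collapses to zero at small n.
* Hypergeometric tails are evaluated through `phyper`'s log-space path;
  the test suite checks them against brute-force pmf summation to 1e-12
  relative error for backgrounds up to 200.
* Empty pattern input yields zero counts and an NA overdominant share
  (denominator zero), never a division error.
* All generators restore the caller's RNG state, so library code never
  perturbs a user's random stream.

## Problem sizes in the test suite

The suite simulates what it needs at run time: the null-calibration check
uses 10,000 genes at 3 vs 3 replicates, the sensitivity check 20
repetitions of 400 genes, and the proportion-recovery check 20 seeds of
the 5000-gene default scenario — sizes chosen so the statistical
assertions are stable at the stated tolerances while the whole suite runs
in well under a minute.

## Known limitations

* The NB test is a moment-based Wald approximation, slightly liberal at
  n = 3 (empirical type-I around 0.06 at nominal 0.05); this is measured
  by the suite and acceptable for pattern classification, but inference on
  individual borderline genes should use the adjusted p-values.
* The 12-pattern rule table is this package's normative reading of the
  additive/dominant/overdominant scheme; borderline call combinations are
  surfaced as `conflicting` rather than silently binned.
* A planted-truth simulation cannot validate the biology of any specific
  cross — it validates that the pipeline recovers what was planted under
  its stated noise model.
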