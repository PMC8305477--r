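---
title: "Methods: consensus differential expression, lncRNA classification and RNA-editing discovery"
author: "editscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: consensus differential expression, lncRNA classification and RNA-editing discovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(editscan)
```

# Scope and data model

`editscan` analyses a two-group bulk RNA-seq experiment (a treatment such
as an extremely-low-frequency electromagnetic field exposure versus
untreated controls, typically 3 replicates per group) *after* alignment
and variant calling. Its inputs are a count matrix over transcriptionally
active regions (TARs), a sample-to-group design table, per-sample SNV
calls with allele depths (VCF), a genome (FASTA), a gene annotation
(GFF3) and optional region masks (BED). Internally all coordinates follow
the Bioconductor 1-based closed convention (`GRanges`/`IRanges`); GFF3
shares that convention on disk and BED/VCF are converted on the way in
and out by `rtracklayer`/`VariantAnnotation`.

Three analyses are provided: consensus differential expression, lncRNA
classification with trans-acting correlation, and an RNA-editing
discovery cascade. A synthetic-study generator with recorded ground truth
closes the loop: every claim the test-suite makes about sensitivity or
error control is measured against planted signals.

# Consensus differential expression

Counts are normalised with median-of-ratios size factors (the median over
all-positive TARs of each sample's ratio to the geometric-mean
pseudo-reference). Two self-contained negative-binomial tests are then
run and *intersected*:

* **Wald test.** Per TAR, the pooled within-group moment estimate of the
  NB dispersion is `alpha = max(0, (s^2 - m) / m^2)`; the effect is
  `log2FC = log2((m_B + 0.5) / (m_A + 0.5))` with a 0.5 pseudocount; its
  standard error follows from the delta method applied to the NB variance
  `m + alpha m^2` of each group mean, and the statistic is referred to
  the standard normal, two-sided.
* **Conditional exact test.** Counts are brought to a common effective
  library size and rounded; each group total is modelled as a sum of iid
  negative binomials sharing the moment dispersion. Conditional on the
  grand total, the group-A total has a distribution free of the NB
  probability parameter, and the two-sided p-value sums the probabilities
  of all outcomes no more likely than the one observed (the conditional
  binomial in the Poisson limit).

Each method's p-values are adjusted by Benjamini--Hochberg. A TAR is a
consensus DE call iff **both** methods give adjusted p < 0.05 and
|log2FC| > 1 (strict inequalities, as conventionally printed) *and* the
two fold-change estimates agree in sign. The sign veto is a package
choice: a "DE" call whose two methods disagree about direction is
uninterpretable. The summary splits calls into up/down and by annotated
biotype, reporting the down-regulated percentage to two decimals.

The companion sample-size helper evaluates the closed form
`n = ceil(2 (z_{1-alpha/2} + z_{power})^2 (1/d + v^2) / ln(Delta)^2)`
for mean per-gene coverage `d`, biological CV `v` and target fold change
`Delta`, with defaults `alpha = 0.05`, `power = 0.8` (the study design
convention; the CV for inbred animals is typically taken as 0.1 and the
minimal fold change as 2).

# lncRNA classification

Unannotated ("novel") transcripts are called lncRNA when they are longer
than 200 nt, multi-exonic, and voted non-coding by **all three** of:

* **ORF metrics** — the longest sense-strand ATG..stop ORF; the vote is
  coding at >= 100 codons or >= 50% transcript coverage (conventional
  CPAT-style cutoffs). The ORF length counts the start codon and excludes
  the stop; coverage includes the stop codon. An ORF must terminate at a
  stop codon: open-ended runs to the 3' end do not count, which is the
  stricter reading and is irrelevant for the planted sequences, where
  stops are dense.
* **Fickett TESTCODE** — the classic position-bias/composition statistic
  with the published probability tables and weights; the coding vote
  threshold defaults to 0.95. Sequences must reach 200 nt for the
  statistic to be defined; shorter transcripts get a non-coding vote and
  are excluded by the length rule anyway.
* **Hexamer log-likelihood ratio** — the mean in-frame (stride 3, frame
  0) hexamer log frequency ratio under a model trained on a coding corpus
  (spliced CDS of annotated coding genes) versus a background corpus
  (intergenic windows), with add-one smoothing over all 4096 hexamers;
  positive scores vote coding. Training on annotation-derived corpora
  avoids using any ground-truth label.

Unanimity mirrors the conjunction of multiple published predictors:
non-coding status requires that *no* predictor finds coding potential.
Transcripts already annotated with a lncRNA biotype short-circuit the
cascade.

Trans-acting lncRNA--mRNA links are all pairs whose Pearson correlation
on `log2(count + 1)` profiles reaches `|r| >= 0.9` by default. The
threshold is a configuration knob: published analyses have used both 0.9
and 0.7 for this step, and the package does not resolve that discrepancy —
it surfaces the threshold in the run configuration and report.
Correlations over only six samples are volatile; the pair list is a
screening device, not an inference.

# RNA-editing discovery cascade

Called SNVs pass through ordered stages, each contributing one row to an
audit trail (`n_out` of stage *k* equals `n_in` of stage *k+1*):

1. **Hard filters** (GATK convention, strict inequalities): mean
   per-sample depth < 10, `MQ < 40`, `QD < 2`, `MQRankSum < -12.5` or
   `ReadPosRankSum < -8` remove the site; an absent annotation passes its
   criterion, mirroring variant-caller behaviour for sites where the
   annotation is undefined. "Depth" is read as the mean per-sample DP;
   `dp_rule = "min"` switches to the per-sample minimum.
2. **Genomic context**: sites within 4 nt (configurable) of any
   exon--intron boundary, or inside simple-sequence-repeat, paralog or
   bidirectional-gene masks, are removed. Pseudogene exclusion is served
   through the same mask channel; the package does not detect pseudogenes
   de novo.
3. **Prevalence**: the alternative allele must be observed in at least
   `ceil(0.5 * n_samples)` samples.
4. **SNP / hypervariable AAF**: sites with an rs identifier, or with any
   sample's alternative allele fraction (AAF) strictly above 0.7, are
   removed. "Any sample" is the default reading; the rule can be
   restricted to treated samples.
5. **Differential test**: per site, alt/ref depths are pooled within each
   group into a 2x2 table and tested with the chi-square homogeneity
   statistic (df 1, no continuity correction) — algebraically a
   goodness-of-fit of the observed pooled counts against equal allele
   fractions. Benjamini--Hochberg FDR is computed across all tested
   sites. The effect size dAAF is the difference of *group means of
   per-sample AAFs* (treated minus control) — robust to per-sample depth
   imbalance — while the test uses pooled depths; both are reported.
   Candidates require FDR < 0.001 and |dAAF| > 0.1. A site with zero
   informative depth in a group gets p = 1 and a flag.
6. **Canonical restriction**: on the host gene's sense strand, A-to-I
   editing reads as A->G (so A->G on + hosts, T->C on - hosts) and C-to-U
   as C->T (+) / G->A (-); everything else is non-canonical and dropped.
   Intergenic sites are assessed on the genomic + strand.

The test-then-restrict order follows the bookkeeping of the filtering
narrative this cascade models (significant imbalance first, canonical
annotation second); the FDR is therefore computed across all tested
sites, not only canonical ones.

Surviving candidates are annotated with one consequence per site by
severity: missense > synonymous > 5'UTR > 3'UTR > non-coding exon >
intron > upstream > downstream > intergenic, with CDS variants translated
through the standard genetic code on the coding strand and a 5 kb
upstream/downstream window (the common variant-effect default). The
standard consequence vocabulary has no slot for exonic positions of
non-coding transcripts, so the package adds a `noncoding_exonic`
category rather than mislabelling such sites.

# The synthetic study and what it does (not) show

`simulateStudy()` generates, under one seed, a toy genome (2 chromosomes)
with 30 coding genes, 30 lncRNAs and 3 head-to-head bidirectional pairs;
NB counts for 3 vs 3 samples; and a multi-sample VCF with 50 editing
sites, 200 germline SNPs and 500 noise sites. Defaults encode the study
conditions the package targets:

* counts: baseline means log-uniform in [50, 2000], dispersion 0.01
  (biological CV 0.1, the inbred-animal convention), planted |log2FC| = 2
  on 10% of TARs, per-sample size factors log-uniform in [0.7, 1.4]
  (library-size CV of roughly 0.1);
* editing: per-read editing probability 0.40 (treated) vs 0.05 (control),
  depth Poisson(50), binomial allele counts (a beta-binomial
  overdispersion knob exists to stress the chi-square's assumptions);
* SNPs: per-site AAF class near 0, 0.5 or 1, shared across samples,
  rs-annotated; noise sites draw alternative reads at rate 0.01;
* coding sequence uses a fixed codon-usage bias (one preferred codon per
  amino acid) so the hexamer signal generalises across seeds; lncRNAs
  carry stop codons planted in all three frames at least every 60 nt,
  keeping every ORF short by construction;
* INFO annotations pass the hard filters except at 10% of noise sites,
  where one annotation is drawn failing.

Stage generators are seeded at `seed`, `seed + 1`, `seed + 2`, so the
same configuration yields byte-identical fixture files and stages can be
re-run compositionally.

What passing tests on this generator demonstrate: correct arithmetic of
every filter and statistic, correct strand handling, calibrated error
control under the generative model, and recovery of effects of the
planted size at the planted depth. What they do not demonstrate:
robustness to alignment artefacts, overdispersed or strand-biased allele
counts, annotation errors, or sequence composition of real genomes —
real data violate the binomial/NB assumptions in ways the toy model only
probes via the overdispersion knob.

# Numerical and design choices

* Strict inequalities everywhere a threshold is conventionally printed
  with `<` or `>` (padj < 0.05, |log2FC| > 1, AAF > 0.7, FDR < 0.001,
  |dAAF| > 0.1); boundary values survive.
* Multi-allelic VCF rows are split into biallelic SNVs
  (`VariantAnnotation::expand()`); non-SNV records are skipped and
  counted. Allele-depth fields beyond the chosen alternative are
  discarded.
* AAF is undefined (and excluded from group means) in samples with zero
  informative reads; a site with an entire group uncovered is flagged and
  assigned p = 1 rather than dropped silently.
* The BH step-up is order-preserving with monotonicity enforcement and
  agrees with `p.adjust(method = "BH")` to numerical precision (both are
  exercised against a literal step-up re-computation in the tests).
* The chi-square statistic uses the closed form
  `N (ad - bc)^2 / (r1 r2 c1 c2)` and returns statistic 0 / p 1 for
  degenerate tables.
* Ties in the exact test's outcome probabilities are included in the
  p-value with a `1 + 1e-7` relative tolerance, matching the convention
  of `binom.test`.
* Simulation problem sizes in the test-suite (20-seed averages; 500 TARs
  for null calibration; 1,000 random instances per oracle-equivalence
  check) were chosen as the smallest sizes at which the measured
  proportions are stable to well under the asserted margins.

# Known limitations

* Two groups only; no covariates, no GLM designs, no dispersion
  shrinkage across TARs (each TAR's moment estimate stands alone, which
  is conservative at low replication).
* The editing cascade starts from called variants: it cannot recover
  sites the caller missed, and hyper-edited clustered reads are out of
  scope.
* The hexamer model is first-order (single in-frame hexamer table);
  predictor weights of published coding-potential tools are not
  reproduced — the package re-implements their core features, not their
  fitted models.
* Consequence annotation reports one consequence per site (most severe
  across overlapping transcripts), not per-transcript effects.
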