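---
title: "Candidate-interactome enrichment of GWAS signals: model, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Candidate-interactome enrichment of GWAS signals: model, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(interactomeScan)
```

## The question and the statistic

A candidate interactome is the set of human genes whose protein products
physically and directly interact with an environmental factor — the human
targets of a viral proteome, or the partners of a receptor such as VDR or
AHR. If exposure to that factor matters for a disease, common variation in
its interactome may carry more association signal than expected by chance.
`interactomeScan` tests this with GWAS summary statistics alone (per-SNP
p-values; no genotypes), treating each interactome as one category in an
ALIGATOR-style gene-set test:

1. **SNP-to-gene mapping.** Every SNP within 20 kb of a gene's annotated
   interval (inclusive at exactly 20 kb) is assigned to that gene. A SNP may
   be assigned to several genes; genes with no assigned SNP are *unmappable*
   and drop out of the analysis universe.
2. **Index SNP.** Each gene is represented by its most associated assigned
   SNP (smallest p; ties broken by smaller position, then rsid).
3. **Significance at P-CUT.** A gene is significant when its index p-value is
   strictly below the cutoff (default 0.05; "stronger than" the cutoff).
4. **LD pruning.** Greedy clumping in ascending index-p order: a gene is
   retained only if its index SNP is independent of every retained index SNP,
   where independent means different chromosome, or more than 1000 kb apart,
   or r² ≤ 0.2. This prevents one association peak from being counted through
   several neighbouring genes: the peak is credited to exactly one gene.
5. **Observed count.** The interactome's statistic is the number of its genes
   in the pruned significant-gene list.
6. **Empirical p-value.** The count is compared with `B = 5000` random gene
   sets matched to the interactome's mappable size and drawn from the
   mappable universe, giving the add-one estimator
   `p = (1 + #{count_b ≥ observed}) / (B + 1)` — never exactly 0, and exactly
   1 when the observed count is 0 (which is why a tiny, signal-free set
   prints `1.0000`).
7. **Study-wide level.** A second bootstrap asks how many interactomes would
   reach `alpha_category = 0.05` in a chance study: each simulated study
   elects one replicate count per interactome as pseudo-observed, recomputes
   its empirical p against counts resampled with replacement from the
   remaining replicates, and records the number of significant interactomes;
   `S = 1000` studies give the expected count and a study-wide p. The number
   of resampled counts at or above the pseudo-observed value is
   Binomial(B, tail fraction of the remaining replicates), and the
   implementation draws that binomial directly rather than materialising the
   resamples — the distribution is identical and the cost drops from
   `O(S·B)` to `O(S)` per interactome.

Every analysis is run twice, with and without a user-supplied region mask
(removing, e.g., the extended MHC, whose long-range haplotypes otherwise
dominate the counts). Both runs use the same derived seeds, so a mask that
touches no SNP reproduces the unmasked p-values bit for bit.

## Gene-size bias and weighted sampling

A long or SNP-dense gene contains a sub-threshold SNP far more often than a
short one, so a set of large genes looks enriched under any uniform null.
With `size_weighted = TRUE` (default) replicate sets are drawn sequentially
with probability proportional to each gene's assigned-SNP count — the
gene-level equivalent of sampling random SNPs and keeping their genes.

This correction is exact only in the regime where a gene's chance of being
significant is roughly proportional to its SNP count (small P-CUT or sparse
SNP coverage). When per-gene significance saturates — many SNPs per gene and
a permissive cutoff push most genes' probabilities toward 1 — inclusion
weight and significance probability decouple: weighting still reduces the
size bias (the unweighted null rejects strictly more often on SNP-dense
sets, which the validation experiment below confirms), but no count-based
weighting can fully reproduce the count distribution of an extreme set such
as the densest decile. The default synthetic conditions (1 SNP/kb, ±20 kb
windows, P-CUT 0.05) sit deliberately in this saturated regime, and the
size-bias experiment should be read as a directional, not absolute, check
there.

## Interactome curation

Hand-curated interactomes are built from an interaction-evidence table by
the rule: keep a human gene only if its *physical-direct* records show
either two independent sources (distinct publication/dataset identifiers) or
one source with two distinct experimental approaches (method terms compared
case-insensitively after trimming). Records classed `indirect` or `unknown`
never count — `unknown` is treated as non-direct because the restriction to
physical-direct interactions is the stricter, more defensible reading. The
rule is applied per human gene within one factor's evidence table (not per
interaction pair), which is the natural unit when one table describes one
environmental factor. The rule is monotone (removing evidence can only
shrink the set) and invariant to record order and duplication, and both
properties are tested.

## Tunable parameters

| Parameter | Default | Units | Meaning |
|---|---|---|---|
| `window_bp` | 20000 | bp | SNP-to-gene assignment window, inclusive |
| `pcut` | 0.05 | — | index-SNP significance cutoff, strict |
| `r2_max` | 0.2 | — | r² at or below which two signals are independent |
| `dist_bp` | 1e6 | bp | distance beyond which signals are independent (strict) |
| `n_replicates` | 5000 | sets | random sets per interactome |
| `n_studies` | 1000 | studies | simulated studies for the study-wide level |
| `alpha_category` | 0.05 | — | per-interactome threshold in the study-wide count |
| `size_weighted` | TRUE | — | SNP-count-weighted replicate sampling |

Sensitivity to the (literature-unconstrained) choice of P-CUT is assessed by
re-running the interactomes that reached significance at 0.05 at the harder
cutoffs 0.005 and 0.03 (`sensitivity_scan()`; `all_sets = TRUE` scans
everything).

Seeding: one master seed per run; stage seeds (replicate sampling, simulated
studies) are drawn from it once, and per-interactome seeds are derived as
`(stage_seed + 1000003·k) mod (2³¹ − 1)`, identical across the masked and
unmasked passes so the two are comparable. Identical master seeds give
byte-identical reports.

## What the synthetic generator emulates — and what it does not

`sim_config()` defaults define the package's reference study conditions:
300 genes on 4 chromosomes; log-normal gene lengths (median 20 kb,
sdlog 1.0 — human gene lengths are roughly log-normal with a natural-log SD
near 1, and this spread is what makes size bias worth correcting);
exponential intergenic gaps (mean 20 kb, a compromise that keeps some SNPs
intergenic and unmappable while keeping the simulated genome compact);
SNPs as a uniform Poisson process at 1/kb, so per-gene SNP counts are
Poisson(length × density); LD blocks of 10 consecutive SNPs sharing a latent
Gaussian factor with correlation 0.7 (Gaussian copula; marginals exactly
uniform; the LD table reports r² = 0.49 for within-block pairs); a spiked
30-gene set in which a random 30% of genes have all index-eligible SNPs'
p-values replaced by Beta(0.1, 1) draws; and 12 null decoy sets (13 sets in
all, mirroring a multi-interactome study) with sizes uniform on 10–110.

The generator reproduces the *structure* the method assumes — uniform null
p-values, block LD with exact r² bookkeeping, variable gene length/SNP
density, intergenic SNPs, planted enrichment — but not realistic human LD
decay, allele frequencies, genotype-level effects, or the empirical gene
spacing of a real genome (real intergenic fractions are much larger).
Passing the validation experiments therefore demonstrates internal
correctness and calibration of the statistic under its own assumptions, not
performance on any particular real GWAS.

## Validation experiments and what they show

All experiments are run by `enrichment_validation_run()` (and re-run from
scratch by `scripts/acceptance.R`); problem sizes were chosen so the whole
suite completes in minutes on one CPU: 500 null datasets (B = 500) for
calibration, 500 for the size-bias contrast, 100 spiked runs for power, 10
enumeration configurations at B = 5000, 50 random instances for the
mapping/pruning brute-force oracle.

* **Calibration.** The observed set is drawn by the *same* weighted sampler
  as the replicates — the only construction under which observed and
  replicate counts are exchangeable and the empirical p-value is calibrated
  by design. Because the counting statistic is integer-valued on a small
  support, ties make the add-one estimator conservative: the measured
  rejection rate at 0.05 sits at or slightly below the nominal level.
* **Enumeration oracle.** On a genome of 20 one-SNP genes with no LD and
  uniform weights, the replicate count is exactly hypergeometric; the
  bootstrap p agrees with the exhaustively enumerated tail within Monte
  Carlo error.
* **Mapping oracle.** The full mapping/pruning stage is compared with an
  independent, loop-by-loop brute-force implementation on random instances.
* **Power.** A uniformly drawn spiked set is scored against the weighted
  null. Under the saturated default conditions this experiment has very low
  power, for three compounding reasons quantified during development:
  (a) most genes are already significant at P-CUT 0.05 (each gene's ±20 kb
  window spans ~60 SNPs), so nine spiked genes add little to the count;
  (b) gene-level clumping credits a spiked peak to exactly one gene, and
  when the peak's smallest p lands in a window shared with a neighbour the
  neighbour can absorb it, leaking planted signal out of the set; and
  (c) the weighted null's count distribution stochastically dominates that
  of a uniformly drawn observed set. The experiment is retained as an honest
  description of the method's behaviour in this regime; detecting a
  30-gene spike reliably requires sparser SNP coverage or a stricter P-CUT,
  where per-gene significance probabilities are far from saturation.
* **Size bias.** On the SNP-densest-decile set, unweighted sampling rejects
  strictly more often than weighted sampling — the direction the correction
  must act in — while absolute calibration of an extreme set is not
  achievable by count weighting in the saturated regime (see above).

## Numerical and degenerate-input conventions

Coordinates are 1-based inclusive everywhere internally; BED input is
converted on read, and interval/window/mask bounds are inclusive. Chromosome
labels are normalized (`chr6` → `6`). Empirical p-values use the add-one
estimator. All tie-breaks (index-SNP selection, pruning order) are
deterministic. Invalid input rows are rejected with counted warnings rather
than aborting, mirroring upstream GWAS quality filtering; `strict = TRUE`
upgrades them to errors. An interactome with no mappable genes gets observed
count 0 and p = 1. A cutoff below every SNP p-value empties the pruned list
and yields p = 1 for every set. The packaged
`extdata/interactomes_synthetic.gmt` carries *synthetic* placeholder gene
symbols with the published sizes of the 13 interactomes (e.g. EBV 110,
JCV 10); it exercises the GMT reader and report layout only and encodes no
real interaction data.

## Known limitations

The bootstrap operates on replicate *counts*; the original ALIGATOR tool's
internal resampling is described only loosely in the literature, and the
two-level scheme here (elect one replicate, resample the rest) is this
package's concrete reading of it. LD is an input, not computed from a
reference panel. The curation rule depends on free-text source and method
vocabularies. Real-data p-values from any specific published study are not
reproducible without that study's summary statistics, which are not
distributed here.
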