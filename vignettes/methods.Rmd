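---
title: "Detecting chromosomal drive haplotypes from GBS tag counts: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting chromosomal drive haplotypes from GBS tag counts: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cdhscan)
```

`cdhscan` scores three maize chromosomal drive haplotypes (CDHs) — Ab10,
K10L2 and the B chromosome — in genotyping-by-sequencing (GBS) data, and
models their distribution against genetic background and environment.
This vignette documents the statistical machinery, the assumptions each
stage makes, the parameters that matter, and the places where the design
was genuinely open and a choice had to be made.

## 1. The tag index

GBS yields short tags at restriction-site-adjacent loci. A sample that
carries a multi-megabase haplotype produces tags across it; a non-carrier
produces only scattered mis-mapped reads there. For each 1 Mb bin and
sample the package computes

$$\mathrm{index} = \sqrt{c} + d$$

where $c$ is the number of tags in the bin with nonzero depth in that
sample and $d$ the summed reads-per-million (RPM) depth of those tags.
The two terms capture complementary signals: $c$ saturates quickly and
reflects *breadth* (how much of the bin is covered at all), $d$ reflects
*depth* and keeps growing with copy number. Two conventions are not
forced by the formula and are therefore config-exposed
(`bin_tag_index()`):

* **$d$ sums RPM-normalised depths**, not raw counts. Normalisation to
  RPM happens immediately before the index in the pipeline; summing raw
  counts would make the index track library size.
* **$c$ counts only tags observed in that sample** (`count_mode =
  "present"`). Counting all tags located in the bin would give blanks and
  true negatives identical $c$, erasing the contrast the index exists to
  expose.

Tags are assigned to the bin containing their start coordinate; tags
spanning a boundary are not split. The index is additive in $(c, d)$
across sub-bins, with the square root applied only at final bin
granularity — a property the tests verify against a per-tag oracle.

Filtering precedes binning, in a fixed order: RPM normalisation, then the
blank-derived sample filter, then the mapping-quality tag filter.
**Blanks** (wells with no genomic DNA) measure pure sequencing
background; the sample cutoff is the minimum blank missingness minus
0.001, so any real sample indistinguishable from background is dropped.
Whether missingness should be computed before or after the mapq filter is
not determined by anything in the data model; this implementation
computes it before, and the cutoff can always be supplied explicitly.
Tags need BWA mapping quality ≥ 20 (a tag at exactly 20 is kept). A
sample with zero total reads is an error at normalisation, named
explicitly, rather than a silent NaN.

Min/max scaling is **per bin across samples** (row-wise). This is what
makes presence/absence visually and numerically comparable across
samples; scaling per sample would erase exactly the cross-sample contrast
clustering needs. A constant bin scales to all zeros (not NaN) so
clustering never sees missing values.

## 2. Control-anchored iterative k-means calling

All clustering operates on per-sample vectors of scaled tag index over a
CDH's **diagnostic bins** — bins flagged `diagnostic_for` in the bin
definitions, or selected automatically as bins whose control-group means
differ by ≥ 0.5 (`select_diagnostic_bins()`).

One round: draw `min(n_pos, n_neg)` positive and the same number of
negative controls, add a chunk of experimental samples (at most
`spike_fraction` × the control count; 0.25 for chromosome-10 CDHs, 0.10
for the B), run `stats::kmeans` with k = 2, and name each cluster by its
control members only: a cluster is *positive* (*negative*) when ≥ 80% of
its controls are. A round is valid only when both clusters are named,
differently, and every control sits in the cluster matching its known
status; otherwise the controls are redrawn. k-means details the
presence/absence model does not pin down — Euclidean distance on the
scaled vectors, 10 random initialisations per round, Hartigan–Wong — are
fixed and seeded.

Experimental samples inherit their cluster's label; the loop is organised
so every experimental sample accrues one call per pass until `rounds`
(default 125) calls are recorded. The final call requires ≥ 95% agreement
(`consensus_call()`); everything else is *ambiguous*. Two numerical
guards keep the loop total: a redraw cap of 50 per round (the
presence/absence model implies redrawing could loop forever on signal-free
data), and a no-call fallback — an abandoned round records nothing for its
chunk, the affected samples simply miss that pass and `n_rounds` reports
how many calls each sample actually received. Consensus fractions are
computed over recorded calls, so the degenerate no-signal case terminates
with ambiguous calls rather than hanging.

Two workflow rules reflect what the assays can and cannot see:

* **Chromosome 10 is sequential.** The K10L2 diagnostic region is largely
  contained in Ab10, so the K10L2 assay cannot distinguish the two. Ab10
  is called first; only Ab10-negatives proceed to K10L2; Ab10-positives
  get K10L2 `unknown`. Ab10-ambiguous samples are excluded from the
  K10L2 stage by default (config-switchable): an ambiguous Ab10 sample
  may be an Ab10 carrier, and feeding it to K10L2 would risk a false
  K10L2 positive.
* **The B chromosome is two-stage.** Samples with many B copies are so
  far from everything else that they can form their own cluster and
  invalidate rounds. Stage 1 uses high-copy controls to extract high-copy
  positives; stage 2 re-assays everything not yet positive with low-copy
  controls. A sample is positive if positive at either stage.

Experimental rounds for chromosome-10 CDHs are anchored on **low-copy
(heterozygous) controls** by default: natural carriers are mostly
heterozygous, and homozygous experimental samples still fall nearer the
heterozygous centroid than the negative one. This too is
config-switchable (`copy_class`).

Control validation (`control_validation()`) mirrors calling without
experimental samples: the control panel is split into 3 random subgroups
(each needing ≥ 2 controls of each status; deficient subgroups merge
upward, and a panel too small to split is clustered as one group),
k-means + naming is applied per subgroup, and each control is scored
against its truth over 100 repetitions. High- and low-copy positives are
validated separately so clustering reflects presence/absence rather than
copy number.

## 3. Pseudo copy number and zygosity

Pseudo copy number is the ratio of a sample's mean **unscaled** tag index
over the CDH diagnostic bins to its mean over 1 Mb bins of single-copy
core-gene sequence (`single_copy_gene_bins()` builds bins containing 1 Mb
of *gene* sequence, not genomic coordinates; a trailing partial bin is
kept only when at least half full). Min/max scaling would destroy the
ratio's meaning, so this stage uses the unscaled index. Because numerator
and denominator share the sample's library size and total genomic
content, the ratio is invariant to sequencing depth — the tests multiply
a sample's counts sevenfold and recover the identical estimate — and,
unlike the scaled index, it is robust to carrying other CDHs.

The estimate is deliberately continuous ("pseudo"): absolute calibration
would require controls of known copy number. For chromosome-10 CDHs,
hom/het zygosity is thresholded at the midpoint of the homozygous and
heterozygous control means — the simplest separator consistent with the
controls; with either class missing the answer is `unknown`, never a
guess. A sample whose single-copy mean is zero is flagged `unknown`
rather than raising an error, since one broken sample should not abort a
cohort.

## 4. Ab10 typing

Ab10 occurs as cytological types I/II/III. A 500-tree random forest
(unlimited depth, √p features per split — standard defaults, nothing in
the typing problem suggests otherwise) is trained on the scaled Ab10
diagnostic bins of typed controls with a stratified 70/30 split; holdout
accuracy is reported on the 30%. Typing of new samples uses the vote
fractions: a sample is assigned a type only when ≥ 65% of trees agree
(boundary inclusive), otherwise it is ambiguous. The 65% threshold is
taken as given, not optimised. This conservatism is the point: natural
Ab10 haplotypes recombine, and a mixed signature *should* fail the vote
rule — the tests simulate recombinant-like samples (type I + type II
signal) and assert they come out ambiguous. For exploring that variation,
`gini_pca()` runs a PCA over the `top_k` (default 25) bins ranked by mean
decrease in Gini impurity, keeping the selected bins in genomic order so
that `top_k = all` reproduces the unrestricted PCA exactly.

## 5. Association models

The genotype filters are hard and boundary-exact: calls with depth ≤ 3 or
≥ 20 or genotype quality ≤ 60 become missing; SNPs with minor-allele
frequency < 0.05 or missingness > 75% are dropped (MAF recomputed after
masking); then samples with > 10% missing calls are dropped. A
user-supplied exclusion list — in practice the product of an external
homology/transposable-element screen — is applied verbatim; recomputing
it would require aligners and assemblies outside this package's scope.
Imputation is likewise external: the synthetic genotypes are complete,
and real data should be imputed before entering the package.

Population structure is summarised by PCA on centred dosages
(mean-imputed for the PCA only); the GWAS fits `phenotype ~ dosage +
PC1..PC10` per SNP — logistic for presence/absence, linear for
log-transformed B copy number — and reports the Wald test on the dosage
term, flagged significant at 5×10⁻⁸. Monomorphic SNPs are skipped with a
flag; non-converged or separated fits are flagged, never silently
dropped. Multi-allelic sites are first tested as factors; alternate
alleles with no significant effect are removed and the remaining allele
coded additively (`collapse_multiallelic()`).

Stepwise simplification (`stepwise_glm()`) drops the single worst term
with p > 0.01, refits, and repeats; the fitting engine is `stats::glm`
(IRLS), and the test suite checks it against a hand-rolled IRLS oracle to
six decimals. Term p-values are Wald by default — the plain reading of a
per-variable p-value, multi-df for factors — with a likelihood-ratio
switch (`test = "lrt"`). Tie-breaking is deterministic: largest p first,
then alphabetical; variables are canonically sorted before the first fit,
which is why the surviving term set is invariant to input order
(`check_order_invariance()` re-runs the whole procedure under random
permutations and asserts identity). Only complete cases enter, so the
null model is identical across refits. Deviance explained is
$(D_{null} - D_{res})/D_{null}$; `deviance_partition()` refits one
sub-model per variable class on the same complete-case set, and the
partitions are *not* expected to sum to the full model — variable classes
share variation, and the collinear extreme (each partition ≈ full, sum ≫
full) is part of the test suite. Collinearity screening flags covariate
pairs with |Pearson r| > 0.70 (rank correlation is a defensible
alternative; Pearson is the default here) — advisory only, since the
analyst may keep a collinear variable deliberately.

## 6. What the generator simulates, and what it does not

`simulate_tag_dataset()` draws tag counts from a negative binomial
(variance $\mu + \phi\mu^2$, default dispersion $\phi = 0.3$) — GBS depth
is overdispersed, though no particular count model is canonical — with a
log-normal per-sample library factor (σ = 0.3) and a tag dropout rate of
0.05. Tags in a CDH's diagnostic bins have their mean multiplied by
`dosage_effect × copies` in carriers (default `dosage_effect` 10) and by
a mis-mapping floor of 0.02 in non-carriers — nonzero on purpose, so
scaling and clustering face realistic contrast rather than exact zeros.
Blanks draw from a sparse contaminant model (1% of tags, ~2 reads),
which by construction makes them more missing than any real sample — so
the blank-derived cutoff removes nothing real in simulation.

The simulated reference is a concatenated mapping target: Ab10 (20 Mb,
distal 12 Mb diagnostic, last six bins type-specific two per type), K10L2
(12 Mb, distal 8 Mb diagnostic, with Ab10 carriers also producing signal
there — the property that forces the sequential workflow), the uniquely
mappable portion of the B chromosome (6 Mb), and a 1000 Mb single-copy
backbone. The backbone-to-diagnostic proportions matter more than their
absolute sizes: RPM is compositional, and only when diagnostic regions
are a small share of the tag space — as in the real ~2.1 Gb genome — does
carrying one CDH (say, several B chromosomes) leave the scaled signal of
another CDH usable. An early layout with a 30 Mb backbone made
co-carriers miscallable for exactly this reason; the current proportions
keep the compositional shift within what the clustering tolerates, which
is the realistic regime. The B chromosome's small diagnostic space
likewise reflects that it is mostly repeats. Tag density (50 per Mb) is
arbitrary and configurable; nothing ties it to a real enzyme.

Carrier copy numbers: chromosome-10 controls are het (1) or hom (2); B
controls are low (1) or high (8); experimental B carriers draw 1+Poisson(2)
capped at 14 by default, or uniform 1..14 (`b_copy_dist = "uniform"`) for
dosage-recovery studies. Experimental Ab10 carriers are recombinant-like
(type I + II signature) with probability 0.3.

`simulate_association_dataset()` draws genotypes from a k-population
admixture model (Balding–Nichols divergence, default F = 0.15, Dirichlet
admixture), environment variables correlated with admixture (default 60%
of variance), and a binary phenotype from a logistic model over declared
causal SNPs and environment coefficients.

What passing tests on these data do **not** show: robustness to
enzyme/GC bias (none is simulated, and none is corrected), to batch
differences between sequencing providers, to partial or diverged
haplotypes beyond the mixed type signatures, to genotyping error in the
association module (dosages are exact), or to linkage disequilibrium
(SNPs are drawn independently given ancestry). Real Ab10 diversity is
known to exceed three clean types; the generator's disjoint signatures
are the best case for the typer, which is precisely why its 100% holdout
accuracy on them is a machinery check, not a field claim.

## 7. Problem sizes and reproducibility

Everything is a pure function of configuration plus seed: the pipeline
(`run_full()`) derives per-stage sub-seeds from one master seed, writes
the configuration hash and seed into every output header, and re-running
reproduces outputs byte for byte (asserted in the tests). The test suite
and acceptance script run at desk scale by design: control panels of
20+20 per CDH with 100 validation repetitions; calling with 125 rounds
for the oracle-equivalence check and 20–25 rounds where only the
mechanics are under test; copy-number recovery over 200 samples spanning
0–14 B copies; GWAS calibration on 2000 samples × 1000 SNPs and power
over 50 replicates of a planted OR = 3, MAF 0.3 SNP. These sizes were
chosen as the smallest at which each property is comfortably
identifiable.

## 8. Known limitations

* Calling is always anchored to labelled controls; there is no de novo
  discovery of unknown CDHs, and miscoded controls will poison rounds
  (the redraw rule detects inconsistency only against the labels it is
  given).
* The consensus loop's cost grows linearly in rounds × samples/chunk;
  very large cohorts should raise `spike_fraction`'s denominator (more
  controls) or parallelise across CDHs externally.
* Pseudo copy number is relative; cross-study comparisons require shared
  controls.
* The GWAS uses fixed PC covariates, not a mixed model; close kinship
  beyond broad structure is uncorrected.
* The stepwise procedure inherits the usual caveats of p-value-driven
  selection; the deviance partition is descriptive, not causal.
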