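# cdhscan

Scoring large **chromosomal drive haplotypes** (CDHs) in low-coverage
genotyping-by-sequencing (GBS) data.

Maize carries three prevalent selfish chromosomal elements: **Ab10**
(Abnormal chromosome 10, a female meiotic driver built around knob repeat
arrays and the KINDR/TRKIN kinesins), **K10L2** (a smaller chromosome-10
variant with TR-1 knobs that suppresses Ab10 drive), and the supernumerary
**B chromosome**, which accumulates to 1–14 copies through nondisjunction
at the second pollen mitosis. These multi-megabase haplotypes are invisible
to ordinary SNP genotyping, but GBS read depth over them is highly
informative. `cdhscan` turns GBS tag tables into presence/absence calls,
relative copy-number estimates and Ab10 type assignments, and provides the
downstream association toolkit for relating CDH distribution to genetic
background and environment. A built-in generator simulates every input the
pipeline consumes, so the whole method is testable without sequencing data.

## The method

For each sample and each non-overlapping 1 Mb bin of a CDH reference
haplotype, the **tag index** is

```
index(bin, sample) = sqrt(c) + d
```

where `c` is the number of GBS tags in the bin with nonzero depth in the
sample and `d` is the summed reads-per-million depth of those tags. After
per-bin min/max scaling across samples, carriers and non-carriers separate
sharply over the diagnostic bins. Calling is **control-anchored iterative
k-means**:

1. draw roughly equal numbers of CDH-positive and CDH-negative control
   samples, spike in experimental samples (at most 25% of the control
   count for chromosome-10 CDHs, 10% for the B chromosome);
2. k-means with k = 2; name each cluster positive/negative only if ≥ 80%
   of its control members share that status; redraw controls until every
   control is correctly identified;
3. experimental samples inherit their cluster's label; repeat until every
   sample has 125 recorded calls; a sample keeps its majority label only
   if ≥ 95% of its calls agree, otherwise it is **ambiguous**.

Because the Ab10 pipeline cannot see K10L2 and the K10L2 pipeline cannot
distinguish Ab10 from K10L2, Ab10 is called first and only Ab10-negative
samples are assayed for K10L2. The B chromosome is called in two stages
(high-copy controls first, then low-copy controls on the remainder) so
that very high copy samples do not form their own cluster.

**Pseudo copy number** is the ratio of a sample's mean unscaled tag index
over a CDH's diagnostic bins to its mean over 1 Mb bins of single-copy
core-gene sequence; hom/het zygosity is thresholded at the midpoint of the
homozygous and heterozygous control means. **Ab10 types I/II/III** are
assigned by a 500-tree random forest on the scaled diagnostic bins (70/30
stratified train/holdout; a sample is typed only when ≥ 65% of trees
agree), with a PCA over the top Gini-importance bins for exploring type
variation. The association module provides per-SNP logistic/linear GWAS
with the top 10 principal components of population structure as covariates
(genome-wide threshold 5×10⁻⁸), hard genotype filters (depth > 3 and < 20,
GQ > 60, MAF ≥ 0.05, per-SNP missingness ≤ 75%, per-plant ≤ 10%),
collinearity screening (|r| > 0.70), stepwise GLM simplification at
α = 0.01, and deviance partitioning across population-structure, genetic
and environmental variable classes.

## Worked example

```r
library(cdhscan)

cfg <- sim_config(n_controls_pos = 10, n_controls_neg = 10,
                  n_experimental = 12, seed = 1)
ds  <- simulate_tag_dataset(cfg)
ds$tags
#> <tag_matrix> 51900 tags x 54 samples (raw counts)
#> chromosomes: Ab10, K10L2, B, core

norm   <- rpm_normalize(ds$tags)
cutoff <- blank_missingness_cutoff(norm, ds$manifest)   # 0.9889
filt   <- filter_samples_and_tags(norm, cutoff)
#> removed 2 sample(s) above the missingness cutoff
#> removed 5222 tag(s) below the mapping-quality threshold
scaled <- minmax_scale(bin_tag_index(filt, ds$bins))
scaled
#> <bin_index> 1038 bins x 52 samples (min/max scaled)

calls <- chr10_workflow(scaled, scaled, ds$manifest, rounds = 25, seed = 2)
head(subset(calls, cdh == "Ab10"), 4)
#> # A tibble: 4 x 6
#>   sample_id cdh   call     consensus_fraction n_rounds flag
#> 1 exp_001   Ab10  negative                  1       25 <NA>
#> 2 exp_002   Ab10  negative                  1       25 <NA>
#> 3 exp_003   Ab10  negative                  1       25 <NA>
#> 4 exp_004   Ab10  negative                  1       25 <NA>
```

The two blank wells are removed by the blank-derived missingness cutoff
(they are sequencing background), low-confidence tags go with the mapping
quality filter, and every sample gets a consensus call with its agreement
fraction: here all 25 of 25 rounds agreed, and the two simulated Ab10
carriers among the 12 experimental samples are the two samples called
positive (confusion table below). The `consensus_fraction` column is what
the 95% rule thresholds; `flag` marks samples that never received a valid
round.

```r
truth <- ds$truth
table(call  = calls$call[calls$cdh == "Ab10"],
      truth = truth$ab10_copies[match(calls$sample_id[calls$cdh == "Ab10"],
                                      truth$sample_id)] > 0)
#>           truth
#> call       FALSE TRUE
#>   negative    10    0
#>   positive     0    2
```

Non-carriers sit near zero pseudo copy number
(`pseudo_copy_number(index, index, "B")` gives ~0.02–0.03 for the
experimental non-carriers above), carriers near `dosage_effect × copies`
relative to single-copy genes.

A command-line front end with the same functionality ships in
`inst/cli/cdhscan` (subcommands `simulate`, `tagindex`, `call`,
`copynumber`, `type`, `gwas`, `envmodel`, `run`).

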