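---
title: "Co-expression networks, embedded regulators and contiguous gene clusters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Co-expression networks, embedded regulators and contiguous gene clusters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spearnet)
```

## The problem

Bulk RNA-seq profiled across many cultivation conditions carries enough
signal to infer which genes act together: gene pairs whose expression rises
and falls in concert across conditions are candidates for shared pathways,
shared regulation, or physical clustering on the genome. `spearnet`
implements that inference for condition-series designs of the kind used to
characterise substrate decomposition by wood-degrading basidiomycetes —
a few dozen conditions (different plant substrates, media, time points),
typically in biological duplicate — where the dynamic range of expression
is enormous and distributions are far from Gaussian. Everything downstream
of the raw count matrix is rank-based for exactly that reason.

## Preprocessing model

**Normalization.** Library sizes are removed with the median-of-ratios
estimator: for genes with strictly positive counts in all samples, the
per-gene reference is the geometric mean across samples, and each sample's
size factor is the median over those genes of count/reference
(`median_of_ratios_size_factors()`). Factors are rescaled to geometric
mean 1 so they are identified; this absorbs one global constant, which is
irrelevant to every rank-based statistic downstream. The estimator assumes
the bulk of genes is not differential between samples. Under a
condition-series in which *every* gene responds strongly to condition
(log-scale condition effects with standard deviation around 1.5), part of
the shared condition signal leaks into the factors and recovery of true
library sizes degrades to roughly 10–18% relative error; with
library-size-dominant variation it is about 3% at 2,000 genes. The
size-factor recovery check therefore runs in the estimator's stated
domain (mild condition effects, `condition_sd = 0.2`), and the attenuation
under globally differential data is a documented limitation, not a defect
of the estimator. Dispersion estimation, shrinkage and Wald testing are
deliberately out of scope: nothing here makes differential-expression
claims.

**Replicate averaging.** Normalized counts are averaged within condition
and rounded half away from zero to whole numbers
(`normalize_and_average()`), matching the spreadsheet-style rounding used
when such matrices are distributed. Conditions with a single sample pass
through unaveraged. Rounding is configurable (`round = FALSE`); it has no
visible effect on rank statistics except at very low counts.

**Expression tiers.** A gene is classified relative to a housekeeping
reference — by default actin, beta-tubulin and GAPDH, three stably and
highly expressed genes (`default_housekeeping()`). The reference is the
arithmetic mean of the housekeeping genes *per condition*, not one global
mean: the question asked is "does this gene reach x% of housekeeping in at
least one condition", so per-condition ratios are the natural unit. A
gene's peak ratio is its maximum over conditions of value/reference, and
its tier is the highest threshold it *strictly* exceeds: high (> 50%),
moderate (> 5%), detectable (> 1%), else below. Strict comparison is an
explicit choice (the boundary cases are vanishingly rare on real data) and
the thresholds are configurable (`classification_thresholds()`). Tier
totals are reported both nested (">1% in at least one condition" counts
every gene above the threshold) and disjoint; published totals of this
kind are conventionally the nested counts, and
`classification_summary()` returns both so no reader has to guess.

**Heat-map transform.** `log10_heatmap()` maps values of at least 1 to
`log10(v)` and values below 1 — including silent zeros — to 0, so the
rendering floor is 0 rather than $-\infty$. The colour-scale floor/ceiling
(conventionally 0–10, or 4.5–10 for highly expressed cohorts) are recorded
but never used to clip data.

## Network model

**The statistic.** Co-expression between two genes is the Spearman rank
correlation: average-rank both profiles, take the Pearson correlation of
the ranks (`spearman_rho()`). It is invariant under any strictly
increasing transform of either profile, which makes the choice of
normalization scale immaterial and tames the heavy upper tail of
expression data. Constant profiles (e.g. silent genes) have no defined
rank correlation and are returned as `NA` and excluded from networks —
never coerced to 0.

**Significance.** Raw p-values default to the t approximation
$t = \rho\sqrt{(n-2)/(1-\rho^2)}$ on $n-2$ degrees of freedom, the
standard choice in the R ecosystem at $n$ in the twenties; a permutation
option (`correlation_pvalue(method = "permutation")`) is exhaustive up to
$n = 7$ ($n! \le 5040$ orderings) and seeded Monte-Carlo with the add-one
estimator beyond, for honest inference at tiny $n$ or under heavy ties.
At $|\rho| = 1$ the t statistic degenerates and p = 0 is returned with a
logged note. Multiplicity is controlled with Benjamini–Hochberg q-values
(`bh_adjust()`), and the *family is always exactly the set of pairs
computed in one call*: a 13-gene cohort network adjusts over its 78 pairs,
an all-vs-one scan over its ~14k pairs, a regulator screen over all
candidate × cohort pairs. This per-call scoping matches how such networks
are reported (different networks legitimately use different FDR levels)
and makes every q-value reproducible from the call alone.

**Edge calling.** `pairwise_edges()` retains pairs with `q < alpha` whose
coefficient strictly exceeds the threshold — `rho > rho_threshold` for
positive-only networks, `|rho|` for signed ones; negative edges use the
symmetric cutoff `rho < -rho_threshold` since no separate negative
convention exists. Defaults are `rho > 0.4`, FDR `< 0.05` for small
functional cohorts; genome-wide top-k modules use the far stricter preset
`module_params()` (`rho > 0.86`, FDR `< 1e-6`, k = 10). The FDR level
0.05 is the default; an adjusted-p cutoff of 0.5 occasionally appears in
print for such pipelines and remains reachable through configuration, but
is almost certainly a typo for 0.05 and is not a default here.

**Modules.** `all_vs_one()` computes the full focal-vs-genome edge table;
`top_k_module()` filters by q and threshold first, then ranks by rho —
filter-then-rank, though at module-preset thresholds the two orders
coincide. Ties at the cut break lexicographically by partner ID so module
membership is identical across platforms.

**Embedded regulators.** `regulator_embedding()` scores each candidate
transcription factor by how many cohort genes it connects to with a
significantly positive (putative activator) or significantly negative
(putative repressor) edge, ranking by `max(n_positive, n_negative)`. The
cohort size in the output is the full cohort, so scores read as "21 of
40"-style fractions even when some cohort genes were constant and could
not be tested.

## Contiguous cluster detection

Physically adjacent genes that share a co-expression signature are called
as clusters by a greedy seed-and-extend scan along each chromosome's
positional gene order (`detect_contiguous_clusters()`). The algorithm is
deliberately transparent and fully specified, and makes no claim to
replicate any external clustering tool:

1. **Test family.** On each chromosome, every gene pair within positional
   distance `max_silent_interior + 1` among usable genes is tested
   (Spearman + t p-value) and BH-adjusted once, per chromosome. These are
   exactly the pairs the scan below can ever use as seed or extension
   links, so q-values are fixed before scanning and independent of the
   scan path.
2. **Seeding.** A cluster starts wherever two consecutive genes have
   `rho >= rho_threshold` and `q < alpha`.
3. **Extension.** The next gene joins if its link to the nearest
   qualifying member is significant *and* its median rho against all
   current qualifying members stays at or above the threshold. The median
   (mean available via `extension_stat`) is robust to one outlying
   member; the against-all-members statistic is descriptive and carries
   no additional p-value. Up to `max_silent_interior` consecutive
   non-qualifying genes (default 1) are tolerated inside — silent genes do
   occur inside real co-expressed loci — after which the cluster closes.
4. **Emission.** Silent genes are trimmed from the ends (clusters start
   and end with qualifying members), clusters need at least `min_size`
   (default 3) qualifying members, and overlap is resolved left-to-right
   greedily, so calls are maximal, non-overlapping, deterministic.

Constant-profile genes and genes below `expression_floor` can never
qualify but may sit inside clusters as silent members.
`confirm_cluster_coexpression()` re-tests every member pair within a call
and flags members with no significant edge — the confirmation step that
rejects spurious groupings.

## The synthetic-data generator

`simulate_dataset()` draws a negative-binomial count matrix over a
condition series with known, planted structure, so every pipeline stage
has a ground-truth test surface. Defaults mirror the design the defaults
of the analysis side were meant for: 27 conditions in biological
duplicate, ~3 stable highly expressed housekeeping genes, log-normal
library size factors (SD 0.15), shared NB dispersion 0.1, baseline
log-means uniform on [1, 8] (counts roughly 3–3000) and condition effects
of SD 1.5 on the natural-log scale — a wide dynamic range of the kind seen
across diverse growth substrates. Co-expression is planted through shared
Gaussian latent factors: module members load on one factor (latent
pairwise correlation `loading^2`), regulator targets couple to the
regulator's own trajectory with a signed strength, and contiguous clusters
are modules placed at consecutive gene indices on the synthetic contigs
(500 genes per contig, fixed 2 kb spacing), optionally with silenced
interior members (all-zero counts).

Two calibration facts matter when interpreting recovery tests. First, the
observed Spearman correlation between planted members is *below* the
latent correlation: ranks attenuate Gaussian correlation by the copula map
$\rho_S = (6/\pi)\arcsin(r/2)$, and count noise attenuates further, more
strongly for weakly expressed genes. A loading of 0.982 yields a
population Spearman of 0.90 between members (measured on 600-condition
simulations), and that calibrated value is what the planted-module
recovery tests use; `loading_for_rho()` anchors the latent scale only.
Second, recovery fixtures draw planted-gene baselines from the expressed
range (log-means in [3, 8]): rank correlations on near-zero counts are
information-free, and functional cohorts are by construction expressed
genes.

What the generator does **not** emulate: per-gene dispersion trends, gene
length and GC effects, correlated housekeeping drift, batch structure, or
any real organism's expression profiles. Passing recovery tests therefore
demonstrates that the algorithms detect the structures they claim to
detect at realistic sample sizes and effect sizes — not that any
particular biological catalogue is reproducible.

## Problem sizes used by the test suite

The shipped tests run entirely on simulated data at sizes chosen to make
the statistical properties measurable while keeping the suite quick to
run routinely: FDR control on 50 null datasets of 200 genes × 27
conditions; module recovery over 100 seeded runs at 200 genes; cluster
null rates over 20 genomes of 500 genes; oracle equivalence over 1,000
random profiles; size-factor recovery at 2,000 genes. The
`scripts/acceptance.R` report recomputes the same quantities from scratch
at the same sizes.

## Known limitations

* Median-of-ratios factors partially absorb condition signal when most of
  the transcriptome responds to condition (see above); rank statistics are
  largely insensitive, but absolute normalized values should be read with
  that in mind.
* The t approximation is anti-conservative under heavy ties at small
  `n`; use the permutation method when that matters.
* The cluster scan is greedy: a long weakly linked run can shadow a
  stronger overlapping arrangement, and raising the threshold can in
  principle split one cluster into two. Determinism was preferred over
  global optimisation.
* BH families are per call; merging edge lists from different calls mixes
  incomparable q-values.
* The CLI is a thin wrapper (`spearnet_cli()`, script in `inst/cli/`);
  anything beyond its subcommands is meant to be driven from R.
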