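---
title: "Methods: caste methylome analysis in sparsely methylated genomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: caste methylome analysis in sparsely methylated genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(castemeth)
library(dplyr)
```

## The problem

Social-insect genomes are sparsely methylated: a few tenths of a percent of
CpGs carry methylation, almost exclusively in gene bodies, while every other
site produces a trickle of apparently methylated reads from incomplete
bisulfite conversion (~0.5% of reads). Comparing methylomes between castes
(here: reproductive vs sterile workers, pooled per colony) under these
conditions poses three linked problems this package addresses:

1. separating true methylation from conversion noise (a classification
   problem, not a thresholding one);
2. testing caste differences when intercolony variation dwarfs the caste
   signal (a covariate-adjustment problem);
3. relating the small set of methylated genes to expression differences
   taken from upstream count models (an integration problem).

## Models and procedures

### Conversion error and QC

The unmethylated lambda spike-in estimates the non-conversion rate:
efficiency is `1 - W(lambda)`, with W the weighted (pooled-count)
methylation level. The corrected level of any unit is
`max(0, (p - eps) / (1 - eps))`. Genome-wide summaries pool counts before
correcting: truncating per-site corrected levels at zero and averaging would
inflate the genome-wide level by roughly `eps * P(x = 0)` at this sparsity.

Coverage filtering keeps a site only when, in every sample, coverage lies
between `min_cov` (default 10 reads) and that sample's 99.9th percentile.
The percentile is computed per sample with linear interpolation: coverage
outliers reflect library-specific artifacts (collapsed repeats, mapping
pile-ups), so a pooled cutoff would let a bad library leak through. The
intersection-across-samples rule keeps the tested site universe identical
in all libraries. Filtering is observable: parsers retain zero-coverage rows
so removals happen in exactly one place.

### Methylation-status calling

Counts in one sample are modelled as a two-component mixture: a binomial
error component with success probability `p0` and a methylated component,
beta-binomial by default. `p0` defaults to the lambda estimate and stays
fixed during EM — the spike exists precisely to pin it down, and freeing it
lets the error component drift upward in sparse data (a free-fit switch
exists). The beta-binomial absorbs biological variation in methylation level
among truly methylated sites; a point-binomial variant is available for
data where that variation is negligible.

Fitting is per sample, respecting library-specific error rates, and runs on
the aggregated unique `(x, n)` pairs — at 17x coverage a 50,000-site sample
collapses to a few hundred distinct pairs, so EM converges in milliseconds.
Initialisation: mixture weight = fraction of sites with `x/n > 0.5`
(floored at `1/n_sites`), methylated-component mean 0.8. Convergence when
the log-likelihood improves by `< 1e-6`, capped at 500 iterations with a
warning flag. All-zero input returns a degenerate model with weight 0
rather than an error.

Binary calls use local FDR: sites ranked by posterior membership in the
methylated component; the call set is the largest prefix whose mean
`(1 - posterior)` stays at or below the target (default 0.05). The mean of
an increasing sequence is increasing, so the prefix rule is exact. The
non-discovery rate (mean posterior over uncalled sites) is reported
symmetrically. The "methylated" label is tied to the component with the
larger mean, which makes calls invariant to relabelling the components.

### Differential methylation

Sites unmethylated in all samples carry no information about caste and only
dilute the multiple-testing correction, so testing is restricted to sites
called methylated in at least one sample. Each site is tested by binomial
logistic regression of `(methylated, unmethylated)` counts on caste plus
colony, with a 1-df likelihood-ratio test of the caste term. Colony enters
as fixed covariate levels: with three colonies there is nothing to gain
from shrinking three intercepts, and the fixed-effect fit is exact in small
samples. No overdispersion correction is applied by default; with one
library per caste-colony cell the colony covariate already absorbs the
dominant extra-binomial structure (the null-calibration results below bear
this out).

Degenerate sites — no variation in either direction, separated or
non-converged fits — get `p = 1` with a flag instead of being dropped,
keeping the BH denominator stable. Benjamini–Hochberg q-values are used for
the 5% threshold; the effect threshold is a ≥10% absolute difference of
caste-pooled proportions (sum of methylated reads over sum of total reads
per caste).

Gene calls are deliberately dual-threshold: at least one DM CpG *and* a
≥10% difference in gene-level weighted methylation, where the caste value
is the mean of per-colony W values (one library per colony per caste, so
colonies are the replication unit). Gene-level W uses the full gene span;
exon-level W uses exon intervals. Sites in no feature are reported as
intergenic with the nearest gene within 5000 bp (coordinate distance, both
sides) and never count toward gene calls.

A permutation null for the DM-site count is provided but prints a caveat
unconditionally: with strong colony structure, shuffling caste labels
across colonies breaks the exchangeability the permutation p-value needs.
With six samples the full exchangeable set is only `choose(6,3) = 20`
assignments, so an enumeration mode replaces sampling.

### Integration with expression

Expression levels are compared across weighted-methylation bins — none
(exactly 0), low (>0–0.2], medium (0.2–0.7], high (0.7–1]; boundaries
upper-inclusive — by Kruskal–Wallis plus pairwise Dunn rank contrasts with
BH adjustment. The Dunn Z uses the standard tie-corrected rank-sum variance;
the all-tied degenerate case returns H = 0 by convention. Log expression
uses `log(FPKM + 0.01)`; the offset choice only matters for zero-FPKM genes
and 0.01 sits two decades below typical expressed-gene FPKM.

Per-gene models of expression on methylation fit
`expr ~ W * caste + (1 | colony)` with Satterthwaite inference; a singular
random-intercept fit (likely with only three colonies) falls back to fixed
colony effects with a flag — the fixed-effect targets are unchanged either
way. Gene-set contrasts of weighted methylation (`W ~ group * caste`)
report the nested-model comparison table (interaction vs main effects,
then each main effect) in residual-df/RSS/F form so every F statistic
equals the algebraic identity on raw residuals.

Set overlaps use the upper-tail hypergeometric `P(X >= k)`; the default
universe is the set of genes identified in the expression data, and both
sets must be subsets of it. DE/DEE flags are inputs — differential
expression and exon-usage fitting belong to upstream count-model tools —
and the synthetic expression tables stand in for them during testing.

### Enrichment and orthology

GO enrichment is hypergeometric per term with BH across the terms tested in
one run only; terms annotated to no study gene are not tested, since
zero-overlap rows cannot be enriched and only dilute the correction. No GO
graph propagation is performed. Ortholog pairs are reciprocal best hits
with e-value at most 1e-3 ("minimum e-value" in common BLAST parlance is a
threshold, not a floor), ties broken by bitscore and unresolvable ties
discarded, the reciprocal-and-same-partner rule applied, and any gene still
in more than one pair removed — yielding a strict one-to-one matching.

## What the simulator emulates

`simulate_wgbs()` generates the design the analysis assumes: two castes by
`n_colonies` colonies (default 3), one pooled library per cell, coverage
negative binomial around 17.7 reads (size 8) truncated at one read,
non-conversion 0.45%, methylated-site levels Beta(8, 2). Methylated sites
cluster into genes, mirroring insect gene-body methylation. The colony
effect is a single `Normal(0, 0.5^2)` logit-scale draw per colony, shared
by both of that colony's samples and all methylated sites — this is what
makes samples cluster by colony in PCA and what the colony covariate is
there to absorb. A genome-wide methylation level around 0.2% of CpG
calls — the scale reported for holometabolous insect methylomes —
corresponds to ~0.35% of sites methylated; the default 2% methylated
fraction is the benchmark condition for mixture recovery, and results
always state which of the two conditions they were computed under.

DM sites shift caste levels by `±dm_effect/2` (clipped to [0.01, 0.99];
levels are redrawn so the shift survives clipping, keeping the truth-table
guarantee `|p_r - p_s| >= dm_effect`). The hypermethylated caste is a fair
coin per DM gene — per gene rather than per site so that gene-level truth
is well defined, while direction tests keep a true null. Colony effects of
0.5 on the logit scale translate to roughly ±8 percentage points at a 0.8
level: comparable to the planted 30% caste effect within one colony, which
is exactly the regime where an unadjusted test would fail.

What the simulator does *not* model: read-level artifacts (M-bias,
duplicates, mapping error), spatial correlation of methylation along the
genome, per-individual variation inside a pooled library (an optional
pooling mode averages latent individuals), or a generative link between
methylation and expression unless one is requested
(`simulate_expression(meth_effect = ...)`). Passing recovery tests on this
generator therefore demonstrates the statistical machinery, not robustness
to alignment artifacts.

## Numerical and design choices

- Internal coordinates are 1-based inclusive (the dominant input dialect);
  BED is converted at the boundary. Feature-boundary overlap is inclusive.
- CpGs on opposite strands are independent sites; no dyad merging.
- Tested-site universes stay fixed under BH: degenerate fits return
  `p = 1`, never `NA`.
- Best-hit ties in RBH discard the query (logged); any laxer rule breaks
  the one-to-one guarantee.
- EM is monitored for monotone log-likelihood; the trace is kept on the
  model object and asserted in tests.
- Problem sizes in the test-suite and acceptance benchmarks: 50,000 sites
  for mixture recovery, 5,000 sites for the differential pipeline and its
  10-seed null calibration — sizes at which the binomial asymptotics are
  representative while a full run stays interactive.

## Worked pipeline run

```{r pipeline}
cfg <- sim_config(n_sites = 5000, n_dm_sites = 160, n_dm_genes = 20,
                  dm_effect = 0.30, seed = 1)
sim <- simulate_wgbs(cfg)
eps <- 1 - conversion_efficiency(simulate_lambda(cfg))

qc <- filter_sites(sim$counts)
calls <- bind_rows(lapply(sim$samples$sample_id, function(s) {
  one <- filter(qc$counts, sample_id == s)
  call_status(fit_msc(one, p0 = eps), one)
}))
info <- filter_informative(calls)
res <- dm_sites(qc$counts, sim$samples, sites = info)

site_genes <- filter(annotate_sites(distinct(qc$counts, chrom, pos),
                                    sim$features), feature_type == "gene")
cw <- caste_methylation(weighted_methylation(qc$counts, site_genes),
                        sim$samples)
genes <- dm_genes(res, site_genes, cw)

c(informative = nrow(info), dm_sites = sum(res$is_dm),
  dm_genes = sum(genes$is_dm_gene))
```

```{r recovery}
truth <- sim$truth_genes$gene_id[sim$truth_genes$dm_flag]
called <- genes$gene_id[genes$is_dm_gene]
c(recovered = length(intersect(called, truth)),
  false_positive = length(setdiff(called, truth)))
```

## Known limitations

- The mixture model assumes exchangeable sites within a sample; regional
  methylation structure would be information it ignores.
- With three colonies, the colony covariate costs two residual df per
  site test; power at weak effects is limited by design, not
  implementation.
- Gene-level calls inherit the annotation: unannotated promoters or
  mis-assigned gene spans shift W and can flip marginal calls.
- The hypergeometric overlap p-value is only as meaningful as its
  universe; it must be stated with every result.
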