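---
title: "Models and methods behind spatialith"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind spatialith}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spatialith)
```

# The problem

When a single melanoma metastasis is sectioned and sampled on a grid, the
resulting sub-regions differ in copy-number events, expression programs,
methylation, T-cell repertoires and mutation content. spatialith implements
the analysis stages such a multi-region study needs — copy-number event
calling, gene-set signature scoring, spatial similarity and consensus
clustering, TCR repertoire statistics, multi-omic concordance, and
mutation-based phylogenies — together with a synthetic spatial-tumor
generator that provides full ground truth, because real multi-region
patient data of this kind are access-restricted.

Every user-facing function takes a data frame first and returns a tibble,
so stages chain with the pipe; fitted objects expose `tidy()`/`glance()`
methods and result types have `autoplot()` methods.

# The synthetic tumor generator

`simulate_tumor()` draws one dataset from a fully specified generative
model. Each modality uses its own RNG stream derived from the master seed,
so an identical `sim_config()` reproduces byte-identical output and adding
one modality never perturbs another.

**Geometry.** `n_sections` z-levels, each a `rows x cols` grid of regions
(default 3 sections of 4 x 4 = 48 regions, the scale of a densely sampled
metastasis). Boundary cells of the grid are labeled `margin`, interior
cells `core`. The histologic core/margin call of a real study is a
pathologist's consensus; the boundary rule is the closest synthetic
analogue and is the one deliberate simplification of the geometry.

**Copy number.** Each simulated chromosome is tiled into equal segments.
A configured event (chromosome, gain/loss, log2 magnitude, region subset)
adds its magnitude to every segment of the chromosome in the affected
regions; Gaussian segment noise (sd 0.05 by default, the order of
segmentation jitter in array/WES segment means) is added everywhere. The
default events are one truncal gain plus three spatially localized
subclonal events (a chr7 gain at +0.58 log2, a chr13 gain, a chr10 loss),
so the default tumor has exactly four region "genotypes".

**Expression.** Counts are negative binomial with
`log2(mu) = baseline_g + gamma * cn_g + delta_g * immune_j`. `gamma`
(default 1) is the dosage coupling: one log2 unit of copy number shifts
log2 expression by `gamma`. The immune field `immune_j` is a sum of
`n_immune_pockets` Gaussian bumps placed at random grid positions plus
white noise, rescaled to [0, 1] — discrete hot and cold pockets over a
smooth background. Immune-program genes (10 percent of the universe by
default) respond with `delta = 2`; all other genes ignore the field. A
negative binomial (single shared dispersion, default 0.1) was chosen over
Poisson or log-normal because bulk RNA counts are overdispersed; per-gene
dispersion would add parameters without changing what the downstream
stages can recover. Dispersion below 1e-8 falls back to Poisson, which is
the documented small-dispersion limit.

**Methylation.** Each gene carries 3 probes. For a random half of genes,
`logit(beta) = a_p - 1.5 * log2(count + 1) + noise`, so beta falls as
expression rises; the other half have independent Gaussian logits. The
logistic transform keeps every beta strictly inside (0, 1).

**Mutations.** 15 truncal, 22 intermediate and 16 private mutations by
default (53 total — the sharing spectrum printed for a densely sampled
metastasis). Expected VAF is `0.5 * purity_j * CCF` with binomial read
noise at 100x; local copy number is deliberately ignored in the VAF model,
a documented simplification. Detection power is drawn high (0.9-1) so the
default dataset survives the power filter intact; tests that exercise the
filter plant their own low-power calls.

**TCR repertoires.** A pool of clones with Zipf base abundances
(exponent 1). The top `truncal_clone_count` clones are ubiquitous with
only mild spatial modulation; the rest carry Gaussian spatial bumps (sd
1.5 cells) over the grid, so clones expand locally and most low-abundance
clones are private to a neighbourhood — the qualitative behaviour of
repertoires in sectioned tumors. DNA template counts are multinomial
draws; RNA frequencies are DNA frequencies times per-clone activation
multipliers, renormalized, then multinomially sampled. The defaults plant
two over-active clones (multipliers 4 and 2.5) and one suppressed clone
(0.4).

**What the generator does not emulate**: histology-driven core/margin
irregularity, per-gene dispersion, copy-number-aware VAFs, clone
phylogenies inside the TCR pool, batch effects, and any image-derived
quantity. Passing recovery tests therefore shows the analysis stages are
correct under the stated model, not that they are robust to every artifact
of real data.

# Copy-number event calling

Gene-level values are length-weighted means of overlapping segment log2
ratios (SEG input is 1-based inclusive; overlaps are computed on that
convention). Gene events use an inclusive threshold at 0.6 — a value at
exactly +/-0.6 is an event. Whole-chromosome events use the strict rule:
segments with log2 ratio strictly above 0.3 must cover strictly more than
70 percent of the chromosome length (symmetrically for losses). The two
boundary conventions differ on purpose: each follows the wording of the
rule it implements. "Chromosome length" defaults to the span of that
sample's segments on the chromosome, which avoids shipping an assembly
table; an explicit `chrom_lengths` table overrides it. Uncovered genes are
excluded from the CNA burden count, not imputed.

# Signature scoring

The geometric-mean score of a gene set is the mean of `log2(count + 1)`
over its members — the geometric mean of (count + 1) expressed on the
log2 scale. The pseudocount (default 1, configurable) makes the score
defined at zero counts. Population abundance scores (`marker_abundance()`)
use the same arithmetic but a distinct method tag: they are an explicit
marker-mean stand-in for deconvolution tools, and outputs say so.

`ssgsea_score()` implements the single-sample rank-weighted running-sum
statistic: genes are ranked by expression (descending, ties broken by
gene identifier so scores are deterministic), the in-set ECDF is weighted
by `rank^tau` (tau = 0.25, the cited tool's default), and the score is the
sum of the running difference against the uniform out-of-set ECDF. No
cross-sample normalization is applied; scores are per-sample quantities.

Group comparisons are Welch two-sided t-tests with Benjamini-Hochberg
adjustment across the signatures passed in one call — the call defines
the adjustment family, so users control it. Tertile binning places
boundaries at the 1/3 and 2/3 empirical quantiles with ties assigned to
the lower bin, making an all-equal input all "low" rather than an error.

# Differential expression and over-representation

The DE stage is deliberately simple — per-gene Welch t on log2 counts with
BH adjustment — and is tagged `welch_simplified` in its output: the
pipeline needs a two-group stage to run end to end, and heavy-machinery
count models are out of scope. Empirical-Bayes variance moderation
(shrinkage toward the pooled mean variance, default off, prior df 4) is
available for small groups. `RPL`/`RPS`-prefixed ribosomal genes can be
excluded before testing, and selection thresholds are strict
inequalities on both the fold change and the adjusted p.

Over-representation is the upper-tail hypergeometric test: a list of n
genes containing k members of a K-gene term on an N-gene background
scores `P(X >= k)`. The background defaults to the measured gene universe
and is configurable. Gene ratios `k/n` and background ratios `K/N` are
emitted both numerically and as strings. On a null simulation the test is
slightly conservative (achieved alpha about 0.04 at nominal 0.05 for
GO-sized terms) because the statistic is discrete; this is a property of
the exact test, not an implementation artifact.

# Spatial structure

Similarity between regions is negative Euclidean distance over signature
scores; pairs at or above the 75th percentile of similarity are linked
(ties kept), so the network depends only on distance ranks and is
invariant under any strictly decreasing transform. Margin enrichment is a
two-sided Fisher exact test (point-probability rule) on the
(immune high vs not) x (margin vs core) table; degenerate tables return
p = 1 with a note instead of erroring.

Consensus clustering subsamples 80 percent of samples without replacement
B = 500 times, clusters each subsample hierarchically (1 - Pearson
distance, complete linkage) and cuts at every k from 2 to `kmax` (20).
The consensus of a pair is its co-clustering rate among resamples
containing both. `A(k)` is the area under the empirical CDF of consensus
values, and the delta-area curve `delta(k) = (A(k) - A(k-1)) / A(k-1)`
(with `delta(2) = A(2)`) is usually read by eye; `optimal_k()` makes the
reading deterministic by choosing the largest k with `delta(k) >= 0.1`.
The 0.1 flattening threshold and the 0.8/500 resampling defaults follow
common practice for the method; only `kmax = 20` is inherited from the
study design.

Cluster contiguity uses 4-adjacency within a section plus identical
(x, y) across adjacent sections. Cross-section adjacency is approximate —
each slice is gridded independently in a real study — and is flagged as
such. Singleton clusters are contiguous by convention and flagged.

# TCR repertoire statistics

Clone identity defaults to the nucleotide level, keyed on (CDR3nt, V, J);
amino-acid level is an explicit aggregation. Clonality is
`1 - H / ln(R)` over productive nucleotide-level frequencies (Shannon
entropy, natural log), defined as 1 for a monoclonal repertoire — the
assay vendor's convention. The Morisita overlap defaults to Morisita-Horn
on frequencies (`2 sum(pq) / (sum(p^2) + sum(q^2))`), the repertoire
convention; the classical Morisita index on raw counts is an option.

Activation is the residual of RNA frequency regressed on DNA frequency
over all shared productive clones (with intercept); a positive residual
marks a transcriptionally over-active clone. The regression population
defaults to all shared clones rather than the top 5 because five points
barely constrain a line; a `top_n` option restores the restricted fit. A
log-log option exists because raw frequencies are heavy-tailed and the
largest clones dominate ordinary least squares. This matters for
quantitative recovery: raw-scale residuals scale with clone abundance, so
their rank agreement with planted multipliers is structurally attenuated,
while log-scale residuals approximate `log(multiplier)` directly. The
recovery analyses in the test-suite and acceptance script therefore use
the log-scale fit (and plant multipliers independently of clone abundance,
since multipliers assigned in abundance order are collinear with the
regressor and cannot be attributed by any fit); the raw-scale default is
validated at sign level — an over-active clone shows positive residuals
essentially everywhere it is detected.

# Multi-omic concordance

Probe-level betas collapse to genes by the arithmetic mean. Variable-gene
selection uses the median absolute deviation by default; the
mean-absolute-deviation variant is offered because both statistics appear
under the same "MAD" abbreviation in practice, and ties are broken by gene
identifier. Per-gene Spearman correlations of copy number and methylation
against expression are classified with a |rho| >= 0.3 gate (configurable):
copy number is concordant when positive, methylation when negative;
"mixed" marks genes passing both gates and "undetermined" neither.

Dendrograms use complete linkage with Euclidean (genes) or 1 - Pearson
(samples) distance. Leaf order is made deterministic by placing, at every
merge, the subtree containing the lexicographically smallest member on the
left. Entanglement between two leaf orders is
`sum(|r_A - r_B|^L) / max` with L = 1.5, normalized by the value of an
order against its own reversal, so 0 means identical orders and 1 exact
reversal. An exhaustive branch-flip minimization is available for trees of
at most 12 leaves and is off by default so results stay reproducible
across machines.

# Variant filtering and phylogenetics

The power filter keeps mutations with detection power at or above 0.8 in
every assessed sample (inclusive boundary); the neoantigen-grade variant
filter uses strict inequalities on all five of its conditions
(tumor count > 30, normal count > 10, tumor VAF > 0.05,
normal VAF < 0.01, power > 0.8), and the neoantigen call keeps expressed
(FPKM > 1, RNA alt count > 4) peptides with predicted IC50 < 500 nM —
affinities are consumed as input, no predictor is embedded. The inclusive
vs strict boundary difference between the two power rules is intentional
and documented at both call sites.

Trees are built by standard neighbor joining (Studier-Keppler Q matrix)
on Hamming distances over the binary presence matrix. Ties in Q are
broken by the lexicographically smallest label pair and negative branch
lengths are clamped to zero with a note, so topologies are deterministic.
Bootstrap support resamples mutations (characters, not samples) with
replacement, rebuilds the tree, and reports the percentage of replicates
containing each internal split of the original tree.

# Problem sizes and runtime choices

The test-suite and acceptance script run the generator at 16-48 regions,
40-400 genes and 8-40 clones, consensus clustering at n = 32 samples with
B = 500 resamples, and 20-seed recovery loops; these sizes give stable
recovery statistics while keeping a full run in the low minutes on a
single core. `run_pipeline()` defaults to lighter consensus settings
(B = 200, kmax = 10) for the same reason; both are ordinary arguments.

# Known limitations

The DE stage is a t-test, not a count model; marker-mean scores are not a
deconvolution; the VAF model ignores local copy number; cross-section
adjacency assumes aligned grids; the entanglement search is exhaustive
only for small trees; and the generator's immune field has a free spatial
scale (`pocket_sd`) that no external dataset pins down. Each limitation
is also flagged at the relevant function's documentation.
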