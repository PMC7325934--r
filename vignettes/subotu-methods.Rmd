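---
title: "Methods: sub-OTU community analysis for metal-contaminated soils"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sub-OTU community analysis for metal-contaminated soils}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(subotu)
```

## Scope

`subotu` implements a fine-resolution ("sub-OTU") amplicon community
analysis for soils along a heavy-metal contamination gradient, together with
the accompanying soil-geochemistry statistics. The pipeline runs end to end
on synthetic data generated by the package itself, so every stage is
testable offline: simulate reads, apply read-level quality rules, cluster
dereplicated sequences around abundant seeds, assign rank-aware taxonomy,
normalize and filter feature tables, test differential abundance with a
negative-binomial model, and ordinate communities against geochemistry.

## The sub-OTU clustering model

Conventional OTU clustering at 97% identity merges ecologically distinct
lineages. The sub-OTU approach instead:

1. **Dereplicates** exact sequences, tallying counts per sample; the pool is
   sorted by decreasing total count with lexicographic tie-breaking so every
   downstream step is deterministic.
2. **Designates seeds**: dereplicated sequences with total count $\ge$ 10
   (configurable; applied to the pooled count across samples by default,
   with a per-sample mode behind a flag). Pooling maximizes cross-sample
   comparability of features; the per-sample alternative is available
   because single-sample studies may prefer it.
3. **Merges non-seeds** into their nearest seed when the global alignment
   identity is at least 98%. Ties go to the more abundant seed, then
   lexicographically. Non-seeds below the threshold are retained as
   independent features rather than discarded, so rare divergent lineages
   survive. Assignment is independent per non-seed — an independent
   non-seed never becomes a merge target — matching the two-class
   seed/non-seed design.

Counts are conserved exactly: the feature table's grand total equals the
dereplicated pool's grand total on every run, and the test suite asserts
it.

**Identity metric.** Identity is computed from a Needleman–Wunsch global
alignment with end gaps penalized (match $+1$, mismatch $-1$, gap $-2$ per
column) as matching columns divided by total alignment columns. Because
every alignment column is either an aligned pair or a gap, the column count
equals $L_p + L_s - (\text{matches} + \text{mismatches})$, which lets
identities be extracted from batched alignments without materializing
aligned strings.

**k-mer prefilter.** Aligning every non-seed against every seed is
quadratic, so a conservative k-mer screen (default $k = 8$) skips hopeless
pairs: each of the query's $L_q - k + 1$ k-mer positions is destroyed by at
most $k$ edits, and identity $\ge t$ allows at most
$\lceil (1-t)(L_q + L_s) \rceil$ edits, giving a lower bound on shared
k-mer positions that any passing pair must meet. The bound counts query
positions with multiplicity, so it remains valid for repetitive sequences.
The screen never changes results; the suite asserts byte-identical feature
tables against exhaustive all-pairs assignment on pools of several hundred
sequences.

## Read preparation

Reads are screened in a fixed order: non-nucleotide characters; forward
primer presence at the 5' end within a configurable mismatch budget
(IUPAC-aware; default 2), then stripped; the reverse-complemented reverse
primer stripped from the 3' end *if present* (merged reads need not span
it, so absence does not reject); leading/trailing N runs trimmed with any
internal N rejecting the read; mean per-base error from Phred qualities
above 0.01 rejecting the read (FASTA input skips this check — the original
quality rule belongs to a paired-end merger, which is out of scope, and a
mean-error ceiling preserves its intent on merged reads); and a 150 bp
minimum length after trimming. The per-sample report partitions input
counts exactly across rejection reasons.

**Chimera detection** is a minimal two-parent crossover test rather than a
full scoring heuristic: a sequence is flagged when two candidate parents,
each at least twice as abundant (configurable skew), admit a single
breakpoint with both segments matching their parent at $\ge 0.99$ identity
while no single candidate explains the whole sequence at $> 0.95$. Segment
checks are positional and apply to same-length candidates (amplicons of a
common locus); chimera removal runs after dereplication and before seed
clustering. On simulated data (10% chimera rate, error-free) the detector
flags $\ge 95$% of true chimeras with no false positives; the suite asserts
the weaker bounds of $\ge 80$% sensitivity and $\le 1$% false positives to
leave stochastic headroom.

## Taxonomy assignment

Feature representatives are searched against a lineage-annotated reference
with the same alignment identity. Hits below a 90% floor are discarded; a
feature with no hits is unassigned. The best hit's seven-rank lineage is
walked top-down, stopping before the first unnamed rank (QIIME-style
`g__` empties), and depth is additionally gated by identity: genus requires
$\ge 97$%, species $\ge 99$%. Equal-identity ties collapse to the lowest
common named lineage of the tied hits (the most defensible choice when the
reference cannot distinguish them). The gates are asserted as invariants on
every output; per-sample annotation rates report the percentage of reads in
features assigned at least at the kingdom rank.

## Abundance summaries

Total sum scaling divides each sample by its total (idempotent; columns sum
to 1 within $10^{-9}$). Feature filtering removes features lacking a count
of $\ge 4$ in $\ge 20$% of samples, then the bottom 10% of the remainder by
inter-quartile range of relative abundance; both knobs are configurable and
the removal report is returned alongside the table. Core-microbiome
membership requires relative abundance $\ge 0.01$% in $\ge 20$% of samples
(a stricter 0.2% convention is available via `core_abundance = 0.002`; the
0.01% value is the default because it is the convention the analysis
platform this workflow follows uses at the filtering stage). Chao1 richness
uses the bias-corrected form
$S_{obs} + F_1(F_1 - 1)/(2(F_2 + 1))$, defined even when doubletons are
absent; the classic form is available by flag and falls back to the
corrected one at $F_2 = 0$. Display transforms follow the plotting
conventions: log then per-feature z-score for heatmaps (pseudocount: half
the smallest nonzero relative abundance; zero-variance rows flagged and set
to 0), and pooling of taxa below 1% mean relative abundance into "Other"
for barplots.

## Differential abundance

Counts are modelled as negative binomial with effective library sizes from
trimmed-mean-of-M-values (TMM) normalization (30%/5% trims on M and A,
precision weights, factors rescaled to geometric mean 1; the reference
sample is the one whose upper-quartile count fraction is closest to the
mean). A common dispersion is estimated by method of moments on normalized
counts — per-feature $(\hat v - \hat\mu)/\hat\mu^2$ pooled within groups,
then the median across informative features — and each feature is tested
with a likelihood-ratio test of group means against an intercept-only
model, fitting means by Newton iterations at fixed dispersion, with
p-values from $\chi^2_{k-1}$ and Benjamini–Hochberg adjustment at a 5% FDR.
Log2 fold changes come from group means of normalized counts with a 0.5
pseudocount, reported relative to the reference (first) group level. This
is a deliberately independent implementation with a single common
dispersion — no empirical-Bayes tagwise shrinkage — because the procedure
being reproduced is "GLM plus BH at 0.05", not a particular tool's
numerics.

**Known limitation.** At very small sample sizes (2 groups of 5) the
$\chi^2$ approximation to the LRT is slightly liberal in its extreme tail.
Bulk calibration is good (the rejection rate at $\alpha = 0.05$ under a
complete null sits near 0.05, and the suite asserts it within
$[0.03, 0.07]$), but across hundreds of features the smallest p-values are
more extreme than uniform, so the *realized* false-discovery proportion of
BH under a complete null exceeds its nominal 5% (about 10–12% in our
simulations). This is a property of the NB-LRT/chi-square procedure itself
at these sample sizes, not of this implementation — the reference
negative-binomial GLM machinery in the Bioconductor ecosystem gives the
same rate on identical tables — and the remedies (quasi-likelihood F-tests,
tagwise shrinkage) are outside this package's scope. The acceptance suite
states the nominal-control property honestly and the corresponding check
fails by that margin; interpret small-sample BH lists accordingly.

## Multivariate analysis

Bray–Curtis dissimilarity $d = 1 - 2\sum\min(x_i, x_j)/\sum(x_i + x_j)$
feeds principal coordinates analysis (Gower double-centering and
eigendecomposition). Negative eigenvalues — expected for non-Euclidean
dissimilarities — are dropped with a warning and their count reported; no
Lingoes/Cailliez correction is applied because the plots being emulated are
plain 2-D PCoA. For Euclidean inputs the embedding reproduces input
distances to machine precision. Hierarchical clustering offers
group-average (UPGMA; ultrametric heights equal to average between-cluster
dissimilarity) and Ward linkage in the squared-distance (ward.D2)
convention, chosen because the source tooling's convention is unstated;
dendrograms serialize to newick.

PERMANOVA partitions the total sum of squared dissimilarities and tests the
pseudo-F by label permutation, $p = (1 + \#\{F^* \ge F\})/(1 + n_{perm})$,
with a seed-reproducible permutation stream, no strata, and the permutation
lower bound $p \ge 1/(n_{perm}+1)$. Note that with two very small balanced
groups, permutations that reproduce the observed partition tie with the
observed statistic, so the attainable minimum p-value is slightly above the
bound; with groups of 8 and 999 permutations two well-separated clusters
reach $p = 0.001$.

CCA relates the chi-square-standardized taxon table to environmental
variables by weighted least squares and eigen-analysis of the fitted
matrix, returning site, taxon, and biplot scores in the scaling-2
convention. Environmental variables are log(X+1)-transformed and
standardized first (disableable), below-detection values are imputed at
half the variable minimum and flagged, and constant or collinear
environment columns raise errors (collinearity by condition number).
Constrained eigenvalues are bounded by the corresponding unconstrained
correspondence-analysis eigenvalues and lie in $[0, 1]$; total inertia
equals the table's chi-square statistic over its grand total. These
identities are asserted in the tests.

## Soil geochemistry

The packaged five-site table (`geochem_table()`) records moisture, total
carbon/nitrogen/phosphorus, loss on ignition, extractable NH~4~/NO~3~/PO~4~,
and total and methyl mercury; below-detection entries are the literal
`"b.d."` in the shipped CSV and parse to `NA`. Conventions: ng/g $\equiv$
ppb, so ppm = ng/g / 1000. Pearson correlations use raw values with
pairwise exclusion of below-detection entries; the THg–MeHg correlation
across the five sites is 0.83 and the mean MeHg/THg fraction over the three
low-mercury sites is 2.6%. Contamination binning uses THg cutoffs of 1000
(high) and 100 (medium) ng/g — chosen to reproduce the reported site
classification, since the classification is stated but the cutoffs are
not — with reference status flagged from metadata rather than inferred from
THg. Site and variable dendrograms use log(X+1), Bray–Curtis, and
group-average linkage; on this table the high- and medium-contamination
sites are mutual nearest neighbours, reproducing the reported clustering.

```{r geochem}
g <- geochem_table()
round(pearson_pairs(g, "thg_ng_g", "mehg_ng_g"), 2)
mehg_fraction(g, sites = c("H-02", "S3", "R1"))$mean_pct
bin_and_cluster(g)$bins
```

## The synthetic-data generator

The generator emulates the study design the pipeline targets: a crossed
layout of contamination level (reference/low/medium/high) × generation
(G1–G3) × chamber type (diffusion chamber DC / microbial trap MT), by
default one sample per cell (24 samples, on the order of the 30-sample
design it mirrors). Reference taxa are random 250-base sequences — far
below any clustering threshold pairwise, hence separable by construction —
with nested seven-rank lineages, a fraction of which have unnamed genus or
species to exercise the truncation rule.

Abundances follow a log-normal/Dirichlet hybrid: per-taxon baseline
log-abundances drawn once, shifted by enrichment log-fold-changes that
scale with contamination level and generation (so "metal-enriched" taxa
rise in contaminated, later-generation samples), then softmax-normalized
into Dirichlet means with concentration 50 — enough scatter to be
realistic without drowning the design signal. Reads are the forward primer
(515F/926R and ITS1F/ITS2R ship as presets), the full source amplicon, and
the reverse-complemented reverse primer, with i.i.d. substitutions (default
0.2%/base) and, with probability 1% by default, a single-breakpoint
two-parent chimera whose breakpoint falls in the central 20–80% of the
amplicon and whose parents come from the same sample. Qualities are
constant Q40.

Each operation runs on its own RNG stream derived from the config seed and
restores the caller's RNG state, so identical configs give byte-identical
outputs and no global state leaks.

What the generator does **not** emulate: indels and position-dependent
error profiles, quality-score decay along the read, paired-end structure
(inputs model already-merged reads), taxon-specific amplification bias,
and realistic phylogenetic sequence similarity (taxa are maximally
separated). Passing tests therefore demonstrate the algorithms' correctness
under the stated model, not classifier performance on real, closely related
lineages.

## Problem sizes and numerical choices

The test and acceptance runs use deliberately modest sizes chosen to make
the assertions sharp while keeping the suite quick: 20-taxa simulations
with 4 samples × 500 reads at 0.5% error for clustering recovery; an
8-taxa noiseless run for exact round-trips; NB simulations of 300–1000
features with 5–10 samples per group; 200-seed PERMANOVA null calibration
at 199 permutations. Ties in sorting are always broken deterministically
(count-descending, then lexicographic); identity comparisons use a
$10^{-12}$ tolerance when grouping tied hits; all-zero features test as
$p = 1$ with zero fold change rather than erroring.
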