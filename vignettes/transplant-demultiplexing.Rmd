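---
title: "Demultiplexing donor and recipient cells from transplant scRNA-seq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Demultiplexing donor and recipient cells from transplant scRNA-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(txdemux)
```

## The problem

A droplet scRNA-seq experiment on a transplant sample contains cells of two
genetic individuals: the organ donor and the recipient. Assigning each cell
barcode to its individual of origin — without separately genotyping either —
is possible because cells express germline single nucleotide variants (SNVs):
at an SNV where the two genomes differ, the fraction of a cell's reads
carrying the alternative allele (its *allele fraction*) reflects the cell's
genotype (about 0, 0.5 or 1 for zero, one or two alternative copies).

Transplant samples break the assumptions of pooled-sample demultiplexers in
two ways. First, the two genotypes can be wildly imbalanced — a handful of
recipient immune cells among thousands of donor parenchymal cells, or vice
versa. Second, droplet data carry confounders that blur genotype signal:
cell–cell doublets (one droplet, two cells, possibly one of each genotype)
and ambient RNA (free-floating molecules encapsulated alongside a cell,
importing alleles from other cells' genotypes). `txdemux` implements a
two-stage genotype discovery method designed for exactly this regime,
together with a simulator of such mixtures and a benchmarking layer, so the
whole method is testable end-to-end on synthetic data with known truth.

## Input data

The unit of input is a panel of expressed SNVs with per-cell read counts: a
sites-only VCF, sparse alternative-allele (AD) and total (DP) count matrices
in MatrixMarket format with sites as rows and cells as columns, and a barcode
list — the layout produced by cellSNP-style counting tools. `read_allele_counts()`
validates and bundles these into an `allele_counts` object; only biallelic
SNVs are supported (multi-allelic records are dropped with a warning).

Before fitting, `filter_snvs()` removes sites that cannot help: apparently
homozygous sites (mean minor allele fraction across covered cells above
0.999), sites covered in fewer than 10 cells, and sites with alternative
reads in fewer than 5 cells. The same filter is applied before exporting
input files for other demultiplexers with `export_demux_input()`. We apply
the filter uniformly by default (`demultiplex(..., prefilter = TRUE)`); it
can be disabled when the caller has already filtered.

## The model

Each genotype g is summarised by a per-site allele-fraction profile. Given a
set of cells assigned to g, the profile is the pooled, pseudocount-shrunk
estimate

    af_g(s) = (sum of alt reads at s + c) / (sum of total reads at s + 2c)

with symmetric Beta pseudocount c (default 1). A cell's reads at a site are
modelled as Binomial(total, af) with the allele fraction clamped to
[1e-3, 1 - 1e-3]; the clamp bounds the log-likelihood damage any single
contaminating read (sequencing error, ambient molecule) can inflict. The
doublet profile is derived, not estimated: the mean of the two genotype
profiles weighted by each genotype's mean per-cell coverage at the site —
a doublet is one cell of each genotype, so parent contributions scale with
per-cell depth rather than with group size, which matters when the groups
are imbalanced.

Ambient RNA is deliberately not modelled as a parameter. Because the
genotype profiles are re-estimated from the (contaminated) cells themselves,
contamination shifts the profiles and the cells coherently: a genotype's
profile under r% ambient contamination is approximately
(1 - r) af_g + r af_pool, which is also the expectation of its cells'
observations. Classification therefore remains self-consistent, and
robustness comes from the clamp, the assignment margin and the doublet
calibration below rather than from an explicit ambient estimate.

## Two-stage discovery

**Stage 1 — community clustering.** High-quality cells (covering at least
`min_snvs_per_cell` = 25 sites; others are classified at the end but never
drive discovery) are placed in a k-nearest-neighbour graph (k = 10) under
the allele-fraction distance: the mean absolute difference over sites
covered in *both* cells, defined only when at least `min_shared_sites` = 5
sites are shared. Louvain modularity clustering of this graph yields
communities; the two *core-sized* communities (at least k cells — a smaller
community has a centroid too noisy, and a neighbourhood too small, to anchor
a genotype) whose centroids are farthest apart seed the two candidate
genotype groups, and every other community attaches to its nearer seed.
Small intermediate communities dominated by doublets attach to one side and
are cleaned up during refinement. The candidate split is accepted when the
seed cores are separated by at least `sep_floor` = 0.1 support-weighted mean
absolute allele-fraction difference, and when both merged groups have at
least k cells. On samples above `max_discovery_cells` = 2,000 eligible
cells, discovery runs on a seeded subsample of that size — an O(n²) graph
construction cap; every cell is still scored and classified.

**Stage 2 — rescue of rare genotypes.** When clustering finds one genotype,
a handful of second-genotype cells may still be present — too few to form a
community. Every eligible cell receives a *genotype score*: its mean
per-read binomial log-likelihood under the dominant profile (estimated from
all eligible cells), a depth-normalised consistency measure with per-read
minimum log(1e-3). Cells below `median - 5 × MAD` (MAD with the 1.4826
normal-consistency constant; a degenerate MAD of 0 rescues nothing) are
flagged, and the flagged set is accepted as a candidate second genotype if
its pooled profile differs from the rest by at least `sep_floor`.

**Bisection fallback.** Community detection occasionally fragments on
balanced mixtures under heavy ambient noise into communities too mixed to
seed from, a regime the MAD rescue (built for rare genotypes) cannot serve
either. As a last discovery route the cells are bisected by k-means on
their allele-fraction vectors (uncovered entries imputed with the site
mean). An unconditional k = 2 would happily split a single genotype along a
*pseudo-haplotype* axis — cells grouped by their chance allele draws at
heterozygous sites, a difference that is systematic in the very reads the
clustering saw — so the bisection is validated on held-out data: every
count is binomially thinned into two halves, k-means runs on half A alone,
and the resulting split must show at least `sep_floor` separation on half
B. Phantom axes have no echo in independent reads; genotype axes do. If no
route yields a validated second genotype the sample is reported
single-genotype — the method never force-splits.

## Refinement and doublet calibration

Given an initial partition, the fit alternates hard-assignment steps:
estimate both genotype profiles from currently assigned singlets, derive the
doublet profile, simulate a calibration set of synthetic doublets (each the
summed counts of one random cell from each group, one per observed cell),
classify every eligible cell, and repeat until the labels reach a fixed
point or `max_iter` = 50 sweeps. The tracked objective — the total
best-label log-likelihood over eligible cells — is non-decreasing across
accepted sweeps by construction: a sweep that fails to improve it terminates
refinement, which also guards the corner where pseudocount (Beta-MAP)
estimation deviates from the pure maximum-likelihood monotonicity argument.

Doublet calls are gated by a calibration in a two-feature space: the
doublet-vs-best-singlet log-likelihood difference and the log total read
count. The raw doublet log-likelihood itself scales with depth — synthetic
doublets carry roughly twice a singlet's reads — so the difference is the
statistic that transfers from the calibration set to observed cells, and
depth is the second genuine doublet signature. The doublet class centre is
fitted to the synthetic set (means), the singlet bulk centre to the observed
cells (medians, robust to the true-doublet minority), with a pooled
per-dimension spread: the equal-covariance (linear-discriminant) form is
deliberate, because with class-specific spreads the much wider synthetic
class captures any sufficiently extreme singlet in its far tail. A cell is
called doublet only when this calibrated log-likelihood ratio is positive
and clears the assignment margin.

A singlet call's margin is the GT1-vs-GT2 log-likelihood gap — not the gap
to the doublet profile, which interpolates the genotypes and would
systematically unassign well-identified minor cells under heavy ambient
contamination. Cells whose margin falls below `assign_margin` = 2 nats, or
that cover no site, are `unassigned`.

**Validity of the refined second genotype.** Two gates guard against
refinement stabilising a spurious split. First, the refined minor group
must keep separation of at least `sep_floor` from the major profile and must
*replicate*: split into random halves, each half's per-site allele-fraction
deviation from the major profile is computed, and the support-weighted
correlation (through the origin) of the two deviation vectors must reach
0.5. A genuine genotype deviates identically in both halves; a group
assembled from sampling noise — even one selected for extremeness, which
defeats standard-error corrections — deviates at different sites in each
half. Ambient contamination cancels out of this statistic because it shifts
both halves and the major profile alike. The test needs at least 4 minor
cells and 10 mutually informative sites; below that the separation check
stands alone, which keeps the rescue of very rare genotypes (down to 8
cells) available. Second, a trustworthy fit must assign at least 75% of
eligible cells: a spurious split converges to two near-identical profiles
whose margins leave most cells unassigned. A stage-1 fit failing either gate
is discarded and the stage-2 route is tried; if that also fails, the sample
is reported single-genotype.

## The transplant simulator

`simulate_sample()` and `simulate_grid()` generate two-genotype droplet
mixtures with ground truth. Population allele frequencies are drawn from
Beta(0.8, 0.8) truncated to [0.05, 0.95] (a U-shaped site-frequency shape
typical of expressed SNV panels), and two diploid individuals are drawn
under Hardy–Weinberg equilibrium; a site's true allele fraction is
error, 0.5 or 1 - error for 0/1/2 alternative copies (base error 0.005).
Five percent of sites are genotype-identical "false positive" calls with an
inflated error of 0.05, emulating the elevated false-positive rate of SNV
calling from sparse single-cell reads. Per cell, the number of covered
sites is LogNormal(log 75, sdlog 0.3) truncated to [20, panel size], and
each covered site receives 1 + Poisson(1) reads — the coverage of a
moderately sequenced 10x experiment over a 500-site panel. Doublets are the
summed counts of one cell of each genotype, `round(0.10 × minor count)` of
them (round-half-even), with parents drawn without replacement from
dedicated pools so no barcode is simultaneously a singlet and a doublet
parent. Ambient RNA is simulated at the collapsed-molecule level: every
read unit of every (site, cell) count independently moves, with the ambient
probability, to a uniformly chosen *different* barcode at the same site.
Moving whole molecules (rather than fractions of a molecule's tags) matches
the physical process by which one free-floating molecule ends up in one
droplet; the sample's total molecule count is conserved exactly.

The benchmark grid defaults reproduce a transplant mixing design: 4,000
singlets per sample, minor counts
25, 50, 75, 100, 150, 200, 300, 400, 500, 750, 1,000, 2,000, three
replicates and ambient rates 0–40% — 180 samples. What the generator does
*not* emulate: cell-type structure (coverage heterogeneity enters only
through the per-cell depth distribution, so doublets here always have about
twice a singlet's reads, whereas a real T-cell/epithelial doublet can be
dominated by the larger cell), sequencing-level artefacts upstream of the
count matrices, and linkage between sites. Passing benchmarks on these data
therefore demonstrate correctness of the algorithm under the stated
generative model, not performance on any particular tissue.

## Problem sizes and numerical choices

The packaged benchmarks run at a desk scale of 1,000 cells × 500 SNVs with
the full minor-count range scaled to 25–500 (the grid's 750/1,000/2,000
entries exceed or equal the scaled total and are dropped), and the
25-minor-cell sensitivity experiment at the full 3,975 + 25 composition;
these sizes were fixed as the package's reference configuration for the
acceptance script and test suite. Determinism is a contract: every
stochastic step (discovery subsampling, Louvain, doublet simulation,
simulator draws) is governed by explicit seeds, and identical input plus an
identical seed reproduces a fit byte for byte. Ties in the KNN graph break
toward the lower cell index; community seeding ties break toward the lower
community index; the label-matching tie in benchmarking keeps the identity
permutation. Degenerate inputs are refused loudly: empty matrices, empty
barcode lists, all-filtered panels, and discovery with fewer than 2k
eligible cells are errors, while a cell with no covered site is always
`unassigned`.

## Benchmarking conventions

`tpr_fdr()` scores one-vs-rest confusion per class after `match_labels()`
resolves the arbitrary GT1/GT2 orientation. Unassigned predictions count as
false negatives for the cell's true class and never as false positives —
the conservative reading, chosen because an unassigned cell costs the
analyst a cell but never poisons a genotype's expression profile. The
pooled `"singlet"` class counts a singlet as a true positive only under its
own matched genotype. Undefined ratios are `NA`, never 0. `ari()` is the
standard pair-counting adjusted Rand index. `grid_report()` aggregates
per-grid-cell metrics into means ± sample standard deviations, stratified
at minor count 100 (100 belongs to the low stratum).

## Limitations

Which genotype is the donor is not decided here: labels GT1/GT2 are
anonymous, and orientation must come from cell-type composition or, in
sex-mismatched transplants, X/Y-linked expression. Doublet detection is
intrinsically harder than singlet assignment — under heavy ambient
contamination the calibrated gate deliberately sacrifices doublet recall to
protect singlet precision — and expression-based doublet detectors are a
sensible complement. More than two genotypes are out of scope. The
simulator's parametric assumptions are stated above; real tissue adds
cell-type effects it does not capture.
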