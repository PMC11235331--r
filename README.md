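# txdemux

Donor/recipient demultiplexing of transplant single-cell RNA-seq by
expressed SNVs — without matched germline genotyping.

## The problem

scRNA-seq of a transplant sample (kidney or lung biopsy, bronchoalveolar
lavage) mixes cells of two genetic individuals: the organ donor and the
recipient. Most analyses need each cell barcode assigned to its individual
of origin. Existing genotype demultiplexers assume roughly balanced pools of
genetically distinct samples; transplant samples violate that badly — a
handful of recipient cells among thousands of donor cells is common — and
droplet artefacts (cell–cell doublets, ambient RNA) import the other
genotype's alleles into a cell's reads.

`txdemux` assigns every barcode a label in {GT1, GT2, doublet, unassigned}
from per-cell SNV allele counts alone, using a two-stage discovery method
built for extreme imbalance:

1. **Community clustering** of a k-nearest-neighbour graph over
   allele-fraction distances (mean |AF difference| over mutually covered
   sites) among high-quality cells, with the two farthest core communities
   seeding the genotype groups.
2. **MAD rescue**: when clustering finds one genotype, cells whose *genotype
   score* (mean per-read binomial log-likelihood under the dominant
   profile) falls below `median − 5·MAD` are tested as a rare second
   genotype — sensitive down to a few cells.
3. **Iterative refinement** alternates pseudocount allele-fraction profile
   estimation, `af = (Σalt + c)/(Σtotal + 2c)`, with per-cell binomial
   classification under the GT1/GT2/doublet profiles, simulating synthetic
   doublets each sweep to calibrate the doublet acceptance region. If no
   second genotype validates, the sample is reported single-genotype —
   never force-split.

The package also ships the transplant-mixture simulator used to benchmark
the method (Hardy–Weinberg genotype pairs, sparse per-cell coverage,
parent-summed doublets at 10% of the minor population, collapsed-molecule
ambient RNA swapping) and a benchmarking layer (per-class TPR/FDR against
ground truth, adjusted Rand index, grid aggregation).

## Worked example

Simulate a 1,000-singlet mixture (900 + 100 cells of two genotypes, 10
doublets, 20% ambient contamination) and demultiplex it:

```r
library(txdemux)

sim <- simulate_sample(sim_config(n_total = 1000, seed = 42),
                       minor_count = 100, ambient_rate = 0.2, seed = 42)
fit <- demultiplex(sim$matrix, demux_config(seed = 42))
summary(fit)
#> Two-stage SNV genotype demultiplexing
#>   cells: 1010 (1010 discovery-eligible), sites: 405
#>   second genotype found: TRUE
#>
#>        GT1        GT2    doublet unassigned
#>        901         99         10          0
#>   genotype separation (mean |dAF|): 0.278
#>   refinement: 3 iteration(s), converged = TRUE
#>   final objective (log-likelihood): -47463.1
```

`second genotype found: TRUE` says discovery succeeded; the genotype
separation (mean absolute allele-fraction difference between the two fitted
profiles over mutually supported sites, 0.278 here) quantifies how distinct
the genomes look through this SNV panel. Against the simulator's truth:

```r
table(predicted = fit$labels, truth = sim$truth)
#>             truth
#> predicted    GT1 GT2 doublet
#>   GT1        900   1       0
#>   GT2          0  99       0
#>   doublet      0   0      10
#>   unassigned   0   0       0

tpr_fdr(fit$labels, sim$truth, class = "singlet")
#> class singlet: TP=999 FP=1 FN=1  TPR=0.9990 FDR=0.0010
```

999 of 1,000 true singlets get their correct genotype despite the 9:1
imbalance and 20% ambient contamination, and all 10 doublets are caught.
The fitted model is a regular R object:

```r
round(head(coef(fit), 3), 3)          # per-site AF profiles (rows chrom:pos)
#>        GT1   GT2 doublet
#> 1:10 0.974 0.542   0.803
#> 3:30 0.500 0.500   0.500
#> 4:40 0.014 0.500   0.290
```

`predict(fit, newdata)` classifies new cells on the same SNV panel,
`simulate(fit, ...)` draws synthetic singlets from a fitted profile, and
`plot(fit, counts)` draws the dot-plot validation figure over a compact
panel of genotype-predictive SNVs (`rank_snvs()` + `greedy_cover()`, which
covers every cell at least N = 5 times; the most predictive sites are often
mitochondrial, since MT transcripts dominate many cells' reads):

```r
head(rank_snvs(filter_snvs(sim$matrix), fit)[, c("chrom", "pos", "score")], 3)
#>   chrom  pos     score
#> 1    10 2860 0.1708575
#> 2    16  390 0.1655643
#> 3    MT 1840 0.1602146
```

A thin command-line interface (`exec/txdemux`) exposes the same pipeline as
subcommands: `simulate`, `filter`, `export` (cellSNP/vireo and souporcell
input layouts), `demux`, `dotplot`, `benchmark`.

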