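#' Simulation configuration for synthetic transplant mixtures
#'
#' Describes a two-genotype droplet experiment: a panel of expressed SNVs with
#' population allele frequencies, two diploid individuals drawn under
#' Hardy-Weinberg equilibrium, sparse per-cell site coverage, doublets formed
#' by summing the reads of one cell of each genotype, and ambient RNA
#' simulated by swapping whole collapsed molecules between barcodes.
#'
#' The benchmark grid defaults mirror a transplant mixing experiment: 4,000
#' singlets per sample, minor-genotype counts 25-2,000, three replicates,
#' ambient rates 0-40% and doublets at 10% of the minor population
#' (3 x 12 x 5 = 180 samples).
#'
#' @param n_total total singlet cells per sample.
#' @param minor_count minor-genotype singlets in a single sample (used by
#'   [simulate_sample]; the grid uses `minor_counts`).
#' @param minor_counts minor-genotype counts of the benchmark grid.
#' @param n_replicates grid replicates.
#' @param ambient_rates ambient RNA molecule-swap rates of the grid.
#' @param doublet_rate doublet count as a fraction (default 0.10) of the
#'   population given by `doublet_basis`.
#' @param doublet_basis `"minor"` (default: 10% of the minor genotype
#'   population) or `"total"`.
#' @param n_sites SNV panel size.
#' @param pop_af_shape Beta shape parameters (symmetric pair) of the
#'   population allele-frequency distribution, truncated to `pop_af_range`.
#' @param pop_af_range truncation range for population allele frequencies.
#' @param error_rate per-read base error: homozygous sites have true allele
#'   fraction `error_rate` or `1 - error_rate`.
#' @param fp_snv_fraction fraction of panel sites that are genotype-identical
#'   false-positive SNV calls with inflated error `fp_error`.
#' @param fp_error error rate at false-positive sites.
#' @param mean_sites_per_cell,sites_sdlog,min_sites_per_cell per-cell
#'   covered-site count: LogNormal(log(mean), sdlog) rounded and truncated to
#'   `[min_sites_per_cell, n_sites]`.
#' @param depth_lambda per covered site, total reads = 1 + Poisson(lambda).
#' @param seed master seed; per-sample seeds are derived from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_total = 4000L, minor_count = 100L,
                       minor_counts = c(25L, 50L, 75L, 100L, 150L, 200L, 300L,
                                        400L, 500L, 750L, 1000L, 2000L),
                       n_replicates = 3L,
                       ambient_rates = c(0, 0.1, 0.2, 0.3, 0.4),
                       doublet_rate = 0.10,
                       doublet_basis = c("minor", "total"),
                       n_sites = 500L,
                       pop_af_shape = 0.8, pop_af_range = c(0.05, 0.95),
                       error_rate = 0.005,
                       fp_snv_fraction = 0.05, fp_error = 0.05,
                       mean_sites_per_cell = 75, sites_sdlog = 0.3,
                       min_sites_per_cell = 20L,
                       depth_lambda = 1.0,
                       seed = 1L) {
  doublet_basis <- match.arg(doublet_basis)
  stopifnot(n_total > 0, minor_count >= 0,
            n_replicates > 0, all(ambient_rates >= 0 & ambient_rates <= 1),
            doublet_rate >= 0, doublet_rate <= 1, n_sites >= 1,
            error_rate >= 0, error_rate < 0.5,
            fp_snv_fraction >= 0, fp_snv_fraction <= 1,
            mean_sites_per_cell > 0, min_sites_per_cell >= 1,
            depth_lambda >= 0)
  structure(as.list(environment()), class = "sim_config")
}

#' Draw a pair of diploid genotypes over a synthetic SNV panel
#'
#' Population allele frequencies are Beta-distributed (truncated by
#' rejection), each individual's genotype (0/1/2 alt copies) is drawn under
#' Hardy-Weinberg equilibrium, and a fraction of sites is made
#' genotype-identical with inflated error to mimic false-positive SNV calls.
#' True allele fractions are `error`, `0.5`, `1 - error` for 0/1/2 alt copies.
#'
#' @param n_sites panel size (>= 1).
#' @param seed RNG seed; identical seeds give identical pairs.
#' @param config A [sim_config] supplying the distribution parameters.
#' @return A list of class `genotype_pair`: `sites` (data.frame), `pop_af`,
#'   `gt1`, `gt2` (0/1/2), `true_af1`, `true_af2`, `fp_sites` (logical).
#' @export
draw_genotypes <- function(n_sites, seed = 1L, config = sim_config()) {
  stopifnot(n_sites >= 1)
  with_seed(seed, {
    p <- numeric(0)
    while (length(p) < n_sites) {
      cand <- stats::rbeta(2L * n_sites, config$pop_af_shape, config$pop_af_shape)
      p <- c(p, cand[cand >= config$pop_af_range[1] & cand <= config$pop_af_range[2]])
    }
    p <- p[seq_len(n_sites)]
    hwe_draw <- function() {
      u <- stats::runif(n_sites)
      ifelse(u < (1 - p)^2, 0L, ifelse(u < (1 - p)^2 + 2 * p * (1 - p), 1L, 2L))
    }
    gt1 <- hwe_draw()
    gt2 <- hwe_draw()
    fp <- rep(FALSE, n_sites)
    n_fp <- round(config$fp_snv_fraction * n_sites)
    if (n_fp > 0) fp[sample.int(n_sites, n_fp)] <- TRUE
    gt2[fp] <- gt1[fp]
    af_of <- function(gt, err) ifelse(gt == 0L, err, ifelse(gt == 1L, 0.5, 1 - err))
    err_site <- ifelse(fp, config$fp_error, config$error_rate)
    bases <- c("A", "C", "G", "T")
    ra <- with_seed(seed + 104729L, {
      r <- sample(bases, n_sites, replace = TRUE)
      a <- vapply(r, function(b) sample(setdiff(bases, b), 1), character(1))
      cbind(r, a)
    })
    sites <- data.frame(chrom = as.character(rep_len(c(1:22, "MT"), n_sites)),
                        pos = 10L * seq_len(n_sites),
                        ref = ra[, 1], alt = ra[, 2],
                        stringsAsFactors = FALSE)
    structure(list(sites = sites, pop_af = p, gt1 = gt1, gt2 = gt2,
                   true_af1 = af_of(gt1, err_site),
                   true_af2 = af_of(gt2, err_site),
                   fp_sites = fp),
              class = "genotype_pair")
  })
}

# vectorized singlet generation: n cells of one genotype -> sparse triplets
simulate_singlets <- function(pair, n, genotype, config, seed) {
  if (n == 0L) {
    S <- length(pair$pop_af)
    return(list(alt = Matrix::sparseMatrix(integer(0), integer(0), x = numeric(0),
                                           dims = c(S, 0)),
                total = Matrix::sparseMatrix(integer(0), integer(0), x = numeric(0),
                                             dims = c(S, 0))))
  }
  af <- if (genotype == 1L) pair$true_af1 else pair$true_af2
  S <- length(af)
  with_seed(seed, {
    ncov <- pmin(S, pmax(config$min_sites_per_cell,
                         round(stats::rlnorm(n, log(config$mean_sites_per_cell),
                                             config$sites_sdlog))))
    cell <- rep.int(seq_len(n), ncov)
    site <- unlist(lapply(ncov, function(k) sample.int(S, k)), use.names = FALSE)
    tot <- 1L + stats::rpois(length(site), config$depth_lambda)
    alt <- stats::rbinom(length(site), tot, af[site])
    list(alt = Matrix::sparseMatrix(site, cell, x = alt, dims = c(S, n)),
         total = Matrix::sparseMatrix(site, cell, x = tot, dims = c(S, n)))
  })
}

#' Simulate one singlet cell's allele counts
#'
#' Draws a covered-site set from the depth model, per-site total reads
#' `1 + Poisson(lambda)` and alt reads `Binomial(total, true allele fraction)`
#' for one individual of a [draw_genotypes] pair. Cells with very low drawn
#' coverage are legal; a cell can in principle cover no informative site.
#'
#' @param genotype `1` or `2`: which individual of the pair.
#' @param pair A `genotype_pair` from [draw_genotypes].
#' @param config A [sim_config] (depth model parameters).
#' @param seed RNG seed.
#' @return A data.frame with columns `site` (1-based index), `alt`, `total`
#'   for the covered sites.
#' @export
simulate_singlet <- function(genotype, pair, config = sim_config(), seed = 1L) {
  stopifnot(genotype %in% c(1L, 2L))
  m <- simulate_singlets(pair, 1L, as.integer(genotype), config, seed)
  idx <- Matrix::summary(m$total)
  data.frame(site = idx$i, alt = m$alt[cbind(idx$i, 1L)], total = idx$x)
}

#' Form doublets by summing reads of one cell of each genotype
#'
#' Each doublet is the elementwise sum of the alt and total counts of one GT1
#' parent and one GT2 parent, parents drawn without replacement from dedicated
#' parent pools (so no barcode serves as both a singlet and a doublet parent
#' in an assembled sample). The doublet count is `round(rate * minor_count)`
#' with round-half-even.
#'
#' @param gt1_pool,gt2_pool lists with sparse `alt`/`total` matrices (parent
#'   pools, sites x cells).
#' @param minor_count size of the minor genotype population the rate applies to.
#' @param rate doublet rate (default 0.10).
#' @param seed RNG seed.
#' @return A list with `alt`, `total` (sites x n_doublets) and `parents`
#'   (n_doublets x 2 pool indices).
#' @export
make_doublets <- function(gt1_pool, gt2_pool, minor_count, rate = 0.10,
                          seed = 1L) {
  n1 <- ncol(gt1_pool$total); n2 <- ncol(gt2_pool$total)
  if (!n1 || !n2) stop("parent pools must be non-empty")
  nd <- round(rate * minor_count)
  if (nd > n1 || nd > n2)
    stop(sprintf("requested %d doublets exceeds parent pool size (%d, %d)",
                 nd, n1, n2))
  if (nd == 0L) {
    S <- nrow(gt1_pool$total)
    return(list(alt = Matrix::sparseMatrix(integer(0), integer(0), x = numeric(0),
                                           dims = c(S, 0)),
                total = Matrix::sparseMatrix(integer(0), integer(0), x = numeric(0),
                                             dims = c(S, 0)),
                parents = matrix(integer(0), 0, 2)))
  }
  pick <- with_seed(seed, cbind(sample.int(n1, nd), sample.int(n2, nd)))
  list(alt = gt1_pool$alt[, pick[, 1], drop = FALSE] +
         gt2_pool$alt[, pick[, 2], drop = FALSE],
       total = gt1_pool$total[, pick[, 1], drop = FALSE] +
         gt2_pool$total[, pick[, 2], drop = FALSE],
       parents = pick)
}

#' Simulate ambient RNA by swapping collapsed molecules between barcodes
#'
#' Treats every read unit of every (site, cell) count as one collapsed
#' molecule and independently moves it, with probability `rate`, to a
#' uniformly drawn *different* barcode at the same site. The total molecule
#' count of the sample is conserved exactly and truth labels are unchanged;
#' moving whole molecules (rather than individual read tags) matches the
#' ambient RNA generating process, where all tags of one molecule end up in a
#' single droplet.
#'
#' @param x An [allele_counts] object (or a `sim_sample`, whose matrix is
#'   modified in place with the ambient rate recorded in its provenance).
#' @param rate swap probability per molecule, in `[0, 1]`.
#' @param seed RNG seed.
#' @return The contaminated object, same class as the input.
#' @export
add_ambient <- function(x, rate, seed = 1L) {
  stopifnot(rate >= 0, rate <= 1)
  if (inherits(x, "sim_sample")) {
    x$matrix <- add_ambient(x$matrix, rate, seed)
    x$provenance$ambient_rate <- rate
    return(x)
  }
  if (rate == 0) return(x)
  B <- length(x$barcodes)
  if (B < 2L) return(x)
  idx <- Matrix::summary(x$total)
  if (!nrow(idx)) return(x)
  a <- x$alt[cbind(idx$i, idx$j)]
  tot <- as.integer(idx$x)
  site <- rep.int(idx$i, tot)
  bc <- rep.int(idx$j, tot)
  is_alt <- sequence(tot) <= rep.int(a, tot)
  with_seed(seed, {
    swap <- stats::runif(length(site)) < rate
    if (any(swap)) {
      r <- sample.int(B - 1L, sum(swap), replace = TRUE)
      bc[swap] <- r + (r >= bc[swap])      # uniform over the other barcodes
    }
  })
  total <- Matrix::sparseMatrix(site, bc, x = 1, dims = dim(x$total))
  alt <- Matrix::sparseMatrix(site[is_alt], bc[is_alt], x = 1,
                              dims = dim(x$alt))
  out <- x
  out$alt <- as_count_matrix(alt)
  out$total <- as_count_matrix(total)
  out
}

#' Simulate one transplant mixture sample with ground truth
#'
#' Assembles `n_total - minor_count` GT1 singlets, `minor_count` GT2 singlets
#' and `round(doublet_rate * minor_count)` doublets (parents simulated
#' separately so no singlet barcode is reused), then applies ambient
#' contamination at `ambient_rate`.
#'
#' @param config A [sim_config]; `minor_count`, `n_total`, `doublet_rate` and
#'   `seed` are taken from it unless overridden.
#' @param minor_count,ambient_rate,seed optional overrides.
#' @param replicate replicate id recorded in provenance.
#' @param pair optional pre-drawn `genotype_pair` (drawn from `seed` if NULL).
#' @return A list of class `sim_sample`: `matrix` ([allele_counts]), `truth`
#'   (factor per barcode: GT1/GT2/doublet) and `provenance`.
#' @export
simulate_sample <- function(config = sim_config(),
                            minor_count = config$minor_count,
                            ambient_rate = 0, seed = config$seed,
                            replicate = 1L, pair = NULL) {
  stopifnot(minor_count >= 0, minor_count < config$n_total)
  if (is.null(pair)) pair <- draw_genotypes(config$n_sites, seed, config)
  n2 <- as.integer(minor_count)
  n1 <- config$n_total - n2
  basis <- if (config$doublet_basis == "minor") minor_count else config$n_total
  nd <- if (n2 == 0L) 0L else round(config$doublet_rate * basis)

  s1 <- simulate_singlets(pair, n1, 1L, config, seed + 1L)
  s2 <- simulate_singlets(pair, n2, 2L, config, seed + 2L)
  p1 <- simulate_singlets(pair, nd, 1L, config, seed + 3L)
  p2 <- simulate_singlets(pair, nd, 2L, config, seed + 4L)
  dbl <- if (nd > 0) make_doublets(p1, p2, basis, config$doublet_rate, seed + 5L)
         else make_doublets_empty(config$n_sites)

  alt <- cbind(s1$alt, s2$alt, dbl$alt)
  total <- cbind(s1$total, s2$total, dbl$total)
  n_all <- n1 + n2 + ncol(dbl$total)
  barcodes <- sprintf("BC%06d-1", seq_len(n_all))
  truth <- factor(rep(c("GT1", "GT2", "doublet"), c(n1, n2, ncol(dbl$total))),
                  levels = c("GT1", "GT2", "doublet"))
  m <- allele_counts(pair$sites, barcodes, alt, total)
  out <- structure(list(matrix = m,
                        truth = stats::setNames(truth, barcodes),
                        pair = pair,
                        provenance = list(replicate = as.integer(replicate),
                                          minor_count = n2,
                                          n_total = config$n_total,
                                          n_doublets = ncol(dbl$total),
                                          ambient_rate = 0,
                                          seed = as.integer(seed))),
                   class = "sim_sample")
  if (ambient_rate > 0) out <- add_ambient(out, ambient_rate, seed + 6L)
  out
}

make_doublets_empty <- function(S) {
  list(alt = Matrix::sparseMatrix(integer(0), integer(0), x = numeric(0),
                                  dims = c(S, 0)),
       total = Matrix::sparseMatrix(integer(0), integer(0), x = numeric(0),
                                    dims = c(S, 0)),
       parents = matrix(integer(0), 0, 2))
}

#' @export
print.sim_sample <- function(x, ...) {
  p <- x$provenance
  cat(sprintf("sim_sample: %d GT1 + %d GT2 singlets + %d doublets, ambient %.0f%% (replicate %d, seed %d)\n",
              p$n_total - p$minor_count, p$minor_count, p$n_doublets,
              100 * p$ambient_rate, p$replicate, p$seed))
  print(x$matrix)
  invisible(x)
}

#' Enumerate the simulation grid
#'
#' One row per (replicate x minor count x ambient rate) combination, with the
#' deterministically derived per-sample seed. With the default configuration
#' this is 3 x 12 x 5 = 180 samples.
#'
#' @param config A [sim_config].
#' @return A data.frame with columns `replicate`, `minor_count`,
#'   `ambient_rate`, `seed`.
#' @export
grid_layout <- function(config = sim_config()) {
  if (!all(config$minor_counts < config$n_total))
    stop("every grid minor_count must be below n_total")
  g <- expand.grid(ambient_rate = config$ambient_rates,
                   minor_count = config$minor_counts,
                   replicate = seq_len(config$n_replicates),
                   KEEP.OUT.ATTRS = FALSE)
  g <- g[, c("replicate", "minor_count", "ambient_rate")]
  g$seed <- with_seed(config$seed, sample.int(.Machine$integer.max, nrow(g)))
  rownames(g) <- NULL
  g
}

#' Materialise (and optionally process) the simulation grid
#'
#' Generates one [simulate_sample] per grid row. To keep memory bounded on
#' large grids, a function can be applied to each sample as it is produced,
#' in which case only its results are retained.
#'
#' @param config A [sim_config].
#' @param FUN optional function of (`sample`, `row`) applied to each generated
#'   sample; default returns the samples themselves.
#' @param layout optional precomputed [grid_layout] (or a subset of its rows).
#' @return A list with one element per grid row, named
#'   `rep<r>_minor<m>_amb<a>`.
#' @export
simulate_grid <- function(config = sim_config(), FUN = NULL,
                          layout = grid_layout(config)) {
  out <- vector("list", nrow(layout))
  names(out) <- sprintf("rep%d_minor%d_amb%g", layout$replicate,
                        layout$minor_count, layout$ambient_rate)
  for (k in seq_len(nrow(layout))) {
    row <- layout[k, ]
    s <- simulate_sample(config, minor_count = row$minor_count,
                         ambient_rate = row$ambient_rate,
                         seed = row$seed, replicate = row$replicate)
    out[[k]] <- if (is.null(FUN)) s else FUN(s, row)
  }
  out
}

#' Write a simulated sample to disk
#'
#' Emits the cellSNP-style allele-count files plus `truth.tsv`
#' (barcode, label) and `provenance.json`.
#'
#' @param sample A `sim_sample`.
#' @param out_dir output directory.
#' @return Invisibly, the output directory.
#' @export
write_sim_sample <- function(sample, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_allele_counts(sample$matrix, out_dir)
  utils::write.table(data.frame(barcode = names(sample$truth),
                                label = as.character(sample$truth)),
                     file.path(out_dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(sample$provenance,
                       file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
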