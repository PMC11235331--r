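#' Demultiplexing configuration
#'
#' Free parameters of the two-stage genotype discovery method. All are
#' exposed; the defaults are tuned for droplet samples of roughly 1,000 to
#' 10,000 cells with a few hundred expressed SNVs.
#'
#' @param min_snvs_per_cell cells must cover at least this many SNV sites to
#'   take part in genotype discovery (they are still classified at the end).
#' @param knn_k neighbours per cell in the allele-fraction KNN graph.
#' @param min_shared_sites minimum number of sites covered in both cells for
#'   their allele-fraction distance to be defined.
#' @param mad_k MAD multiplier for the stage-2 genotype-score threshold.
#' @param doublet_sim_multiplier simulated doublets per observed eligible cell
#'   used to calibrate the doublet acceptance region.
#' @param pseudocount Beta pseudocount added to allele-fraction estimates.
#' @param max_iter maximum refinement iterations.
#' @param assign_margin minimum top-vs-runner-up log-likelihood margin (nats)
#'   for a confident label; below it a cell is unassigned.
#' @param af_floor allele fractions are clamped to `[af_floor, 1 - af_floor]`
#'   in all likelihoods, bounding the damage a single contaminating read
#'   (ambient RNA, sequencing error) can do.
#' @param sep_floor minimum mean absolute allele-fraction difference, over
#'   sites informative in both profiles, for two candidate genotypes to be
#'   accepted as genuinely distinct.
#' @param max_discovery_cells stage-1 graph size cap; when more cells are
#'   eligible a seeded subsample of this size is used for discovery only
#'   (every cell is still scored and classified).
#' @param seed integer seed controlling every stochastic step (subsampling,
#'   community detection, doublet simulation); identical input + seed gives an
#'   identical result.
#' @return A list of class `demux_config`.
#' @export
demux_config <- function(min_snvs_per_cell = 25L, knn_k = 10L,
                         min_shared_sites = 5L, mad_k = 5.0,
                         doublet_sim_multiplier = 1.0, pseudocount = 1.0,
                         max_iter = 50L, assign_margin = 2.0,
                         af_floor = 1e-3, sep_floor = 0.1,
                         max_discovery_cells = 2000L, seed = 1L) {
  stopifnot(min_snvs_per_cell > 0, knn_k > 0, min_shared_sites > 0,
            mad_k > 0, doublet_sim_multiplier >= 0, pseudocount > 0,
            max_iter > 0, assign_margin >= 0, af_floor > 0, af_floor < 0.5,
            sep_floor >= 0, max_discovery_cells > 0)
  structure(list(min_snvs_per_cell = as.integer(min_snvs_per_cell),
                 knn_k = as.integer(knn_k),
                 min_shared_sites = as.integer(min_shared_sites),
                 mad_k = mad_k,
                 doublet_sim_multiplier = doublet_sim_multiplier,
                 pseudocount = pseudocount,
                 max_iter = as.integer(max_iter),
                 assign_margin = assign_margin,
                 af_floor = af_floor,
                 sep_floor = sep_floor,
                 max_discovery_cells = as.integer(max_discovery_cells),
                 seed = as.integer(seed)),
            class = "demux_config")
}

# evaluate expr under a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

LABELS <- c("GT1", "GT2", "doublet", "unassigned")

#' Cells eligible for genotype discovery
#'
#' High-quality cells expressing a reasonable number of SNV loci: those
#' covering at least `min_snvs_per_cell` sites. Remaining cells never enter
#' discovery or genotype estimation but are always classified at the end.
#'
#' @param x An [allele_counts] object.
#' @param config A [demux_config].
#' @return Integer vector of eligible cell (column) indices.
#' @export
select_eligible_cells <- function(x, config = demux_config()) {
  elig <- which(sites_per_cell(x) >= config$min_snvs_per_cell)
  if (length(elig) < 2L * config$knn_k)
    stop(sprintf("insufficient cells for discovery: %d eligible (need >= %d); lower min_snvs_per_cell or knn_k",
                 length(elig), 2L * config$knn_k))
  elig
}

#' Allele-fraction distance between two cells
#'
#' Mean absolute difference of allele fractions over sites covered in both
#' cells; `NA` (no KNN edge candidate) when fewer than `min_shared_sites`
#' sites are shared. Symmetric, bounded in `[0, 1]`.
#'
#' @param af_a,af_b numeric allele-fraction vectors over the full site panel,
#'   `NA` at uncovered sites.
#' @param min_shared_sites minimum shared covered sites.
#' @return A single distance, or `NA_real_` if undefined.
#' @export
af_distance <- function(af_a, af_b, min_shared_sites = 5L) {
  shared <- which(!is.na(af_a) & !is.na(af_b))
  if (length(shared) < min_shared_sites) return(NA_real_)
  mean(abs(af_a[shared] - af_b[shared]))
}

# dense af + coverage mask for a subset of cells (sites x cells)
dense_af <- function(x, cells) {
  tot <- as.matrix(x$total[, cells, drop = FALSE])
  alt <- as.matrix(x$alt[, cells, drop = FALSE])
  cov <- (tot > 0) * 1.0
  af <- ifelse(tot > 0, alt / pmax(tot, 1), 0)
  list(af = af, cov = cov)
}

#' Stage 1: genotype discovery by community clustering
#'
#' Builds a KNN graph over eligible cells using allele-fraction distances,
#' detects communities by modularity maximisation (Louvain), agglomerates
#' community centroids into two candidate genotype groups, and accepts the
#' split only if the merged centroids differ by at least `sep_floor` mean
#' absolute allele fraction over shared covered sites.
#'
#' @param x An [allele_counts] object.
#' @param config A [demux_config].
#' @param eligible optional precomputed eligible cell indices.
#' @return A list of two integer vectors of cell indices (the candidate
#'   genotype groups), or `NULL` when no second genotype is found at this
#'   stage (including disconnected/singleton graphs).
#' @export
stage1_discover <- function(x, config = demux_config(),
                            eligible = select_eligible_cells(x, config)) {
  disc <- eligible
  if (length(disc) > config$max_discovery_cells)
    disc <- sort(with_seed(config$seed,
                           sample(disc, config$max_discovery_cells)))
  d <- dense_af(x, disc)
  nn <- .knn_af_distance(d$af, d$cov, config$knn_k, config$min_shared_sites)

  keep <- which(nn$idx > 0)
  if (!length(keep)) return(NULL)       # no defined distances at all
  from <- rep(seq_along(disc), each = config$knn_k)[keep]
  to <- nn$idx[keep]
  w <- 1 - nn$dist[keep]
  ek <- paste(pmin(from, to), pmax(from, to))
  dup <- duplicated(ek)
  g <- igraph::graph_from_data_frame(
    data.frame(from = from[!dup], to = to[!dup], weight = pmax(w[!dup], 1e-9)),
    directed = FALSE,
    vertices = data.frame(name = seq_along(disc)))
  comm <- with_seed(config$seed,
                    igraph::cluster_louvain(g, resolution = 1))
  memb <- igraph::membership(comm)[as.character(seq_along(disc))]
  sizes <- table(memb)
  if (length(sizes) < 2L) return(NULL)

  # community centroids: per-site mean af over covered member cells
  ids <- sort(unique(memb))
  cents <- vapply(ids, function(cid) {
    m <- memb == cid
    cv <- rowSums(d$cov[, m, drop = FALSE])
    ifelse(cv > 0, rowSums((d$af * d$cov)[, m, drop = FALSE]) / pmax(cv, 1), NA_real_)
  }, numeric(nrow(d$af)))
  cd <- centroid_dist_matrix(cents)
  # seed the two genotype groups with the farthest pair of core-sized
  # communities (a community below knn_k cells has a centroid too noisy —
  # and a neighbourhood too small — to anchor a genotype) and attach every
  # other community, e.g. small doublet-dominated ones sitting between the
  # cores, to the nearer seed; ties resolve to the lowest community index
  core <- which(as.vector(sizes[as.character(ids)]) >= config$knn_k)
  if (length(core) < 2L) return(NULL)
  cd_core <- cd[core, core, drop = FALSE]
  far <- which(cd_core == max(cd_core), arr.ind = TRUE)
  far <- core[far[order(far[, 1], far[, 2]), , drop = FALSE][1, ]]
  super <- ifelse(cd[, far[1]] <= cd[, far[2]], 1L, 2L)

  g1 <- disc[memb %in% ids[super == 1]]
  g2 <- disc[memb %in% ids[super == 2]]
  # a genotype group smaller than k cannot sustain its own neighbourhood in
  # the KNN graph; splits that small are stage 2's job, not stage 1's
  if (min(length(g1), length(g2)) < config$knn_k) return(NULL)
  # measure separation on the two seed communities: under heavy ambient
  # contamination the attached intermediate communities dilute the merged
  # supergroups, while the cores stay representative of the genotypes
  sep <- group_separation(x, disc[memb == ids[far[1]]],
                          disc[memb == ids[far[2]]])
  if (is.na(sep) || sep < config$sep_floor) return(NULL)
  if (length(g2) > length(g1)) list(g1 = g2, g2 = g1) else list(g1 = g1, g2 = g2)
}

centroid_dist_matrix <- function(cents) {
  k <- ncol(cents)
  cd <- matrix(1, k, k); diag(cd) <- 0
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    sh <- which(!is.na(cents[, i]) & !is.na(cents[, j]))
    cd[i, j] <- cd[j, i] <- if (length(sh)) mean(abs(cents[sh, i] - cents[sh, j])) else 1
  }
  cd
}

# Separation between two cell groups: support-weighted mean absolute
# difference of pooled allele fractions over sites informative in both
# groups. Weighting by the smaller group support keeps thinly covered sites
# from dominating. This is a liberal candidate-level check; spurious splits
# that pass it are caught by the split-half replication test after
# refinement (see second_genotype_replicates).
group_separation <- function(x, cells_a, cells_b) {
  aa <- Matrix::rowSums(x$alt[, cells_a, drop = FALSE])
  sa <- Matrix::rowSums(x$total[, cells_a, drop = FALSE])
  ab <- Matrix::rowSums(x$alt[, cells_b, drop = FALSE])
  sb <- Matrix::rowSums(x$total[, cells_b, drop = FALSE])
  w <- pmin(sa, sb)
  inf <- w > 0
  if (!any(inf)) return(NA_real_)
  sum(w[inf] * abs(aa[inf] / sa[inf] - ab[inf] / sb[inf])) / sum(w[inf])
}

# Split-half replication test of a candidate second genotype. The minor
# group is split into random halves and each half's pooled allele-fraction
# deviation from the major profile is computed per site; the statistic is
# their support-weighted correlation through the origin. A genuine genotype
# deviates identically in both halves (r near 1); a group assembled from
# sampling noise — even one selected for extremeness, which defeats
# SE-subtraction corrections — deviates at different sites in each half
# (r near 0). Ambient contamination cancels: it shifts both halves and the
# major profile alike. Requires >= 4 minor cells and >= 10 mutually
# informative sites; below that the candidate separation check stands alone.
second_genotype_replicates <- function(x, minor_cells, major_cells, seed,
                                       r_min = 0.5) {
  if (length(minor_cells) < 4L) return(TRUE)
  half <- with_seed(seed, sample(minor_cells, floor(length(minor_cells) / 2)))
  other <- setdiff(minor_cells, half)
  pool <- function(cells) {
    list(alt = Matrix::rowSums(x$alt[, cells, drop = FALSE]),
         tot = Matrix::rowSums(x$total[, cells, drop = FALSE]))
  }
  a <- pool(half); b <- pool(other); m <- pool(major_cells)
  inf <- a$tot > 0 & b$tot > 0 & m$tot > 0
  if (sum(inf) < 10L) return(TRUE)
  w <- pmin(a$tot, b$tot)[inf]
  af_m <- m$alt[inf] / m$tot[inf]
  da <- a$alt[inf] / a$tot[inf] - af_m
  db <- b$alt[inf] / b$tot[inf] - af_m
  den <- sqrt(sum(w * da^2) * sum(w * db^2))
  if (den == 0) return(FALSE)
  sum(w * da * db) / den >= r_min
}

#' Estimate a per-site genotype allele-fraction profile
#'
#' Pools reads over the given cells with a symmetric Beta pseudocount:
#' `af = (sum alt + pc) / (sum total + 2 pc)` per site. Sites with no
#' supporting reads therefore sit at the prior mean 0.5 and carry no weight in
#' separation checks (support 0).
#'
#' @param x An [allele_counts] object.
#' @param cells non-empty integer vector of cell indices.
#' @param pseudocount positive Beta pseudocount.
#' @return A list with `af` (numeric per site), `support` (total reads per
#'   site) and `n_cells`.
#' @export
estimate_genotype <- function(x, cells, pseudocount = 1.0) {
  if (!length(cells)) stop("cannot estimate a genotype from an empty cell set")
  stopifnot(pseudocount > 0)
  alt <- Matrix::rowSums(x$alt[, cells, drop = FALSE])
  tot <- Matrix::rowSums(x$total[, cells, drop = FALSE])
  list(af = (alt + pseudocount) / (tot + 2 * pseudocount),
       support = tot, n_cells = length(cells))
}

# doublet allele fractions: per-site mean of the two genotype profiles
# weighted by each genotype's mean per-cell coverage (a doublet is one cell of
# each genotype, so parent contributions scale with per-cell depth, not with
# group size)
doublet_profile <- function(m1, m2) {
  w1 <- m1$support / max(1L, m1$n_cells)
  w2 <- m2$support / max(1L, m2$n_cells)
  wt <- w1 + w2
  ifelse(wt > 0, (w1 * m1$af + w2 * m2$af) / pmax(wt, .Machine$double.eps),
         0.5 * (m1$af + m2$af))
}

clamp_af <- function(p, floor) pmin(pmax(p, floor), 1 - floor)

# per-cell binomial log-likelihood (natural log, no combinatorial constant)
# under a per-site allele-fraction vector; sparse-safe: uncovered sites add 0
cell_loglik <- function(x, af, af_floor) {
  p <- clamp_af(af, af_floor)
  as.numeric(Matrix::crossprod(x$alt, log(p)) +
             Matrix::crossprod(x$total - x$alt, log1p(-p)))
}

#' Genotype score of each cell against a dominant genotype
#'
#' Mean per-read binomial log-likelihood of a cell's alt counts under the
#' dominant genotype's allele fractions, clamped to
#' `[af_floor, 1 - af_floor]`. Depth-normalised, so comparable across cells of
#' different coverage; higher (closer to 0) means more consistent with the
#' dominant genotype, with a per-read minimum of `log(af_floor)`.
#'
#' @param x An [allele_counts] object.
#' @param dominant a genotype profile from [estimate_genotype].
#' @param af_floor clamp floor for allele fractions.
#' @return Numeric vector, one score per cell; `NA` for cells with zero
#'   covered sites (routed to unassigned downstream).
#' @export
genotype_score <- function(x, dominant, af_floor = 1e-3) {
  ll <- cell_loglik(x, dominant$af, af_floor)
  reads <- Matrix::colSums(x$total)
  ifelse(reads > 0, ll / pmax(reads, 1), NA_real_)
}

#' Stage 2: rescue of a rare second genotype
#'
#' When stage-1 clustering finds a single genotype, flags eligible cells whose
#' genotype score falls below `median - mad_k * MAD` (MAD with the 1.4826
#' normal-consistency constant) and accepts the flagged set as a second
#' genotype only if its pooled allele-fraction profile differs from the
#' dominant profile by at least `sep_floor` over mutually informative sites.
#'
#' @param x An [allele_counts] object.
#' @param dominant dominant genotype profile estimated from all eligible cells.
#' @param config A [demux_config].
#' @param eligible optional precomputed eligible cell indices.
#' @return Integer vector of rescued minor-genotype cell indices, or `NULL`
#'   when no second genotype is found (including the degenerate MAD = 0 case).
#' @export
stage2_rescue <- function(x, dominant, config = demux_config(),
                          eligible = select_eligible_cells(x, config)) {
  s <- genotype_score(x, dominant, config$af_floor)[eligible]
  ok <- !is.na(s)
  med <- stats::median(s[ok])
  md <- stats::mad(s[ok])                     # 1.4826-scaled
  if (!is.finite(md) || md == 0) return(NULL)
  flagged <- eligible[ok][s[ok] < med - config$mad_k * md]
  if (!length(flagged)) return(NULL)
  rest <- setdiff(eligible, flagged)
  if (!length(rest)) return(NULL)
  sep <- group_separation(x, rest, flagged)
  if (is.na(sep) || sep < config$sep_floor) return(NULL)
  flagged
}

#' Simulate cell-cell doublet count profiles
#'
#' Draws `n` synthetic doublets, each the elementwise sum of the alt and total
#' counts of one uniformly drawn GT1 cell and one uniformly drawn GT2 cell.
#' Used to calibrate the doublet log-likelihood acceptance region.
#'
#' @param x An [allele_counts] object.
#' @param gt1_cells,gt2_cells non-empty cell index vectors.
#' @param n number of synthetic doublets (> 0).
#' @param seed RNG seed; identical seeds give identical synthetic sets.
#' @return A list with sparse `alt` and `total` matrices (`sites x n`) and the
#'   parent index matrix `parents` (`n x 2`).
#' @export
simulate_doublet_profiles <- function(x, gt1_cells, gt2_cells, n, seed = 1L) {
  if (n <= 0) stop("n must be positive")
  if (!length(gt1_cells) || !length(gt2_cells))
    stop("both genotype groups must be non-empty")
  pick <- with_seed(seed, cbind(
    gt1_cells[sample.int(length(gt1_cells), n, replace = TRUE)],
    gt2_cells[sample.int(length(gt2_cells), n, replace = TRUE)]))
  list(alt = x$alt[, pick[, 1], drop = FALSE] + x$alt[, pick[, 2], drop = FALSE],
       total = x$total[, pick[, 1], drop = FALSE] + x$total[, pick[, 2], drop = FALSE],
       parents = pick)
}

# log-likelihood matrix (cells x 3) under GT1 / GT2 / doublet profiles
loglik_matrix <- function(x, model, config) {
  cbind(gt1 = cell_loglik(x, model$gt1$af, config$af_floor),
        gt2 = cell_loglik(x, model$gt2$af, config$af_floor),
        doublet = cell_loglik(x, model$dbl_af, config$af_floor))
}

# Doublet acceptance region calibrated against the simulated doublet set.
# Feature space: (doublet-vs-best-singlet log-likelihood difference,
# log total reads) — the raw doublet log-likelihood scales with depth
# (synthetic doublets carry roughly twice a singlet's reads), so the
# difference is the statistic that transfers from the calibration set to
# observed cells, and depth itself is the second doublet signature. Two
# class centres are fitted: the doublet class on the synthetic set (mean) and
# the singlet bulk on the observed cells (median — robust to the small
# true-doublet minority), with a pooled per-dimension spread (equal
# covariance, so the decision boundary is a plain halfway hyperplane and
# extreme cells cannot be captured by whichever class happens to have the
# wider spread). A cell's doublet evidence is the resulting log-likelihood
# ratio; calls require it to clear the assignment margin, so under heavy
# ambient contamination — where the two distributions overlap —
# over-contaminated singlets are not called doublets.
doublet_calibration <- function(x, model, gt1_cells, gt2_cells, config, seed) {
  n <- max(1L, round(config$doublet_sim_multiplier * length(x$barcodes)))
  syn <- simulate_doublet_profiles(x, gt1_cells, gt2_cells, n, seed)
  synx <- list(alt = syn$alt, total = syn$total)
  fs <- doublet_features(loglik_matrix(synx, model, config), synx)
  fo <- doublet_features(loglik_matrix(x, model, config), x)
  ok <- is.finite(fo[, 2])                 # cells with zero reads drop out
  sd_syn <- apply(fs, 2, stats::sd)
  sd_bulk <- apply(fo[ok, , drop = FALSE], 2, stats::mad)
  cal <- list(mu_syn = colMeans(fs),
              mu_bulk = apply(fo[ok, , drop = FALSE], 2, stats::median),
              sd_pooled = pmax(sqrt((sd_syn^2 + sd_bulk^2) / 2), 1e-6))
  if (!all(is.finite(unlist(cal)))) return(NULL)
  cal
}

doublet_features <- function(ll, x) {
  cbind(delta = ll[, 3] - pmax(ll[, 1], ll[, 2]),
        log_reads = log(pmax(Matrix::colSums(x$total), 0)))
}

# log-likelihood ratio (doublet class vs singlet bulk) per cell, equal
# per-dimension variance
doublet_evidence <- function(feat, cal) {
  if (is.null(cal)) return(feat[, "delta"])  # fall back to the raw difference
  gauss <- function(f, mu)
    stats::dnorm(f[, 1], mu[1], cal$sd_pooled[1], log = TRUE) +
    stats::dnorm(f[, 2], mu[2], cal$sd_pooled[2], log = TRUE)
  gauss(feat, cal$mu_syn) - gauss(feat, cal$mu_bulk)
}

#' Classify every cell against the current genotype model
#'
#' Assigns each cell (eligible or not) the argmax of its binomial
#' log-likelihood under the GT1, GT2 and doublet profiles. With a calibration
#' from the synthetic doublet set, a `doublet` call requires positive doublet
#' evidence (the calibrated log-likelihood ratio of the doublet class against
#' the singlet bulk); otherwise the best singlet label is taken. A call is
#' downgraded to `unassigned` when its margin — doublet evidence for doublet
#' calls, the GT1-vs-GT2 log-likelihood gap for singlet calls — is below
#' `assign_margin`, or when the cell covers zero sites.
#'
#' @param x An [allele_counts] object.
#' @param model internal model list (`gt1`, `gt2` profiles and `dbl_af`).
#' @param config A [demux_config].
#' @param calibration synthetic-doublet calibration (internal, from the
#'   refinement loop); `NULL` reduces the rule to the pure three-profile
#'   argmax with the margin safeguard.
#' @return A list with `label` (character, levels GT1/GT2/doublet/unassigned),
#'   `ll` (cells x 3 log-likelihood matrix) and `margin`.
#' @export
classify_cells <- function(x, model, config = demux_config(), calibration = NULL) {
  ll <- loglik_matrix(x, model, config)
  best_singlet <- ifelse(ll[, 1] >= ll[, 2], 1L, 2L)
  feat <- doublet_features(ll, x)
  ev <- doublet_evidence(feat, calibration)
  ev[!is.finite(feat[, "log_reads"])] <- -Inf
  is_dbl <- ev > 0
  lab_idx <- ifelse(is_dbl, 3L, best_singlet)
  margin <- ifelse(is_dbl, ev, abs(ll[, 1] - ll[, 2]))
  label <- c("GT1", "GT2", "doublet")[lab_idx]
  n_inf <- sites_per_cell(x)
  label[margin < config$assign_margin | n_inf == 0L] <- "unassigned"
  list(label = label, ll = ll, margin = margin)
}

#' Iteratively refine genotypes and cell assignments
#'
#' Alternates genotype estimation (on currently GT1/GT2-labelled eligible
#' cells only) with classification of all eligible cells, re-simulating the
#' doublet calibration set each sweep, until the labels reach a fixed point or
#' `max_iter` sweeps elapse. The tracked objective (total assigned-label
#' log-likelihood over eligible cells) is non-decreasing across accepted
#' iterations; a sweep that fails to improve it terminates refinement.
#'
#' @param x An [allele_counts] object.
#' @param groups list of two integer vectors: the initial GT1/GT2 cell groups
#'   from stage 1 or stage 2.
#' @param config A [demux_config].
#' @param eligible optional precomputed eligible cell indices.
#' @return A `demux_fit` object (see [demultiplex]); if one genotype group
#'   empties during refinement, a single-genotype fit with
#'   `second_genotype_found = FALSE` and a warning.
#' @export
refine <- function(x, groups, config = demux_config(),
                   eligible = select_eligible_cells(x, config)) {
  lab <- rep(NA_character_, length(x$barcodes))
  lab[groups$g1] <- "GT1"
  lab[groups$g2] <- "GT2"
  objective <- numeric(0)
  converged <- FALSE
  iter <- 0L
  model <- NULL; calib <- NULL
  xe <- list(alt = x$alt[, eligible, drop = FALSE],
             total = x$total[, eligible, drop = FALSE],
             barcodes = x$barcodes[eligible])

  while (iter < config$max_iter) {
    iter <- iter + 1L
    c1 <- which(lab == "GT1"); c2 <- which(lab == "GT2")
    c1 <- intersect(c1, eligible); c2 <- intersect(c2, eligible)
    if (!length(c1) || !length(c2)) {
      warning("a genotype group emptied during refinement; reporting a single genotype")
      return(single_genotype_fit(x, config, eligible, n_iterations = iter,
                                 note = "group emptied during refinement"))
    }
    new_model <- list(gt1 = estimate_genotype(x, c1, config$pseudocount),
                      gt2 = estimate_genotype(x, c2, config$pseudocount))
    new_model$dbl_af <- doublet_profile(new_model$gt1, new_model$gt2)
    new_calib <- doublet_calibration(x, new_model, c1, c2, config,
                                     seed = config$seed + iter)
    cl <- classify_cells(xe, new_model, config, new_calib)
    obj <- sum(apply(cl$ll, 1, max))
    if (length(objective) && obj < utils::tail(objective, 1) - 1e-8) {
      converged <- TRUE                  # no further improvement possible
      break
    }
    objective <- c(objective, obj)
    model <- new_model; calib <- new_calib
    new_lab <- lab
    new_lab[eligible] <- cl$label
    if (identical(new_lab[eligible], lab[eligible])) {
      converged <- TRUE
      lab <- new_lab
      break
    }
    lab <- new_lab
  }
  # final validity check on the refined partition: the minor genotype must
  # both stay separated from the major profile and replicate across random
  # halves of its cells — a split assembled from sampling noise does neither
  c1 <- intersect(which(lab == "GT1"), eligible)
  c2 <- intersect(which(lab == "GT2"), eligible)
  minor <- if (length(c1) >= length(c2)) c2 else c1
  major <- if (length(c1) >= length(c2)) c1 else c2
  sep <- if (length(minor)) group_separation(x, major, minor) else NA_real_
  if (!length(minor) || is.na(sep) || sep < config$sep_floor ||
      !second_genotype_replicates(x, minor, major, seed = config$seed + 7L)) {
    warning("refined second genotype failed the separation/replication check; reporting a single genotype")
    return(single_genotype_fit(x, config, eligible, n_iterations = iter,
                               note = "second genotype did not validate after refinement"))
  }
  build_fit(x, model, calib, config, eligible,
            second = TRUE, n_iterations = iter, converged = converged,
            objective = objective)
}

# final fit assembly: classify every cell (incl. discovery-ineligible ones)
# under the final model and package the result
build_fit <- function(x, model, calib, config, eligible, second,
                      n_iterations, converged, objective) {
  cl <- classify_cells(x, model, config, calib)
  gs <- genotype_score(x, model$gt1, config$af_floor)
  scores <- data.frame(barcode = x$barcodes,
                       label = cl$label,
                       loglik_gt1 = cl$ll[, 1],
                       loglik_gt2 = cl$ll[, 2],
                       loglik_doublet = cl$ll[, 3],
                       margin = cl$margin,
                       n_informative_sites = as.integer(sites_per_cell(x)),
                       genotype_score = gs,
                       eligible = seq_along(x$barcodes) %in% eligible,
                       stringsAsFactors = FALSE)
  structure(list(labels = factor(cl$label, levels = LABELS),
                 scores = scores,
                 model = model,
                 doublet_calibration = calib,
                 second_genotype_found = second,
                 n_iterations = n_iterations,
                 converged = converged,
                 objective = objective,
                 sites = x$sites,
                 barcodes = x$barcodes,
                 config = config),
            class = "demux_fit")
}

single_genotype_fit <- function(x, config, eligible, n_iterations = 0L,
                                note = NULL) {
  m1 <- estimate_genotype(x, eligible, config$pseudocount)
  ll1 <- cell_loglik(x, m1$af, config$af_floor)
  gs <- genotype_score(x, m1, config$af_floor)
  n_inf <- as.integer(sites_per_cell(x))
  label <- ifelse(n_inf == 0L, "unassigned", "GT1")
  scores <- data.frame(barcode = x$barcodes, label = label,
                       loglik_gt1 = ll1, loglik_gt2 = NA_real_,
                       loglik_doublet = NA_real_, margin = NA_real_,
                       n_informative_sites = n_inf, genotype_score = gs,
                       eligible = seq_along(x$barcodes) %in% eligible,
                       stringsAsFactors = FALSE)
  structure(list(labels = factor(label, levels = LABELS),
                 scores = scores,
                 model = list(gt1 = m1, gt2 = NULL, dbl_af = NULL),
                 doublet_calibration = NULL,
                 second_genotype_found = FALSE,
                 n_iterations = n_iterations,
                 converged = TRUE,
                 objective = numeric(0),
                 sites = x$sites,
                 barcodes = x$barcodes,
                 config = config,
                 note = note),
            class = "demux_fit")
}

#' Demultiplex a transplant scRNA-seq sample by genotype
#'
#' Fits the two-stage genotype discovery model to per-cell SNV allele counts.
#' Stage 1 clusters high-quality cells on a KNN graph of allele-fraction
#' distances ([stage1_discover]); when that finds a single genotype, stage 2
#' looks for a rare second genotype by a robust genotype-score threshold
#' ([stage2_rescue]). A discovered partition is polished by iterative
#' refinement with simulated-doublet calibration ([refine]). A refined fit
#' that fails validation — separation or split-half replication of the minor
#' genotype, or an excessive unassigned fraction, the signature of refinement
#' converging onto a spurious split — is discarded, falling through to the
#' stage-2 route and ultimately to a single-genotype report: the sample is
#' never force-split.
#'
#' @param x An [allele_counts] object with at least two cells (typically
#'   pre-filtered; see `prefilter`).
#' @param config A [demux_config].
#' @param prefilter apply [filter_snvs] with `filter_cfg` before fitting
#'   (default `TRUE`).
#' @param filter_cfg A [filter_config] used when `prefilter` is `TRUE`.
#' @return A `demux_fit` object with per-barcode labels
#'   (`GT1`/`GT2`/`doublet`/`unassigned`), per-cell scores, genotype
#'   allele-fraction profiles, `second_genotype_found`, iteration and
#'   convergence diagnostics. Methods: `print`, `summary`, `coef`, `predict`,
#'   `simulate`, `plot`.
#' @examples
#' \donttest{
#' sim <- simulate_sample(sim_config(n_total = 300, minor_count = 60,
#'                                   n_sites = 200, seed = 7))
#' fit <- demultiplex(sim$matrix, demux_config(seed = 7))
#' table(fit$labels, sim$truth)
#' }
#' @export
demultiplex <- function(x, config = demux_config(), prefilter = TRUE,
                        filter_cfg = filter_config()) {
  stopifnot(inherits(x, "allele_counts"))
  if (length(x$barcodes) < 2L) stop("need at least two cells to demultiplex")
  if (nrow(x$sites) == 0L) stop("empty matrix: no SNV sites")
  if (prefilter) {
    x <- filter_snvs(x, filter_cfg)
    if (nrow(x$sites) == 0L) stop("no SNV sites survive filtering")
  }
  eligible <- select_eligible_cells(x, config)
  groups <- stage1_discover(x, config, eligible)
  fit1 <- if (!is.null(groups)) refine(x, groups, config, eligible) else NULL
  if (healthy_fit(fit1, eligible)) return(fit1)
  # no (usable) stage-1 partition: look for a rare second genotype by the
  # robust genotype-score route
  dominant <- estimate_genotype(x, eligible, config$pseudocount)
  minor <- stage2_rescue(x, dominant, config, eligible)
  if (!is.null(minor)) {
    fit2 <- refine(x, list(g1 = setdiff(eligible, minor), g2 = minor),
                   config, eligible)
    if (healthy_fit(fit2, eligible)) return(fit2)
  }
  # last discovery route: k-means bisection of the allele-fraction profiles.
  # Community detection occasionally fragments under heavy ambient noise on
  # balanced mixtures that a plain bisection still separates; its candidates
  # face the same refinement validity gates, so single-genotype samples are
  # not force-split by the unconditional k = 2.
  groups3 <- bisect_discover(x, config, eligible)
  if (!is.null(groups3)) {
    fit3 <- refine(x, groups3, config, eligible)
    if (healthy_fit(fit3, eligible)) return(fit3)
  }
  single_genotype_fit(x, config, eligible)
}

# k = 2 k-means over per-cell allele-fraction vectors, validated on held-out
# reads. An unconditional bisection of a single genotype finds a
# pseudo-haplotype axis: cells grouped by their chance allele draws at
# heterozygous sites, which produces pooled allele-fraction differences that
# are systematic in the very reads the clustering saw. Binomially thinning
# every count into two halves, clustering on half A and measuring the
# split's separation on held-out half B removes that circularity: phantom
# axes have no echo in independent reads, genotype axes do.
bisect_discover <- function(x, config, eligible) {
  disc <- eligible
  if (length(disc) > config$max_discovery_cells)
    disc <- sort(with_seed(config$seed + 13L,
                           sample(disc, config$max_discovery_cells)))
  halves <- thin_counts(x, seed = config$seed + 19L)
  d <- dense_af(halves$a, disc)
  site_mean <- rowSums(d$af * d$cov) / pmax(rowSums(d$cov), 1)
  af <- d$af * d$cov + site_mean * (1 - d$cov)
  km <- with_seed(config$seed + 17L,
                  tryCatch(stats::kmeans(t(af), centers = 2, nstart = 5),
                           error = function(e) NULL))
  if (is.null(km)) return(NULL)
  g1 <- disc[km$cluster == 1L]
  g2 <- disc[km$cluster == 2L]
  if (min(length(g1), length(g2)) < config$knn_k) return(NULL)
  sep <- group_separation(halves$b, g1, g2)
  if (is.na(sep) || sep < config$sep_floor) return(NULL)
  if (length(g2) > length(g1)) list(g1 = g2, g2 = g1) else list(g1 = g1, g2 = g2)
}

# split every (site, cell) count into two binomial halves, alt-ness assigned
# hypergeometrically so each read lands in exactly one half
thin_counts <- function(x, seed) {
  idx <- Matrix::summary(x$total)
  tot <- as.integer(idx$x)
  alt <- as.integer(x$alt[cbind(idx$i, idx$j)])
  with_seed(seed, {
    tot_a <- stats::rbinom(length(tot), tot, 0.5)
    alt_a <- suppressWarnings(stats::rhyper(length(tot), alt, tot - alt, tot_a))
  })
  dims <- dim(x$total)
  mk <- function(a, t) {
    keep <- t > 0
    list(alt = Matrix::sparseMatrix(idx$i[keep], idx$j[keep], x = a[keep],
                                    dims = dims),
         total = Matrix::sparseMatrix(idx$i[keep], idx$j[keep], x = t[keep],
                                      dims = dims))
  }
  list(a = mk(alt_a, tot_a), b = mk(alt - alt_a, tot - tot_a))
}

# A trustworthy two-genotype fit assigns the vast majority of eligible cells:
# a refinement that converges onto a spurious split leaves a large fraction
# of cells without a confident label (two near-identical profiles give small
# margins everywhere). Healthy fits sit well under this bound.
healthy_fit <- function(fit, eligible) {
  if (is.null(fit) || !fit$second_genotype_found) return(FALSE)
  mean(fit$scores$label[eligible] == "unassigned") <= 0.25
}
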