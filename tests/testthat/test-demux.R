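test_that("eligibility gate keeps cells with enough covered SNVs", {
  total <- matrix(0, 30, 25)
  total[1:30, 1:20] <- 1          # 20 cells covering 30 sites
  total[1:10, 21:25] <- 1         # 5 cells covering 10 sites
  m <- toy_counts(matrix(0, 30, 25), total)
  cfg <- demux_config(min_snvs_per_cell = 25, knn_k = 10)
  expect_equal(select_eligible_cells(m, cfg), 1:20)
  expect_error(select_eligible_cells(m, demux_config(min_snvs_per_cell = 50)),
               "insufficient cells")
})

test_that("allele-fraction distance follows its definition", {
  a <- c(rep(0.5, 20), rep(NA, 5))
  expect_equal(af_distance(a, a), 0)
  expect_equal(af_distance(rep(0, 10), rep(1, 10)), 1)
  expect_true(is.na(af_distance(c(0, 1, 0, NA, NA), c(1, 0, 1, NA, NA),
                                min_shared_sites = 5)))
  x <- c(0.2, 0.8, NA, 0.5); y <- c(0.4, 0.2, 0.1, NA)
  expect_equal(af_distance(x, y, 2), af_distance(y, x, 2))
  expect_equal(af_distance(x, y, 2), mean(c(0.2, 0.6)))
})

test_that("genotype profile estimation matches the pseudocount formula", {
  m <- toy_counts(alt = matrix(c(0, 10, 5), 3, 1),
                  total = matrix(c(0, 10, 10), 3, 1))
  g <- estimate_genotype(m, 1L, pseudocount = 1)
  expect_equal(g$af, c(0.5, 11 / 12, 0.5))
  expect_equal(g$support, c(0, 10, 10), ignore_attr = TRUE)
  expect_error(estimate_genotype(m, integer(0)), "empty")
})

test_that("genotype score is the clamped mean per-read log-likelihood", {
  n <- 50
  # perfect fit at clamped-extreme sites: score within the clamp of 0
  m_ref <- toy_counts(matrix(0, n, 1), matrix(2, n, 1))
  dom <- list(af = rep(0, n))
  expect_gt(genotype_score(m_ref, dom), log(1 - 1e-3) - 1e-12)
  # homozygous-opposite at every site: the per-read minimum log(floor)
  m_opp <- toy_counts(matrix(2, n, 1), matrix(2, n, 1))
  expect_equal(genotype_score(m_opp, dom), log(1e-3))
  # determinism and NA for a cell with no reads
  expect_identical(genotype_score(m_opp, dom), genotype_score(m_opp, dom))
  m0 <- toy_counts(matrix(0, n, 2), {z <- matrix(0, n, 2); z[, 1] <- 1; z})
  expect_true(is.na(genotype_score(m0, dom)[2]))
})

test_that("simulated doublet profiles are exact parent sums", {
  m <- toy_counts(alt = matrix(c(0, 4), 1, 2), total = matrix(c(4, 4), 1, 2))
  syn <- simulate_doublet_profiles(m, gt1_cells = 1L, gt2_cells = 2L,
                                   n = 3, seed = 1)
  expect_equal(as.vector(syn$alt), rep(4, 3))
  expect_equal(as.vector(syn$total), rep(8, 3))
  expect_error(simulate_doublet_profiles(m, 1L, 2L, n = 0), "positive")
  s1 <- simulate_doublet_profiles(m, 1L, 2L, 5, seed = 99)
  s2 <- simulate_doublet_profiles(m, 1L, 2L, 5, seed = 99)
  expect_identical(s1$parents, s2$parents)
})

test_that("classification equals brute-force argmax on tiny instances", {
  cfg <- demux_config(assign_margin = 0)
  for (rep in 1:25) {
    set.seed(rep)
    n_sites <- sample(2:5, 1); n_cells <- sample(2:10, 1)
    total <- matrix(rpois(n_sites * n_cells, 2), n_sites, n_cells)
    alt <- matrix(rbinom(length(total), total, 0.5), n_sites, n_cells)
    m <- toy_counts(alt, total)
    model <- list(gt1 = list(af = runif(n_sites), support = rep(10, n_sites),
                             n_cells = 5L),
                  gt2 = list(af = runif(n_sites), support = rep(10, n_sites),
                             n_cells = 5L))
    model$dbl_af <- (model$gt1$af + model$gt2$af) / 2
    got <- classify_cells(m, model, cfg)$label
    profs <- cbind(model$gt1$af, model$gt2$af, model$dbl_af)
    oracle <- vapply(seq_len(n_cells), function(j) {
      if (all(total[, j] == 0)) return("unassigned")
      ll <- vapply(1:3, function(k) {
        p <- pmin(pmax(profs[, k], 1e-3), 1 - 1e-3)
        sum(stats::dbinom(alt[, j], total[, j], p, log = TRUE))
      }, numeric(1))
      c("GT1", "GT2", "doublet")[which.max(ll)]
    }, character(1))
    expect_equal(got, oracle, info = paste("instance", rep))
  }
})

test_that("cells with zero covered sites are always unassigned", {
  total <- matrix(2, 4, 3); total[, 2] <- 0
  m <- toy_counts(matrix(0, 4, 3), total)
  model <- list(gt1 = list(af = rep(0.1, 4), support = rep(8, 4), n_cells = 2L),
                gt2 = list(af = rep(0.9, 4), support = rep(8, 4), n_cells = 2L))
  model$dbl_af <- rep(0.5, 4)
  expect_equal(classify_cells(m, model, demux_config())$label[2], "unassigned")
})

test_that("stage 1 recovers a balanced two-genotype mixture", {
  s <- small_mixture(n_total = 400, minor = 200, seed = 13, ambient = 0)
  x <- filter_snvs(s$matrix)
  g <- stage1_discover(x, demux_config(seed = 13))
  expect_false(is.null(g))
  tru <- as.character(s$truth)
  purity <- function(cells) max(table(tru[cells])[c("GT1", "GT2")], na.rm = TRUE) /
    sum(tru[cells] %in% c("GT1", "GT2"))
  expect_gte(purity(g$g1), 0.95)
  expect_gte(purity(g$g2), 0.95)
})

test_that("stage 1 does not split a single-genotype sample", {
  for (seed in c(23, 101, 202)) {
    s <- simulate_sample(sim_config(n_total = 400, seed = seed),
                         minor_count = 0, ambient_rate = 0.1, seed = seed)
    x <- filter_snvs(s$matrix)
    fit <- suppressWarnings(demultiplex(s$matrix, demux_config(seed = seed)))
    expect_false(fit$second_genotype_found, label = paste("seed", seed))
    expect_true(all(fit$labels %in% c("GT1", "unassigned")))
  }
})

test_that("stage 2 rescues a rare second genotype by the MAD rule", {
  s <- simulate_sample(sim_config(n_total = 1000, seed = 3),
                       minor_count = 8, ambient_rate = 0, seed = 21)
  x <- filter_snvs(s$matrix)
  cfg <- demux_config(seed = 21)
  elig <- select_eligible_cells(x, cfg)
  expect_null(stage1_discover(x, cfg, elig))
  dominant <- estimate_genotype(x, elig, cfg$pseudocount)
  flagged <- stage2_rescue(x, dominant, cfg, elig)
  truth_gt2 <- which(as.character(s$truth) == "GT2")
  expect_true(all(truth_gt2 %in% flagged))
  expect_lte(length(setdiff(flagged, truth_gt2)), 3)
  fit <- demultiplex(s$matrix, cfg)
  expect_true(fit$second_genotype_found)
  expect_true(all(fit$labels[truth_gt2] == "GT2"))
  expect_lte(sum(fit$labels == "GT2"), length(truth_gt2) + 3)
})

test_that("stage 2 returns nothing for degenerate or one-genotype scores", {
  # identical cells -> identical scores -> MAD 0 -> no rescue
  m <- toy_counts(matrix(1, 30, 40), matrix(2, 30, 40))
  cfg <- demux_config(seed = 1)
  elig <- select_eligible_cells(m, cfg)
  dom <- estimate_genotype(m, elig)
  expect_null(stage2_rescue(m, dom, cfg, elig))
  # one tight genotype
  s <- simulate_sample(sim_config(n_total = 300, seed = 5), minor_count = 0,
                       ambient_rate = 0, seed = 5)
  x <- filter_snvs(s$matrix)
  elig <- select_eligible_cells(x, cfg)
  expect_null(stage2_rescue(x, estimate_genotype(x, elig), cfg, elig))
})

test_that("refinement converges quickly to truth on separated mixtures", {
  s <- small_mixture(n_total = 300, minor = 90, seed = 31, ambient = 0)
  fit <- demultiplex(s$matrix, demux_config(seed = 31))
  expect_true(fit$second_genotype_found)
  expect_true(fit$converged)
  expect_lte(fit$n_iterations, 5)
  cs <- tpr_fdr(fit$labels, s$truth, "singlet")
  expect_gte(cs$tpr, 0.99)
  # objective trace is non-decreasing, step by step
  expect_false(is.unsorted(fit$objective))
})

test_that("refinement respects fixed points and the iteration cap", {
  s <- simulate_sample(sim_config(n_total = 200, doublet_rate = 0, seed = 41),
                       minor_count = 80, ambient_rate = 0, seed = 41)
  x <- filter_snvs(s$matrix)
  cfg <- demux_config(seed = 41)
  elig <- select_eligible_cells(x, cfg)
  tru <- as.character(s$truth)
  groups <- list(g1 = intersect(which(tru == "GT1"), elig),
                 g2 = intersect(which(tru == "GT2"), elig))
  fit <- refine(x, groups, cfg, elig)
  expect_equal(fit$n_iterations, 1L)
  expect_true(fit$converged)
  expect_equal(as.character(fit$labels)[elig], tru[elig])

  # a deliberately wrong initial split cannot reach a fixed point in one sweep
  half <- with(list(e = elig), split(e, rep(1:2, length.out = length(e))))
  fit1 <- suppressWarnings(refine(x, list(g1 = half[[1]], g2 = half[[2]]),
                                  demux_config(seed = 41, max_iter = 1), elig))
  expect_equal(fit1$n_iterations, 1L)
  expect_false(fit1$converged && fit1$second_genotype_found)
})

test_that("swapping the initial groups permutes labels, not the partition", {
  s <- small_mixture(n_total = 250, minor = 100, seed = 53, ambient = 0.1)
  x <- filter_snvs(s$matrix)
  cfg <- demux_config(seed = 53)
  elig <- select_eligible_cells(x, cfg)
  g <- stage1_discover(x, cfg, elig)
  fit_a <- refine(x, g, cfg, elig)
  fit_b <- refine(x, list(g1 = g$g2, g2 = g$g1), cfg, elig)
  la <- as.character(fit_a$labels); lb <- as.character(fit_b$labels)
  swap <- c(GT1 = "GT2", GT2 = "GT1", doublet = "doublet",
            unassigned = "unassigned")
  expect_true(identical(la, lb) || identical(la, unname(swap[lb])))
})

test_that("refinement falls back to one genotype when a group empties", {
  s <- simulate_sample(sim_config(n_total = 300, seed = 61), minor_count = 0,
                       ambient_rate = 0, seed = 61)
  x <- filter_snvs(s$matrix)
  cfg <- demux_config(seed = 61)
  elig <- select_eligible_cells(x, cfg)
  # "minor" group of 5 cells of the same single genotype
  fake <- list(g1 = elig[-(1:5)], g2 = elig[1:5])
  fit <- suppressWarnings(refine(x, fake, cfg, elig))
  expect_false(fit$second_genotype_found)
})

test_that("demultiplexing is deterministic and labels partition the barcodes", {
  s <- small_mixture(n_total = 250, minor = 50, ambient = 0.2, seed = 71)
  f1 <- demultiplex(s$matrix, demux_config(seed = 71))
  f2 <- demultiplex(s$matrix, demux_config(seed = 71))
  expect_identical(f1$labels, f2$labels)
  expect_identical(f1$scores, f2$scores)
  expect_equal(sum(table(f1$labels)), length(s$matrix$barcodes))
  expect_error(demultiplex(s$matrix[, 1]), "at least two cells")
  empty <- s$matrix; empty$sites <- empty$sites[0, , drop = FALSE]
  empty$alt <- empty$alt[0, , drop = FALSE]
  empty$total <- empty$total[0, , drop = FALSE]
  expect_error(demultiplex(empty), "no SNV sites|empty")
})

test_that("genotype allele fractions are recovered accurately", {
  for (amb in c(0, 0.2)) {
    s <- simulate_sample(sim_config(n_total = 1000, seed = 83),
                         minor_count = 300, ambient_rate = amb, seed = 83)
    fit <- demultiplex(s$matrix, demux_config(seed = 83))
    expect_true(fit$second_genotype_found)
    idx <- match(paste(fit$sites$chrom, fit$sites$pos),
                 paste(s$pair$sites$chrom, s$pair$sites$pos))
    mp <- match_labels(fit$labels, s$truth)
    truth_af <- if (mp[["GT1"]] == "GT1") s$pair$true_af1 else s$pair$true_af2
    sup <- fit$model$gt1$support >= 20
    mae <- mean(abs(fit$model$gt1$af[sup] - truth_af[idx][sup]))
    expect_lte(mae, 0.05)
  }
})

test_that("fit methods expose the model in standard R idioms", {
  s <- small_mixture(n_total = 250, minor = 80, seed = 91)
  fit <- demultiplex(s$matrix, demux_config(seed = 91))
  expect_output(print(fit), "second genotype found: TRUE")
  sm <- summary(fit)
  expect_s3_class(sm, "summary.demux_fit")
  expect_gt(sm$genotype_separation, 0.1)
  cf <- coef(fit)
  expect_equal(colnames(cf), c("GT1", "GT2", "doublet"))
  expect_true(all(cf >= 0 & cf <= 1))
  # predict on the training panel reproduces the fitted labels
  x <- filter_snvs(s$matrix)
  pr <- predict(fit, x)
  expect_equal(pr$label, as.character(fit$labels))
  # simulated singlets from one genotype classify back to it
  sim2 <- simulate(fit, nsim = 30, seed = 5, genotype = "GT2")
  pr2 <- predict(fit, sim2)
  expect_gte(mean(pr2$label == "GT2"), 0.9)
})

test_that("synthetic doublets are overwhelmingly re-identified as doublets", {
  s <- small_mixture(n_total = 300, minor = 120, seed = 95, ambient = 0)
  fit <- demultiplex(s$matrix, demux_config(seed = 95))
  x <- filter_snvs(s$matrix)
  syn <- simulate_doublet_profiles(x, which(fit$labels == "GT1"),
                                   which(fit$labels == "GT2"), 300, seed = 9)
  synm <- allele_counts(x$sites[, c("chrom", "pos", "ref", "alt")],
                        sprintf("D%03d", 1:300), syn$alt, syn$total)
  pr <- predict(fit, synm)
  expect_gte(mean(pr$label == "doublet"), 0.85)
})
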