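# Toy allele-count builders and independent oracles used across the suite.

toy_sites <- function(n) {
  data.frame(chrom = rep_len(c("1", "2", "MT"), n),
             pos = 100L * seq_len(n),
             ref = rep_len(c("A", "C", "G"), n),
             alt = rep_len(c("G", "T", "A"), n),
             stringsAsFactors = FALSE)
}

toy_counts <- function(alt, total, barcodes = NULL) {
  alt <- as.matrix(alt); total <- as.matrix(total)
  if (is.null(barcodes)) barcodes <- sprintf("BC%03d-1", seq_len(ncol(alt)))
  allele_counts(toy_sites(nrow(alt)), barcodes, alt, total)
}

# a small, well-separated two-genotype mixture for fast end-to-end tests
small_mixture <- function(n_total = 300, minor = 60, ambient = 0, seed = 7,
                          n_sites = 200, doublet_rate = 0.10) {
  simulate_sample(sim_config(n_total = n_total, n_sites = n_sites,
                             doublet_rate = doublet_rate, seed = seed),
                  minor_count = minor, ambient_rate = ambient, seed = seed)
}

# brute-force one-vs-rest confusion oracle (independent of tpr_fdr)
oracle_confusion <- function(pred, truth, class) {
  tp <- fp <- fn <- 0L
  for (i in seq_along(pred)) {
    if (class == "singlet") {
      p_in <- pred[i] %in% c("GT1", "GT2"); t_in <- truth[i] %in% c("GT1", "GT2")
      if (t_in && p_in && pred[i] == truth[i]) tp <- tp + 1L
      else if (p_in && (!t_in || pred[i] != truth[i])) {
        fp <- fp + 1L
        if (t_in) fn <- fn + 1L
      } else if (t_in) fn <- fn + 1L
    } else {
      if (pred[i] == class && truth[i] == class) tp <- tp + 1L
      else if (pred[i] == class) fp <- fp + 1L
      else if (truth[i] == class) fn <- fn + 1L
    }
  }
  list(tp = tp, fp = fp, fn = fn)
}

# pair-counting ARI oracle: explicit loop over item pairs, independent of the
# contingency-table route used by ari()
oracle_ari <- function(a, b) {
  n <- length(a)
  n11 <- n00 <- n10 <- n01 <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    sa <- a[i] == a[j]; sb <- b[i] == b[j]
    if (sa && sb) n11 <- n11 + 1
    else if (sa && !sb) n10 <- n10 + 1
    else if (!sa && sb) n01 <- n01 + 1
    else n00 <- n00 + 1
  }
  den <- (n11 + n10) * (n10 + n00) + (n11 + n01) * (n01 + n00)
  if (den == 0) return(1)
  2 * (n11 * n00 - n10 * n01) / den
}

# all set partitions of seq_len(n) as integer membership vectors
all_partitions <- function(n) {
  if (n == 1) return(list(1L))
  smaller <- all_partitions(n - 1)
  out <- list()
  for (p in smaller) {
    k <- max(p)
    for (g in seq_len(k + 1)) out[[length(out) + 1L]] <- c(p, g)
  }
  out
}
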