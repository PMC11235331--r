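#' Match arbitrary genotype labels to ground truth
#'
#' Genotype labels are arbitrary up to permutation: this picks the GT1/GT2
#' mapping that maximises singlet agreement with the truth labels. `doublet`
#' and `unassigned` are never permuted. Ties keep the identity mapping.
#'
#' @param predicted,truth label vectors (character or factor) over the same
#'   barcodes, using levels GT1/GT2/doublet/unassigned.
#' @return A named character vector mapping predicted labels to matched
#'   labels, e.g. `c(GT1 = "GT2", GT2 = "GT1")` for a swap.
#' @export
match_labels <- function(predicted, truth) {
  predicted <- as.character(predicted); truth <- as.character(truth)
  if (length(predicted) != length(truth))
    stop("predicted and truth must cover the same barcodes")
  id <- sum(predicted == truth & predicted %in% c("GT1", "GT2"))
  swapped <- ifelse(predicted == "GT1", "GT2",
                    ifelse(predicted == "GT2", "GT1", predicted))
  sw <- sum(swapped == truth & swapped %in% c("GT1", "GT2"))
  if (sw > id) c(GT1 = "GT2", GT2 = "GT1", doublet = "doublet",
                 unassigned = "unassigned")
  else c(GT1 = "GT1", GT2 = "GT2", doublet = "doublet",
         unassigned = "unassigned")
}

apply_mapping <- function(labels, mapping) {
  labels <- as.character(labels)
  out <- mapping[labels]
  out[is.na(out)] <- labels[is.na(out)]
  unname(out)
}

#' One-vs-rest confusion summary for a label class
#'
#' True/false positives and negatives of `class` against ground truth after
#' label matching. Unassigned predictions count as false negatives for the
#' cell's true class and never as false positives. Undefined ratios (empty
#' denominators) are `NA`, never 0.
#'
#' @param predicted,truth label vectors over the same barcodes.
#' @param class one of `"GT1"`, `"GT2"`, `"doublet"`, or `"singlet"` (GT1 and
#'   GT2 pooled: a singlet is counted as a true positive only under its own
#'   matched genotype).
#' @param mapping label permutation from [match_labels] (computed if missing).
#' @return A list of class `confusion_summary`: `tp`, `fp`, `fn`, `tpr`,
#'   `fdr`, `class`, `mapping`.
#' @export
tpr_fdr <- function(predicted, truth, class = c("singlet", "GT1", "GT2", "doublet"),
                    mapping = match_labels(predicted, truth)) {
  class <- match.arg(class)
  pred <- apply_mapping(predicted, mapping)
  truth <- as.character(truth)
  if (class == "singlet") {
    tp <- sum(pred == truth & truth %in% c("GT1", "GT2"))
    fp <- sum(pred %in% c("GT1", "GT2") & pred != truth)
    fn <- sum(truth %in% c("GT1", "GT2")) - tp
    absent <- !any(truth %in% c("GT1", "GT2"))
  } else {
    tp <- sum(pred == class & truth == class)
    fp <- sum(pred == class & truth != class)
    fn <- sum(truth == class & pred != class)
    absent <- !any(truth == class)
  }
  structure(list(tp = tp, fp = fp, fn = fn,
                 tpr = if (absent || tp + fn == 0L) NA_real_ else tp / (tp + fn),
                 fdr = if (tp + fp == 0L) NA_real_ else fp / (tp + fp),
                 class = class, mapping = mapping),
            class = "confusion_summary")
}

#' @export
print.confusion_summary <- function(x, ...) {
  cat(sprintf("class %s: TP=%d FP=%d FN=%d  TPR=%s FDR=%s\n", x$class,
              x$tp, x$fp, x$fn,
              formatC(x$tpr, digits = 4, format = "f"),
              formatC(x$fdr, digits = 4, format = "f")))
  invisible(x)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected pair-counting agreement between two labelings of the same
#' cells, via the standard contingency-table formula. Permutation-invariant;
#' 1 for identical partitions, ~0 for independent ones.
#'
#' @param labels_a,labels_b label vectors over the same barcodes (any label
#'   alphabet).
#' @return A single number (`NaN` for fewer than 2 items).
#' @export
ari <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b))
    stop("labelings must cover the same barcodes")
  n <- length(labels_a)
  tab <- table(labels_a, labels_b)
  choose2 <- function(m) sum(choose(m, 2))
  sum_ij <- choose2(tab)
  sum_a <- choose2(rowSums(tab))
  sum_b <- choose2(colSums(tab))
  tot <- choose(n, 2)
  expected <- sum_a * sum_b / tot
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)   # both partitions trivial/identical
  (sum_ij - expected) / (max_index - expected)
}

#' Score demultiplexing results over a simulation grid
#'
#' Builds a per-grid-cell table of one-vs-rest TPR/FDR for the singlet
#' (pooled), GT1, GT2 and doublet classes, and aggregates means and sample
#' standard deviations stratified by minor count greater than 100 versus
#' less than or equal to 100.
#'
#' @param results a list (one element per grid cell) of lists with elements
#'   `replicate`, `minor_count`, `ambient_rate`, `predicted`, `truth` (a
#'   missing/NULL element yields an NA row, never a silently dropped one).
#' @return A list of class `grid_report`: `metrics` (long data.frame) and
#'   `aggregate` (per stratum x class means and SDs of TPR/FDR).
#' @export
grid_report <- function(results) {
  if (!length(results)) stop("empty assignment set: no grid results to score")
  classes <- c("singlet", "GT1", "GT2", "doublet")
  rows <- lapply(seq_along(results), function(k) {
    r <- results[[k]]
    if (is.null(r) || is.null(r$predicted)) {
      meta <- if (is.null(r)) list() else r[c("replicate", "minor_count", "ambient_rate")]
      meta <- lapply(stats::setNames(
        c("replicate", "minor_count", "ambient_rate"),
        c("replicate", "minor_count", "ambient_rate")),
        function(nm) if (is.null(meta[[nm]])) NA else meta[[nm]])
      return(data.frame(replicate = meta$replicate,
                        minor_count = meta$minor_count,
                        ambient_rate = meta$ambient_rate,
                        class = classes, tp = NA_integer_, fp = NA_integer_,
                        fn = NA_integer_, tpr = NA_real_, fdr = NA_real_,
                        stringsAsFactors = FALSE))
    }
    mapping <- match_labels(r$predicted, r$truth)
    do.call(rbind, lapply(classes, function(cl) {
      cs <- tpr_fdr(r$predicted, r$truth, cl, mapping)
      data.frame(replicate = r$replicate, minor_count = r$minor_count,
                 ambient_rate = r$ambient_rate, class = cl,
                 tp = cs$tp, fp = cs$fp, fn = cs$fn,
                 tpr = cs$tpr, fdr = cs$fdr, stringsAsFactors = FALSE)
    }))
  })
  metrics <- do.call(rbind, rows)
  metrics$stratum <- ifelse(metrics$minor_count > 100, "minor>100", "minor<=100")
  agg <- do.call(rbind, lapply(split(metrics,
                                     list(metrics$stratum, metrics$class),
                                     drop = TRUE), function(d) {
    data.frame(stratum = d$stratum[1], class = d$class[1], n_cells = nrow(d),
               mean_tpr = mean(d$tpr, na.rm = TRUE),
               sd_tpr = stats::sd(d$tpr[!is.na(d$tpr)]),
               mean_fdr = mean(d$fdr, na.rm = TRUE),
               sd_fdr = stats::sd(d$fdr[!is.na(d$fdr)]),
               stringsAsFactors = FALSE)
  }))
  rownames(agg) <- NULL
  structure(list(metrics = metrics, aggregate = agg), class = "grid_report")
}

#' @export
print.grid_report <- function(x, ...) {
  cat(sprintf("grid_report over %d grid cells\n",
              nrow(x$metrics) / length(unique(x$metrics$class))))
  print(x$aggregate, digits = 4)
  invisible(x)
}

# demultiplex one simulated sample and return the scoring payload grid_report
# expects; used by the grid benchmarks and the acceptance script
score_sim_sample <- function(sample, config = demux_config(seed = sample$provenance$seed)) {
  fit <- demultiplex(sample$matrix, config)
  list(replicate = sample$provenance$replicate,
       minor_count = sample$provenance$minor_count,
       ambient_rate = sample$provenance$ambient_rate,
       predicted = as.character(fit$labels),
       truth = as.character(sample$truth),
       second_genotype_found = fit$second_genotype_found)
}
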