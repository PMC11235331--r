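#' Rank SNVs by genotype predictiveness
#'
#' Scores each site by how well it separates the two assigned genotypes:
#' `|mean_af(GT1) - mean_af(GT2)| * min(breadth(GT1), breadth(GT2))`, where
#' the mean allele fraction of a group is taken over its covered cells and
#' breadth is the fraction of the group's cells with coverage at the site.
#' A site with opposite homozygous alleles covered in every cell scores 1;
#' a site with identical group means scores 0.
#'
#' @param x An [allele_counts] object.
#' @param assignment a `demux_fit`, or a label vector over the cells of `x`.
#' @return A data.frame of all sites sorted by descending score, ties broken
#'   by (chrom, pos); columns `site` (row index into `x`), `chrom`, `pos`,
#'   `score`, `d_af`, `breadth_gt1`, `breadth_gt2`.
#' @export
rank_snvs <- function(x, assignment) {
  labels <- if (inherits(assignment, "demux_fit")) as.character(assignment$labels)
            else as.character(assignment)
  stopifnot(length(labels) == length(x$barcodes))
  g1 <- which(labels == "GT1"); g2 <- which(labels == "GT2")
  if (!length(g1) || !length(g2))
    stop("nothing to contrast: both genotypes must be assigned to rank SNVs")
  stat <- function(cells) {
    tot <- x$total[, cells, drop = FALSE]
    alt <- x$alt[, cells, drop = FALSE]
    covered <- Matrix::rowSums(tot > 0)
    prof <- cell_maf_profiles(list(sites = x$sites, barcodes = x$barcodes[cells],
                                   alt = alt, total = tot))
    mean_af <- ifelse(covered > 0, Matrix::rowSums(prof$af) / pmax(covered, 1),
                      NA_real_)
    list(mean_af = mean_af, breadth = covered / length(cells))
  }
  s1 <- stat(g1); s2 <- stat(g2)
  d_af <- abs(s1$mean_af - s2$mean_af)
  d_af[is.na(d_af)] <- 0
  score <- d_af * pmin(s1$breadth, s2$breadth)
  ord <- order(-score, x$sites$chrom, x$sites$pos)
  data.frame(site = ord, chrom = x$sites$chrom[ord], pos = x$sites$pos[ord],
             score = score[ord], d_af = d_af[ord],
             breadth_gt1 = s1$breadth[ord], breadth_gt2 = s2$breadth[ord],
             stringsAsFactors = FALSE)
}

#' Greedy selection of an SNV panel covering every cell N times
#'
#' Greedily adds, from the ranked candidates, the site maximising
#' `score * residual coverage gain` (the number of still-deficient cells the
#' site covers), until every cell is covered by at least `N` selected sites or
#' no remaining site helps. Exact minimum set cover is NP-hard; this is the
#' standard greedy approximation, deterministic given its input (rank order
#' breaks ties).
#'
#' @param ranked output of [rank_snvs].
#' @param x the [allele_counts] the ranking was computed on.
#' @param N per-cell coverage target (default 5).
#' @return A list of class `predictive_set`: `sites` (selected row indices in
#'   selection order), `achieved` (per-cell coverage count), `feasible`, and
#'   `deficit` (named per-cell shortfall when infeasible).
#' @export
greedy_cover <- function(ranked, x, N = 5L) {
  if (N <= 0) stop("N must be positive")
  achieved <- rep(0L, length(x$barcodes))
  cand <- ranked[ranked$score > 0, , drop = FALSE]
  covd <- as.matrix(x$total[cand$site, , drop = FALSE] > 0)  # candidates x cells
  selected <- integer(0)
  avail <- rep(TRUE, nrow(cand))
  while (any(achieved < N) && any(avail)) {
    need <- achieved < N
    gains <- cand$score * rowSums(covd[, need, drop = FALSE]) * avail
    best <- which.max(gains)               # rank order breaks exact ties
    if (gains[best] <= 0) break
    selected <- c(selected, cand$site[best])
    achieved <- achieved + as.integer(covd[best, ])
    avail[best] <- FALSE
  }
  feasible <- all(achieved >= N)
  deficit <- pmax(0L, N - achieved)
  names(deficit) <- x$barcodes
  structure(list(sites = selected, achieved = achieved, feasible = feasible,
                 N = as.integer(N),
                 deficit = deficit[deficit > 0L]),
            class = "predictive_set")
}

#' @export
print.predictive_set <- function(x, ...) {
  cat(sprintf("predictive_set: %d SNVs, target coverage %d per cell, feasible = %s\n",
              length(x$sites), x$N, x$feasible))
  if (!x$feasible)
    cat(sprintf("  %d cell(s) below target (max deficit %d)\n",
                length(x$deficit), max(x$deficit)))
  invisible(x)
}

#' Dot-plot statistics of a predictive SNV panel
#'
#' For each (label group x selected SNV): the proportion of the group's cells
#' with coverage at the SNV (dot size) and the mean allele fraction over those
#' covered cells (dot colour; `NA` when no cell of the group is covered).
#' Doublets sit between the two genotypes' allele fractions at discriminating
#' sites, which is the visual signature of a correct two-genotype fit.
#'
#' @param x An [allele_counts] object.
#' @param assignment a `demux_fit` or a label vector.
#' @param pset a non-empty [greedy_cover] selection (or integer site indices).
#' @param cell_types optional per-cell annotation; rows become
#'   (label x cell type) groups.
#' @return A data.frame of class `dotplot_table` with columns `group`, `label`,
#'   `cell_type`, `snv`, `chrom`, `pos`, `cell_fraction`, `mean_af`,
#'   `group_size`.
#' @export
dotplot_table <- function(x, assignment, pset, cell_types = NULL) {
  labels <- if (inherits(assignment, "demux_fit")) as.character(assignment$labels)
            else as.character(assignment)
  sites <- if (inherits(pset, "predictive_set")) pset$sites else as.integer(pset)
  if (!length(sites)) stop("predictive set is empty")
  groups <- if (is.null(cell_types)) labels
            else paste(labels, as.character(cell_types), sep = " / ")
  prof <- cell_maf_profiles(x)
  out <- do.call(rbind, lapply(sort(unique(groups)), function(g) {
    cells <- which(groups == g)
    covs <- x$total[sites, cells, drop = FALSE] > 0
    ncov <- Matrix::rowSums(covs)
    af_sum <- Matrix::rowSums(prof$af[sites, cells, drop = FALSE])
    data.frame(group = g,
               label = labels[cells[1]],
               cell_type = if (is.null(cell_types)) NA_character_
                           else sub("^.* / ", "", g),
               snv = sites,
               chrom = x$sites$chrom[sites], pos = x$sites$pos[sites],
               cell_fraction = as.numeric(ncov) / length(cells),
               mean_af = ifelse(ncov > 0, af_sum / pmax(ncov, 1), NA_real_),
               group_size = length(cells),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  class(out) <- c("dotplot_table", "data.frame")
  out
}

#' Draw a dot plot of genotype-predictive SNVs
#'
#' Base-graphics rendering of a [dotplot_table]: SNVs as columns, label groups
#' as rows, dot area proportional to the group's covered-cell fraction and dot
#' colour encoding the mean allele fraction (blue = reference, red = alt).
#'
#' @param tab A `dotplot_table`.
#' @param max_cex maximum dot size.
#' @param main plot title.
#' @return Invisibly, `tab`.
#' @export
plot_dotplot <- function(tab, max_cex = 3, main = "Genotype-predictive SNVs") {
  groups <- sort(unique(tab$group))
  snvs <- unique(tab$snv)
  xi <- match(tab$snv, snvs)
  yi <- match(tab$group, groups)
  pal <- grDevices::colorRampPalette(c("#2166AC", "#F7F7F7", "#B2182B"))(101)
  col <- ifelse(is.na(tab$mean_af), NA,
                pal[pmin(101, pmax(1, round(tab$mean_af * 100) + 1))])
  op <- graphics::par(mar = c(7, 10, 3, 1))
  on.exit(graphics::par(op))
  graphics::plot(NA, xlim = c(0.5, length(snvs) + 0.5),
                 ylim = c(0.5, length(groups) + 0.5),
                 xaxt = "n", yaxt = "n", xlab = "", ylab = "", main = main)
  graphics::points(xi, yi, pch = 21, bg = col,
                   cex = max_cex * sqrt(pmax(tab$cell_fraction, 0)))
  graphics::axis(1, at = seq_along(snvs),
                 labels = paste0(tab$chrom[match(snvs, tab$snv)], ":",
                                 tab$pos[match(snvs, tab$snv)]),
                 las = 2, cex.axis = 0.7)
  graphics::axis(2, at = seq_along(groups), labels = groups, las = 1,
                 cex.axis = 0.8)
  invisible(tab)
}
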