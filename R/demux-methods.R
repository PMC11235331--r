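#' @export
print.demux_fit <- function(x, ...) {
  cat("Two-stage SNV genotype demultiplexing fit\n")
  cat(sprintf("  %d cells, %d SNV sites\n", length(x$barcodes), nrow(x$sites)))
  cat(sprintf("  second genotype found: %s\n", x$second_genotype_found))
  tab <- table(x$labels)
  cat("  labels: ", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  cat(sprintf("  refinement: %d iteration(s), converged = %s\n",
              x$n_iterations, x$converged))
  invisible(x)
}

#' Summarise a demultiplexing fit
#'
#' @param object A `demux_fit`.
#' @param ... ignored.
#' @return A list of class `summary.demux_fit`: label counts, eligibility
#'   counts, convergence diagnostics, genotype separation (mean absolute
#'   allele-fraction difference over mutually supported sites) and the
#'   configuration used.
#' @export
summary.demux_fit <- function(object, ...) {
  sep <- NA_real_
  if (object$second_genotype_found) {
    inf <- object$model$gt1$support > 0 & object$model$gt2$support > 0
    if (any(inf))
      sep <- mean(abs(object$model$gt1$af[inf] - object$model$gt2$af[inf]))
  }
  structure(list(n_cells = length(object$barcodes),
                 n_sites = nrow(object$sites),
                 label_counts = table(object$labels),
                 n_eligible = sum(object$scores$eligible),
                 second_genotype_found = object$second_genotype_found,
                 n_iterations = object$n_iterations,
                 converged = object$converged,
                 genotype_separation = sep,
                 objective = object$objective,
                 config = object$config),
            class = "summary.demux_fit")
}

#' @export
print.summary.demux_fit <- function(x, ...) {
  cat("Two-stage SNV genotype demultiplexing\n")
  cat(sprintf("  cells: %d (%d discovery-eligible), sites: %d\n",
              x$n_cells, x$n_eligible, x$n_sites))
  cat(sprintf("  second genotype found: %s\n", x$second_genotype_found))
  print(x$label_counts)
  if (x$second_genotype_found)
    cat(sprintf("  genotype separation (mean |dAF|): %.3f\n", x$genotype_separation))
  cat(sprintf("  refinement: %d iteration(s), converged = %s\n",
              x$n_iterations, x$converged))
  if (length(x$objective))
    cat(sprintf("  final objective (log-likelihood): %.1f\n",
                utils::tail(x$objective, 1)))
  invisible(x)
}

#' Genotype allele-fraction estimates of a fit
#'
#' @param object A `demux_fit`.
#' @param ... ignored.
#' @return A numeric matrix, one row per SNV site, with columns `GT1`, `GT2`
#'   and `doublet` (the last two `NA` for single-genotype fits), rownames
#'   `chrom:pos`.
#' @export
coef.demux_fit <- function(object, ...) {
  n <- nrow(object$sites)
  out <- cbind(GT1 = object$model$gt1$af,
               GT2 = if (is.null(object$model$gt2)) rep(NA_real_, n) else object$model$gt2$af,
               doublet = if (is.null(object$model$dbl_af)) rep(NA_real_, n) else object$model$dbl_af)
  rownames(out) <- paste0(object$sites$chrom, ":", object$sites$pos)
  out
}

#' Classify new cells with a fitted genotype model
#'
#' Applies the fit's genotype profiles and doublet calibration threshold to a
#' new allele-count object over the same SNV panel (matched by chrom/pos/
#' ref/alt).
#'
#' @param object A `demux_fit` with two genotypes.
#' @param newdata An [allele_counts] over the same site panel.
#' @param ... ignored.
#' @return A data.frame with one row per new barcode: `barcode`, `label`,
#'   the three log-likelihoods, `margin` and `n_informative_sites`.
#' @export
predict.demux_fit <- function(object, newdata, ...) {
  stopifnot(inherits(newdata, "allele_counts"))
  if (!object$second_genotype_found)
    stop("cannot predict from a single-genotype fit")
  key_fit <- paste(object$sites$chrom, object$sites$pos,
                   object$sites$ref, object$sites$alt)
  key_new <- paste(newdata$sites$chrom, newdata$sites$pos,
                   newdata$sites$ref, newdata$sites$alt)
  if (!identical(key_fit, key_new))
    stop("newdata SNV panel differs from the panel the model was fitted on")
  cl <- classify_cells(newdata, object$model, object$config,
                       object$doublet_calibration)
  data.frame(barcode = newdata$barcodes, label = cl$label,
             loglik_gt1 = cl$ll[, 1], loglik_gt2 = cl$ll[, 2],
             loglik_doublet = cl$ll[, 3], margin = cl$margin,
             n_informative_sites = as.integer(sites_per_cell(newdata)),
             stringsAsFactors = FALSE)
}

#' Simulate singlet cells from a fitted genotype model
#'
#' Draws synthetic singlets whose allele counts follow the fitted per-site
#' allele fractions of one genotype, with per-cell coverage resampled from the
#' observed cells' covered-site counts. Useful for posterior-predictive style
#' sanity checks of a fit.
#'
#' @param object A `demux_fit`.
#' @param nsim number of cells to simulate.
#' @param seed RNG seed.
#' @param genotype `"GT1"` or `"GT2"`.
#' @param ... ignored.
#' @return An [allele_counts] object of simulated cells.
#' @export
simulate.demux_fit <- function(object, nsim = 1, seed = 1L,
                               genotype = c("GT1", "GT2"), ...) {
  genotype <- match.arg(genotype)
  prof <- if (genotype == "GT1") object$model$gt1 else object$model$gt2
  if (is.null(prof)) stop("fit has no ", genotype, " profile")
  n_sites <- nrow(object$sites)
  cov_pool <- pmax(1L, as.integer(object$scores$n_informative_sites))
  with_seed(seed, {
    ncov <- sample(cov_pool, nsim, replace = TRUE)
    trips <- lapply(seq_len(nsim), function(j) {
      s <- sample.int(n_sites, min(ncov[j], n_sites))
      tot <- 1L + stats::rpois(length(s), 1)
      alt <- stats::rbinom(length(s), tot, clamp_af(prof$af[s], 1e-6))
      cbind(i = s, j = rep(j, length(s)), tot = tot, alt = alt)
    })
    tr <- do.call(rbind, trips)
    allele_counts(object$sites[, c("chrom", "pos", "ref", "alt")],
                  sprintf("SIM-%s-%d", genotype, seq_len(nsim)),
                  alt = Matrix::sparseMatrix(tr[, "i"], tr[, "j"], x = tr[, "alt"],
                                             dims = c(n_sites, nsim)),
                  total = Matrix::sparseMatrix(tr[, "i"], tr[, "j"], x = tr[, "tot"],
                                               dims = c(n_sites, nsim)))
  })
}

#' Dot plot of genotype-predictive SNVs for a fit
#'
#' Selects a compact panel of genotype-predictive SNVs ([rank_snvs],
#' [greedy_cover]) and draws the dot-plot validation figure: one column per
#' SNV, one row per label group, dot size = proportion of the group's cells
#' with coverage, dot colour = mean allele fraction.
#'
#' @param x A `demux_fit` with two genotypes.
#' @param counts the [allele_counts] object the model was fitted on.
#' @param n_cover per-cell coverage target for the SNV panel (default 5).
#' @param cell_types optional per-cell annotation (splits label rows).
#' @param ... passed to [plot_dotplot].
#' @return Invisibly, the [dotplot_table] drawn.
#' @export
plot.demux_fit <- function(x, counts, n_cover = 5L, cell_types = NULL, ...) {
  ranked <- rank_snvs(counts, x)
  pset <- greedy_cover(ranked, counts, N = n_cover)
  tab <- dotplot_table(counts, x, pset, cell_types = cell_types)
  plot_dotplot(tab, ...)
  invisible(tab)
}
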