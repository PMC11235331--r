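#' SNV filter configuration
#'
#' Thresholds for the minimal SNV filter applied before demultiplexing or
#' before exporting demultiplexer input. Defaults: sites whose mean minor
#' allele fraction across covered cells exceeds 0.999 (apparently homozygous
#' in every cell, hence uninformative), sites covered in fewer than 10 cells,
#' and sites with fewer than 5 cells carrying an alternative-allele read are
#' removed.
#'
#' @param max_mean_maf maximum mean allele fraction over covered cells.
#' @param min_cells_covered minimum number of cells with coverage.
#' @param min_cells_with_alt minimum number of cells with >= 1 alt read.
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(max_mean_maf = 0.999,
                          min_cells_covered = 10L,
                          min_cells_with_alt = 5L) {
  stopifnot(max_mean_maf >= 0, max_mean_maf <= 1,
            min_cells_covered >= 0, min_cells_with_alt >= 0)
  structure(list(max_mean_maf = max_mean_maf,
                 min_cells_covered = as.integer(min_cells_covered),
                 min_cells_with_alt = as.integer(min_cells_with_alt)),
            class = "filter_config")
}

#' Remove SNVs unlikely to be useful for demultiplexing
#'
#' Applies the three minimal filter rules of [filter_config] and returns a new
#' object restricted to surviving sites, order preserved. The mean minor
#' allele fraction of a site is the mean of `alt/total` over cells with
#' coverage at that site (cells without coverage do not enter the mean).
#' The operation is idempotent for a fixed configuration.
#'
#' @param x An [allele_counts] object.
#' @param config A [filter_config].
#' @return A filtered [allele_counts]; if no site survives, an empty matrix is
#'   returned with a warning (downstream demultiplexing refuses it).
#' @export
filter_snvs <- function(x, config = filter_config()) {
  stopifnot(inherits(x, "allele_counts"), inherits(config, "filter_config"))
  cells_covered <- Matrix::rowSums(x$total > 0)
  cells_with_alt <- Matrix::rowSums(x$alt > 0)
  prof <- cell_maf_profiles(x)
  mean_maf <- ifelse(cells_covered > 0,
                     Matrix::rowSums(prof$af) / pmax(1, cells_covered), 0)
  keep <- mean_maf <= config$max_mean_maf &
    cells_covered >= config$min_cells_covered &
    cells_with_alt >= config$min_cells_with_alt
  if (!any(keep)) {
    warning("all SNV sites removed by filtering; returning an empty matrix")
    out <- x
    out$sites <- x$sites[0, , drop = FALSE]
    out$alt <- x$alt[0, , drop = FALSE]
    out$total <- x$total[0, , drop = FALSE]
    return(out)
  }
  x[which(keep), ]
}
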