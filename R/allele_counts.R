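#' Per-cell allele-count container
#'
#' An `allele_counts` object holds sparse alternative-allele and total read
#' counts for a panel of expressed SNVs across cell barcodes, the universal
#' exchange object of the package. Rows are SNV sites, columns are cells.
#'
#' @param sites data.frame with columns `chrom` (character; `"MT"` allowed),
#'   `pos` (1-based integer position), `ref` and `alt` (single bases).
#' @param barcodes character vector of cell barcodes, one per matrix column.
#' @param alt,total sparse (or dense, coerced) integer count matrices of
#'   dimension `nrow(sites)` x `length(barcodes)`; `alt <= total` entrywise.
#'
#' @return An object of class `allele_counts`: a list with elements `sites`
#'   (data.frame, with a 0-based `id` column added), `barcodes`, `alt` and
#'   `total` (`dgCMatrix`).
#' @examples
#' sites <- data.frame(chrom = c("1", "MT"), pos = c(100L, 50L),
#'                     ref = c("A", "C"), alt = c("G", "T"))
#' m <- allele_counts(sites, c("AAA-1", "TTT-1"),
#'                    alt = matrix(0:3, 2), total = matrix(c(2L, 3L, 2L, 3L), 2))
#' dim(m)
#' @export
allele_counts <- function(sites, barcodes, alt, total) {
  stopifnot(is.data.frame(sites))
  need <- c("chrom", "pos", "ref", "alt")
  miss <- setdiff(need, names(sites))
  if (length(miss))
    stop("sites is missing column(s): ", paste(miss, collapse = ", "))
  sites <- data.frame(chrom = as.character(sites$chrom),
                      pos = as.integer(sites$pos),
                      ref = as.character(sites$ref),
                      alt = as.character(sites$alt),
                      stringsAsFactors = FALSE)
  barcodes <- as.character(barcodes)
  alt <- as_count_matrix(alt)
  total <- as_count_matrix(total)
  x <- structure(list(sites = sites, barcodes = barcodes,
                      alt = alt, total = total),
                 class = "allele_counts")
  validate_allele_counts(x)
}

as_count_matrix <- function(m) {
  m <- methods::as(methods::as(methods::as(m, "dMatrix"), "generalMatrix"),
                   "CsparseMatrix")
  Matrix::drop0(m)
}

validate_allele_counts <- function(x) {
  ns <- nrow(x$sites); nc <- length(x$barcodes)
  if (nc == 0L) stop("no cells: barcode list is empty")
  for (nm in c("alt", "total")) {
    d <- dim(x[[nm]])
    if (d[1] != ns || d[2] != nc)
      stop(sprintf("%s matrix is %d x %d but expected %d sites x %d cells",
                   nm, d[1], d[2], ns, nc))
    v <- x[[nm]]@x
    if (length(v) && (any(v < 0) || any(v != round(v))))
      stop(nm, " matrix must contain non-negative integer counts")
  }
  if (any(x$sites$pos < 1L)) stop("VCF positions must be 1-based (pos >= 1)")
  if (any(x$sites$ref == x$sites$alt))
    stop("ref and alt allele identical at site(s): ",
         paste(which(x$sites$ref == x$sites$alt)[1:min(3, sum(x$sites$ref == x$sites$alt))],
               collapse = ", "))
  key <- paste(x$sites$chrom, x$sites$pos, x$sites$ref, x$sites$alt)
  if (anyDuplicated(key))
    stop("duplicate SNV site(s) in panel: ", key[which(duplicated(key))[1]])
  bad <- x$alt - x$total
  if (length(bad@x) && any(bad@x > 0)) {
    ij <- Matrix::which(bad > 0, arr.ind = TRUE)
    stop(sprintf("alt count exceeds total count at site %d, cell %d (and %d more)",
                 ij[1, 1], ij[1, 2], nrow(ij) - 1L))
  }
  x$sites$id <- seq_len(ns) - 1L   # 0-based ordinal site ids
  rownames(x$alt) <- rownames(x$total) <- NULL
  x
}

#' @export
dim.allele_counts <- function(x) c(nrow(x$sites), length(x$barcodes))

#' @export
print.allele_counts <- function(x, ...) {
  cat(sprintf("allele_counts: %d SNV sites x %d cells\n",
              nrow(x$sites), length(x$barcodes)))
  cov <- length(x$total@x)
  cat(sprintf("  non-zero (site, cell) coverage entries: %d (%.2f%% dense)\n",
              cov, 100 * cov / max(1, prod(dim(x)))))
  invisible(x)
}

#' Subset an allele-count object by sites and/or cells
#'
#' @param x An `allele_counts` object.
#' @param i site (row) index vector.
#' @param j cell (column) index vector.
#' @param ... ignored.
#' @return A new `allele_counts` restricted to the selected sites/cells,
#'   order preserved as given.
#' @export
`[.allele_counts` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$sites))
  if (missing(j)) j <- seq_along(x$barcodes)
  allele_counts(x$sites[i, c("chrom", "pos", "ref", "alt"), drop = FALSE],
                x$barcodes[j],
                x$alt[i, j, drop = FALSE],
                x$total[i, j, drop = FALSE])
}

#' Per-cell allele-fraction profiles
#'
#' Computes the per-(site, cell) allele fraction `alt/total` wherever a cell
#' has coverage. Entries with zero total reads are structurally absent, not
#' zero: downstream distances distinguish "uncovered" from "reference allele".
#'
#' @param x An `allele_counts` object.
#' @return A list with `af` (sparse numeric matrix of fractions; explicit
#'   zeros retained at covered ref-homozygous entries via the paired mask) and
#'   `covered` (pattern of covered entries as a `dgCMatrix` of 0/1).
#' @export
cell_maf_profiles <- function(x) {
  covered <- x$total
  covered@x <- rep(1, length(covered@x))
  af <- x$total
  idx <- Matrix::summary(x$total)        # triplets of covered entries
  a <- x$alt[cbind(idx$i, idx$j)]
  af@x <- a / idx$x
  list(af = af, covered = covered)
}

# number of covered sites per cell
sites_per_cell <- function(x) {
  Matrix::colSums(x$total > 0)
}
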