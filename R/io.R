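#' Read per-cell allele counts in the cellSNP-style sparse layout
#'
#' Ingests a sites-only VCF, a pair of MatrixMarket matrices holding the
#' alternative-allele (AD) and total (DP) read counts with sites as rows and
#' cells as columns, and a plain-text barcode list (optionally gzipped).
#'
#' Multi-allelic VCF records (comma in ALT) are rejected: they are dropped
#' with a warning stating how many were removed, and the corresponding matrix
#' rows are dropped with them.
#'
#' @param vcf_path path to the VCF of SNV sites (one record per matrix row).
#' @param alt_mtx_path,total_mtx_path paths to MatrixMarket count matrices.
#' @param barcodes_path path to a one-barcode-per-line text file.
#' @return A validated [allele_counts] object.
#' @export
read_allele_counts <- function(vcf_path, alt_mtx_path, total_mtx_path,
                               barcodes_path) {
  for (p in c(vcf_path, alt_mtx_path, total_mtx_path, barcodes_path))
    if (!file.exists(p)) stop("input file not found: ", p)
  sites <- read_vcf_sites(vcf_path)
  alt <- Matrix::readMM(alt_mtx_path)
  total <- Matrix::readMM(total_mtx_path)
  barcodes <- readLines(barcodes_path)
  barcodes <- barcodes[nzchar(barcodes)]
  if (!length(barcodes)) stop("no cells: barcode file ", barcodes_path, " is empty")

  n_rec <- nrow(sites) + attr(sites, "n_multiallelic")
  if (nrow(alt) != n_rec || ncol(alt) != length(barcodes))
    stop(sprintf("format error in %s: matrix is %d x %d but VCF has %d records and %d barcodes given",
                 alt_mtx_path, nrow(alt), ncol(alt), n_rec, length(barcodes)))
  if (!all(dim(total) == dim(alt)))
    stop(sprintf("format error in %s: dimensions %d x %d disagree with %s (%d x %d)",
                 total_mtx_path, nrow(total), ncol(total),
                 alt_mtx_path, nrow(alt), ncol(alt)))
  keep <- attr(sites, "kept_rows")
  allele_counts(sites, barcodes,
                alt[keep, , drop = FALSE], total[keep, , drop = FALSE])
}

# Sites-only VCF -> data.frame(chrom, pos, ref, alt). Multi-allelic records
# are dropped (warning); attributes record the original record count and the
# surviving row indices so matrix rows can be subset to match.
read_vcf_sites <- function(path) {
  v <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                error = function(e) stop("parse error in VCF ", path, ": ",
                                         conditionMessage(e)))
  fix <- v@fix
  if (is.null(fix) || nrow(fix) == 0L) stop("VCF ", path, " contains no records")
  pos <- suppressWarnings(as.integer(fix[, "POS"]))
  bad <- which(is.na(pos) | !nzchar(fix[, "REF"]) | is.na(fix[, "ALT"]))
  if (length(bad))
    stop(sprintf("parse error in VCF %s at record %d: missing or non-numeric field",
                 path, bad[1]))
  multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
  if (any(multi))
    warning(sprintf("dropped %d multi-allelic record(s) from %s (only biallelic SNVs are supported)",
                    sum(multi), path))
  keep <- which(!multi)
  sites <- data.frame(chrom = as.character(fix[keep, "CHROM"]),
                      pos = pos[keep],
                      ref = as.character(fix[keep, "REF"]),
                      alt = as.character(fix[keep, "ALT"]),
                      stringsAsFactors = FALSE)
  attr(sites, "n_multiallelic") <- sum(multi)
  attr(sites, "kept_rows") <- keep
  sites
}

write_sites_vcf <- function(sites, path) {
  hdr <- c("##fileformat=VCFv4.2",
           "##source=txdemux",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  rec <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.",
                 sites$chrom, sites$pos, sites$ref, sites$alt)
  writeLines(c(hdr, rec), path)
  invisible(path)
}

write_mtx_int <- function(m, path) {
  Matrix::writeMM(as_count_matrix(m), path)
  invisible(path)
}

#' Write an allele-count object in the cellSNP-style layout
#'
#' Emits `cellSNP.base.vcf`, `cellSNP.tag.AD.mtx`, `cellSNP.tag.DP.mtx` and
#' `barcodes.tsv` under `out_dir`. [read_allele_counts] on these files is the
#' exact inverse (identical counts, site order and barcode order).
#'
#' @param x An [allele_counts] object.
#' @param out_dir output directory, created if needed.
#' @return Invisibly, a named character vector of the written paths.
#' @export
write_allele_counts <- function(x, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(vcf = file.path(out_dir, "cellSNP.base.vcf"),
             alt = file.path(out_dir, "cellSNP.tag.AD.mtx"),
             total = file.path(out_dir, "cellSNP.tag.DP.mtx"),
             barcodes = file.path(out_dir, "barcodes.tsv"))
  write_sites_vcf(x$sites, paths["vcf"])
  write_mtx_int(x$alt, paths["alt"])
  write_mtx_int(x$total, paths["total"])
  writeLines(x$barcodes, paths["barcodes"])
  invisible(paths)
}

#' Export demultiplexer input files
#'
#' Converts an allele-count object (typically post-[filter_snvs]) into the
#' input layout expected by other SNV demultiplexers:
#' \describe{
#'   \item{`vireo`}{the cellSNP layout: sites VCF + sparse AD/DP matrices +
#'     barcodes (identical to [write_allele_counts]); reading it back
#'     reproduces the object exactly.}
#'   \item{`souporcell`}{`alt.mtx` and `ref.mtx` (ref = total - alt,
#'     elementwise) plus `barcodes.tsv`.}
#' }
#'
#' @param x An [allele_counts] object with at least one site and one cell.
#' @param dialect `"vireo"` or `"souporcell"`.
#' @param out_dir output directory, created if needed.
#' @return Invisibly, the written file paths.
#' @export
export_demux_input <- function(x, dialect = c("vireo", "souporcell"), out_dir) {
  dialect <- match.arg(dialect)
  if (nrow(x$sites) == 0L)
    stop("cannot export an empty matrix (no SNV sites)")
  if (dialect == "vireo") return(write_allele_counts(x, out_dir))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(alt = file.path(out_dir, "alt.mtx"),
             ref = file.path(out_dir, "ref.mtx"),
             barcodes = file.path(out_dir, "barcodes.tsv"),
             vcf = file.path(out_dir, "sites.vcf"))
  write_mtx_int(x$alt, paths["alt"])
  write_mtx_int(x$total - x$alt, paths["ref"])
  writeLines(x$barcodes, paths["barcodes"])
  write_sites_vcf(x$sites, paths["vcf"])
  invisible(paths)
}
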