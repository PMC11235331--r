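test_that("constructor keeps dimensions and rejects inconsistent counts", {
  m <- toy_counts(alt = matrix(c(0, 1, 2, 0, 1, 1), 2, 3),
                  total = matrix(c(2, 2, 3, 1, 1, 2), 2, 3))
  expect_s3_class(m, "allele_counts")
  expect_equal(dim(m), c(2L, 3L))

  expect_error(toy_counts(alt = matrix(5, 1, 1), total = matrix(3, 1, 1)),
               "alt count exceeds total")
  expect_error(allele_counts(toy_sites(1), character(0),
                             matrix(0, 1, 0), matrix(0, 1, 0)),
               "no cells")
  expect_error(toy_counts(alt = matrix(-1, 1, 1), total = matrix(2, 1, 1)),
               "non-negative")
  dup <- toy_sites(2); dup[2, ] <- dup[1, ]
  expect_error(allele_counts(dup, "BC1", matrix(0, 2, 1), matrix(1, 2, 1)),
               "duplicate")
})

test_that("allele-fraction profiles are alt/total on covered entries only", {
  m <- toy_counts(alt = matrix(c(1, 5, 0), 3, 1),
                  total = matrix(c(4, 5, 0), 3, 1))
  prof <- cell_maf_profiles(m)
  expect_equal(prof$af[1, 1], 0.25)
  expect_equal(prof$af[2, 1], 1.0)
  # total = 0 entries are structurally absent, not zero
  expect_equal(Matrix::nnzero(prof$covered), 2)
  expect_equal(prof$covered[3, 1], 0)
})

test_that("write -> read round trip is the identity, bit-exact", {
  set.seed(42)
  total <- matrix(rpois(5 * 8, 2), 5, 8)
  alt <- matrix(rbinom(40, total, 0.4), 5, 8)
  m <- toy_counts(alt, total)
  d <- withr::local_tempdir()
  write_allele_counts(m, d)
  m2 <- read_allele_counts(file.path(d, "cellSNP.base.vcf"),
                           file.path(d, "cellSNP.tag.AD.mtx"),
                           file.path(d, "cellSNP.tag.DP.mtx"),
                           file.path(d, "barcodes.tsv"))
  expect_identical(m2$sites, m$sites)
  expect_identical(m2$barcodes, m$barcodes)
  expect_identical(as.matrix(m2$alt), as.matrix(m$alt))
  expect_identical(as.matrix(m2$total), as.matrix(m$total))
})

test_that("reader reports dimension mismatches, bad records and empty barcodes", {
  m <- toy_counts(alt = matrix(0:3, 2), total = matrix(c(2, 3, 2, 3), 2))
  d <- withr::local_tempdir()
  write_allele_counts(m, d)
  # barcode count disagreeing with the matrix
  writeLines(c("only-one"), file.path(d, "barcodes.tsv"))
  expect_error(read_allele_counts(file.path(d, "cellSNP.base.vcf"),
                                  file.path(d, "cellSNP.tag.AD.mtx"),
                                  file.path(d, "cellSNP.tag.DP.mtx"),
                                  file.path(d, "barcodes.tsv")),
               "format error.*AD", ignore.case = TRUE)
  writeLines(character(0), file.path(d, "barcodes.tsv"))
  expect_error(read_allele_counts(file.path(d, "cellSNP.base.vcf"),
                                  file.path(d, "cellSNP.tag.AD.mtx"),
                                  file.path(d, "cellSNP.tag.DP.mtx"),
                                  file.path(d, "barcodes.tsv")),
               "no cells")
  expect_error(read_allele_counts(file.path(d, "nope.vcf"),
                                  file.path(d, "cellSNP.tag.AD.mtx"),
                                  file.path(d, "cellSNP.tag.DP.mtx"),
                                  file.path(d, "barcodes.tsv")),
               "not found")
})

test_that("multi-allelic VCF records are rejected with a warning and a count", {
  d <- withr::local_tempdir()
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
               "1\t100\t.\tA\tG\t.\tPASS\t.",
               "1\t200\t.\tC\tT,G\t.\tPASS\t.",
               "2\t300\t.\tG\tA\t.\tPASS\t."),
             file.path(d, "sites.vcf"))
  Matrix::writeMM(methods::as(Matrix::Matrix(matrix(c(1, 0, 2, 1, 0, 1), 3, 2),
                                             sparse = TRUE), "generalMatrix"),
                  file.path(d, "ad.mtx"))
  Matrix::writeMM(methods::as(Matrix::Matrix(matrix(c(2, 1, 2, 1, 1, 2), 3, 2),
                                             sparse = TRUE), "generalMatrix"),
                  file.path(d, "dp.mtx"))
  writeLines(c("BC1", "BC2"), file.path(d, "bc.tsv"))
  expect_warning(
    m <- read_allele_counts(file.path(d, "sites.vcf"), file.path(d, "ad.mtx"),
                            file.path(d, "dp.mtx"), file.path(d, "bc.tsv")),
    "1 multi-allelic")
  expect_equal(nrow(m$sites), 2L)
  expect_equal(m$sites$pos, c(100L, 300L))
  expect_equal(as.vector(m$total[, 1]), c(2, 2))
})

test_that("SNV filter applies the three rules exactly (toy oracle)", {
  n_cells <- 50
  alt <- matrix(0, 3, n_cells); total <- matrix(0, 3, n_cells)
  # site 1: alt == total in all 20 covered cells -> mean mAF 1 > 0.999
  total[1, 1:20] <- 3; alt[1, 1:20] <- 3
  # site 2: covered in only 9 cells (alt present in >= 5)
  total[2, 1:9] <- 4; alt[2, 1:6] <- 2
  # site 3: covered in 50 cells, 30 with alt, mean mAF 0.4
  total[3, ] <- 5; alt[3, 1:30] <- rep(c(2, 4), 15) / 1  # af 0.4/0.8 mix
  alt[3, 1:30] <- 2; total[3, ] <- 5                     # af 0.4 in 30 cells
  m <- toy_counts(alt, total)
  f <- filter_snvs(m, filter_config())
  expect_equal(nrow(f$sites), 1L)
  expect_equal(f$sites$pos, m$sites$pos[3])
  # brute-force re-check of the three rules on every site
  keep_oracle <- vapply(1:3, function(s) {
    cov <- total[s, ] > 0
    mean_maf <- mean(alt[s, cov] / total[s, cov])
    mean_maf <= 0.999 && sum(cov) >= 10 && sum(alt[s, ] > 0) >= 5
  }, logical(1))
  expect_equal(which(keep_oracle), 3L)
})

test_that("filtering is idempotent and preserves site order", {
  s <- small_mixture(n_total = 120, minor = 30, seed = 9, n_sites = 120)
  f1 <- filter_snvs(s$matrix)
  f2 <- filter_snvs(f1)
  expect_identical(f1$sites, f2$sites)
  expect_identical(as.matrix(f1$alt), as.matrix(f2$alt))
  expect_true(!is.unsorted(match(paste(f1$sites$chrom, f1$sites$pos),
                                 paste(s$matrix$sites$chrom, s$matrix$sites$pos))))
  # brute-force per-site re-check of surviving count
  cfg <- filter_config()
  cov <- Matrix::rowSums(s$matrix$total > 0)
  withalt <- Matrix::rowSums(s$matrix$alt > 0)
  maf <- vapply(seq_len(nrow(s$matrix$sites)), function(i) {
    c <- s$matrix$total[i, ] > 0
    if (!any(c)) return(0)
    mean(s$matrix$alt[i, c] / s$matrix$total[i, c])
  }, numeric(1))
  expect_equal(nrow(f1$sites),
               sum(maf <= cfg$max_mean_maf & cov >= cfg$min_cells_covered &
                   withalt >= cfg$min_cells_with_alt))
})

test_that("removing every site warns and downstream stages refuse the result", {
  m <- toy_counts(alt = matrix(1, 2, 3), total = matrix(1, 2, 3))
  expect_warning(f <- filter_snvs(m), "all SNV sites removed")
  expect_equal(nrow(f$sites), 0L)
  expect_error(suppressWarnings(demultiplex(m)), "no SNV sites survive")
})

test_that("demultiplexer input export writes both dialects correctly", {
  set.seed(11)
  total <- matrix(rpois(4 * 6, 3), 4, 6)
  alt <- matrix(rbinom(24, total, 0.5), 4, 6)
  m <- toy_counts(alt, total)
  d <- withr::local_tempdir()
  export_demux_input(m, "vireo", file.path(d, "v"))
  m2 <- read_allele_counts(file.path(d, "v", "cellSNP.base.vcf"),
                           file.path(d, "v", "cellSNP.tag.AD.mtx"),
                           file.path(d, "v", "cellSNP.tag.DP.mtx"),
                           file.path(d, "v", "barcodes.tsv"))
  expect_identical(as.matrix(m2$alt), as.matrix(m$alt))
  expect_identical(as.matrix(m2$total), as.matrix(m$total))

  export_demux_input(m, "souporcell", file.path(d, "s"))
  ref <- Matrix::readMM(file.path(d, "s", "ref.mtx"))
  expect_identical(as.matrix(ref), as.matrix(m$total - m$alt))

  expect_error(export_demux_input(m, "cellranger", d))
  empty <- suppressWarnings(filter_snvs(toy_counts(matrix(1, 1, 2),
                                                   matrix(1, 1, 2))))
  expect_error(export_demux_input(empty, "vireo", d), "empty")
})
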