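test_that("CX report lines map to records and contexts filter", {
  f <- withr::local_tempfile(fileext = ".cx")
  writeLines(c("chr1\t100\t+\t5\t10\tCG\tCGT",
               "chr1\t150\t-\t0\t3\tCHG\tCAG",
               "chr2\t7\t+\t2\t2\tCHH\tCTT"), f)
  x <- read_cx_report(f)
  expect_equal(length(x), 3L)
  d <- meth_dt(x)
  expect_equal(d$chrom, c("chr1", "chr1", "chr2"))
  expect_equal(d[1, ], data.frame(chrom = "chr1", pos = 100L, strand = "+",
                                  readsM = 5, readsN = 10, context = "CG",
                                  stringsAsFactors = FALSE))
  cg <- read_cx_report(f, contexts = "CG")
  expect_equal(length(cg), 1L)
  expect_equal(meth_dt(cg)$context, "CG")
})

test_that("empty CX report gives empty dataset with a warning", {
  f <- withr::local_tempfile(fileext = ".cx")
  writeLines(character(0), f)
  expect_warning(x <- read_cx_report(f), "empty")
  expect_equal(length(x), 0L)
})

test_that("malformed CX lines are fatal with line numbers", {
  write_cx <- function(lines) {
    f <- tempfile(fileext = ".cx")
    writeLines(lines, f)
    f
  }
  good <- "chr1\t100\t+\t5\t10\tCG\tCGT"
  expect_error(read_cx_report(write_cx(c(good, "chr1\t200\t+\t11\t10\tCG\tCGA"))),
               "line 2.*exceed", class = "mdmr_data_error")
  expect_error(read_cx_report(write_cx("chr1\t100\t+\tfive\t10\tCG\tCGT")),
               "non-integer", class = "mdmr_data_error")
  expect_error(read_cx_report(write_cx("chr1\t100\t+\t5\t10\tCXX\tCGT")),
               "context", class = "mdmr_data_error")
  expect_error(read_cx_report(write_cx("chr1\t100\t+\t5\t10")),
               "7 tab-separated", class = "mdmr_data_error")
  expect_error(read_cx_report(write_cx(c(good, good))),
               "duplicate", class = "mdmr_data_error")
  # context label must match an N-free trinucleotide
  expect_error(read_cx_report(write_cx("chr1\t100\t+\t5\t10\tCHH\tCAG")),
               "inconsistent", class = "mdmr_data_error")
  # but an N suspends the check
  expect_silent(x <- read_cx_report(write_cx("chr1\t100\t+\t5\t10\tCHH\tCNG")))
  expect_error(read_cx_report(tempfile()), "not found",
               class = "mdmr_data_error")
})

test_that("write/read round trip preserves the dataset, also gzipped", {
  pair <- small_planted_pair(seed = 3, L = 2e4, n_dmrs = 1)
  x <- pair$condition1
  f <- withr::local_tempfile(fileext = ".cx")
  write_cx_report(x, f)
  expect_equal(meth_dt(read_cx_report(f)), meth_dt(x))
  # gzip, detected by magic bytes regardless of extension
  fgz <- withr::local_tempfile(fileext = ".txt")
  con <- gzfile(fgz, "wb")
  writeLines(readLines(f), con)
  close(con)
  expect_equal(meth_dt(read_cx_report(fgz)), meth_dt(x))
})

test_that("pooling replicates sums counts and is commutative/associative", {
  a <- mk_methylome(c(100, 200), c(5, 1), c(10, 4))
  b <- mk_methylome(100, 5, 10)
  ab <- pool_replicates(list(a, b))
  d <- meth_dt(ab)
  expect_equal(d$readsM, c(10, 1))
  expect_equal(d$readsN, c(20, 4))
  # identity
  expect_equal(meth_dt(pool_replicates(list(a))), meth_dt(a))
  # position only in replicate 2 contributes a zero-augmented sum
  expect_equal(d[d$pos == 200, c("readsM", "readsN")],
               data.frame(readsM = 1, readsN = 4, row.names = 2L))
  # commutativity / associativity on richer data
  p <- small_planted_pair(seed = 5, L = 2e4, n_dmrs = 1)
  x <- p$condition1; y <- p$condition2; z <- scramble_methylome(x, 1)
  expect_equal(meth_dt(pool_replicates(list(x, y, z))),
               meth_dt(pool_replicates(list(z, x, y))))
  expect_equal(meth_dt(pool_replicates(list(pool_replicates(list(x, y)), z))),
               meth_dt(pool_replicates(list(x, pool_replicates(list(y, z))))))
})

test_that("conflicting context labels at a shared position are fatal", {
  a <- mk_methylome(100, 5, 10, context = "CG", tri = "CGT")
  b <- mk_methylome(100, 5, 10, context = "CHH", tri = "CTT")
  expect_error(pool_replicates(list(a, b)), "conflicting",
               class = "mdmr_data_error")
})

test_that("symmetric CpG pairs pool onto the plus strand when asked", {
  x <- methylome(c("chr1", "chr1", "chr1"), c(10, 11, 50),
                 c("+", "-", "-"), c(3, 4, 1), c(6, 8, 2),
                 c("CG", "CG", "CG"))
  p <- meth_dt(pool_cpg_pairs(x))
  expect_equal(p[p$pos == 10, c("readsM", "readsN")],
               data.frame(readsM = 7, readsN = 14, row.names = 1L))
  expect_false(11 %in% p$pos)      # collapsed onto the partner
  expect_true(50 %in% p$pos)       # lone minus-strand CG kept
})


test_that("DMR export: TSV schema, BED coordinates and score clipping", {
  dmrs <- c(mk_dmr_granges(101, 200, adjp = 1),
            mk_dmr_granges(301, 350, adjp = 1e-120))
  ftsv <- withr::local_tempfile(fileext = ".tsv")
  fbed <- withr::local_tempfile(fileext = ".bed")
  write_dmrs(dmrs, ftsv, "tsv")
  write_dmrs(dmrs, fbed, "bed")
  tsv <- read.delim(ftsv)
  expect_equal(names(tsv),
               c("chrom", "start", "end", "context", "direction",
                 "readsM1", "readsN1", "readsM2", "readsN2",
                 "proportion1", "proportion2", "cytosinesCount",
                 "statistic", "pValue", "adjustedPValue"))
  bed <- read.delim(fbed, header = FALSE)
  # 1-based closed [101, 200] becomes 0-based half-open [100, 200)
  expect_equal(bed$V2, c(100, 300))
  expect_equal(bed$V3, c(200, 350))
  expect_equal(bed$V4, c("CG:loss", "CG:loss"))
  # -10 log10(1) = 0; p clipped at 1e-100 caps the score at 1000
  expect_equal(bed$V5, c(0, 1000))
  # widths agree between the two encodings
  expect_equal(sum(bed$V3 - bed$V2), sum(tsv$end - tsv$start + 1))
})

test_that("empty DMR sets export as header-only TSV and empty BED", {
  empty <- methylDMR:::.empty_dmrs()
  ftsv <- withr::local_tempfile(fileext = ".tsv")
  fbed <- withr::local_tempfile(fileext = ".bed")
  write_dmrs(empty, ftsv, "tsv")
  write_dmrs(empty, fbed, "bed")
  expect_equal(length(readLines(ftsv)), 1L)
  expect_equal(length(readLines(fbed)), 0L)
})

test_that("BED region annotations import as 1-based closed intervals", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t100\t200\tgeneA\t0\t+", f)
  r <- read_regions(f)
  expect_equal(GenomicRanges::start(r), 101L)
  expect_equal(GenomicRanges::end(r), 200L)
  expect_error(read_regions(tempfile(fileext = ".bed")), "not found",
               class = "mdmr_data_error")
  bad <- withr::local_tempfile(fileext = ".xyz")
  writeLines("x", bad)
  expect_error(read_regions(bad), class = "mdmr_usage_error")
})
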