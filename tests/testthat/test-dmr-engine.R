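cfg_fast <- function(method = "neighbourhood", test = "score", ...) {
  dmr_config(method, "CG", test, min_size = 1, ...)
}

test_that("candidate selection is the conjunction of the three conditions", {
  cfg <- dmr_config("bins", "CG")
  base <- data.frame(adjustedPValue = 0.01, proportion1 = 0.8,
                     proportion2 = 0.3, readsN1 = 50, readsN2 = 50,
                     cytosinesCount = 5)   # mean reads 10, |diff| 0.5
  expect_equal(nrow(select_units(base, cfg)), 1L)
  # exhaustive truth table: each predicate broken one at a time
  fail_p <- transform(base, adjustedPValue = 0.2)
  fail_d <- transform(base, proportion2 = 0.55)  # |diff| 0.25
  fail_r <- transform(base, readsN1 = 10, readsN2 = 10)  # mean reads 2
  grid <- expand.grid(p = c(TRUE, FALSE), d = c(TRUE, FALSE),
                      r = c(TRUE, FALSE))
  for (k in seq_len(nrow(grid))) {
    u <- base
    if (!grid$p[k]) u$adjustedPValue <- fail_p$adjustedPValue
    if (!grid$d[k]) u$proportion2 <- fail_d$proportion2
    if (!grid$r[k]) { u$readsN1 <- fail_r$readsN1; u$readsN2 <- fail_r$readsN2 }
    expect_equal(nrow(select_units(u, cfg)),
                 as.integer(grid$p[k] && grid$d[k] && grid$r[k]))
  }
})

test_that("identical samples yield no DMRs under any engine", {
  x <- small_planted_pair(seed = 2, L = 3e4, n_dmrs = 1)$condition1
  for (m in c("neighbourhood", "bins", "noise_filter"))
    expect_equal(length(call_dmrs(x, x, dmr_config(m, "CG"))), 0L)
})

test_that("neighbourhood calls a single fully differential cytosine", {
  a <- mk_methylome(c(100, 5000), c(20, 5), c(20, 10))
  b <- mk_methylome(c(100, 5000), c(0, 5), c(20, 10))
  d <- call_dmrs_neighbourhood(a, b, cfg_fast())
  expect_equal(length(d), 1L)
  expect_equal(GenomicRanges::start(d), 100)
  expect_equal(GenomicRanges::end(d), 100)
  mc <- S4Vectors::mcols(d)
  expect_equal(mc$direction, "loss")
  expect_equal(mc$readsM1, 20)
  expect_equal(mc$readsN2, 20)
  expect_lte(mc$adjustedPValue, 0.05)
})

test_that("complete loss turns every covered common cytosine into a DMC", {
  set.seed(9)
  pos <- sort(sample.int(5e4, 300))
  N1 <- rpois(300, 20) + 5
  N2 <- rpois(300, 20) + 5
  a <- mk_methylome(pos, rbinom(300, N1, 0.85), N1)
  b <- mk_methylome(pos, 0, N2)
  d <- call_dmrs_neighbourhood(a, b, cfg_fast(max_gap = 0))
  called <- GenomicRanges::start(d)
  # every cytosine whose proportion clears the 40% difference is called
  eligible <- pos[meth_dt(a)$readsM / N1 >= 0.4]
  expect_gte(mean(eligible %in% called), 0.97)
  expect_true(all(called %in% pos))
})

test_that("bins pool reads, trim to cytosine extent and skip one-sided bins", {
  # bin [1,100]: cytosines at 20 and 80, differential; bin [501,600]:
  # cytosine only covered in condition 1
  a <- mk_methylome(c(20, 80, 550), c(40, 40, 5), c(50, 50, 10))
  b <- mk_methylome(c(20, 80, 550), c(5, 5, 0), c(50, 50, 0))
  d <- call_dmrs_bins(a, b, dmr_config("bins", "CG", bin_size = 100,
                                       min_size = 10))
  expect_equal(length(d), 1L)
  expect_equal(GenomicRanges::start(d), 20)
  expect_equal(GenomicRanges::end(d), 80)
  mc <- S4Vectors::mcols(d)
  expect_equal(mc$readsM1, 80)    # pooled over the bin
  expect_equal(mc$readsN1, 100)
  expect_equal(mc$cytosinesCount, 2)
})

test_that("noise filter borrows strength for low-coverage positions", {
  pos <- c(100, 120, 140, 160, 180)
  a <- mk_methylome(pos, c(20, 20, 2, 20, 20), c(20, 20, 2, 20, 20))
  b <- mk_methylome(pos, 0, c(20, 20, 2, 20, 20))
  d <- call_dmrs_noise_filter(a, b, dmr_config("noise_filter", "CG",
                                               window_size = 100))
  expect_equal(length(d), 1L)
  # the 2-read cytosine is inside the called region
  expect_lte(GenomicRanges::start(d), 140)
  expect_gte(GenomicRanges::end(d), 140)
  expect_equal(S4Vectors::mcols(d)$regionType, "merged")
  # reported counts are raw sums over the region
  expect_equal(S4Vectors::mcols(d)$readsN1, 82)
})

test_that("merging re-tests pooled counts and respects direction and gap", {
  a <- mk_methylome(c(100, 102), c(10, 10), c(10, 10))
  b <- mk_methylome(c(100, 102), c(0, 0), c(10, 10))
  d <- call_dmrs_neighbourhood(a, b, cfg_fast())
  expect_equal(length(d), 1L)
  expect_equal(as.data.frame(d)$start, 100)
  expect_equal(as.data.frame(d)$end, 102)
  mc <- S4Vectors::mcols(d)
  expect_equal(mc$regionType, "merged")
  expect_equal(c(mc$readsM1, mc$readsN1, mc$readsM2, mc$readsN2),
               c(20, 20, 0, 20))
  # the merged p-value is the raw re-test of the pooled table
  expect_equal(mc$pValue,
               score_test_counts(20, 20, 0, 20)$pValue)
  # opposite directions never merge
  a2 <- mk_methylome(c(100, 102), c(10, 0), c(10, 10))
  b2 <- mk_methylome(c(100, 102), c(0, 10), c(10, 10))
  d2 <- call_dmrs_neighbourhood(a2, b2, cfg_fast())
  expect_equal(length(d2), 2L)
  expect_equal(S4Vectors::mcols(d2)$direction, c("loss", "gain"))
  # far-apart candidates stay apart
  a3 <- mk_methylome(c(100, 1000), c(10, 10), c(10, 10))
  b3 <- mk_methylome(c(100, 1000), c(0, 0), c(10, 10))
  d3 <- call_dmrs_neighbourhood(a3, b3, cfg_fast(max_gap = 200))
  expect_equal(length(d3), 2L)
})

test_that("merge_dmrs rejects overlapping candidates", {
  a <- mk_methylome(c(100, 102), c(10, 10), c(10, 10))
  b <- mk_methylome(c(100, 102), c(0, 0), c(10, 10))
  overlapping <- GenomicRanges::GRanges(
    seqnames = "chr1", ranges = IRanges::IRanges(c(100, 101), c(102, 110)),
    direction = "loss", statistic = 0, pValue = 0.01,
    adjustedPValue = 0.01, regionType = "cytosine")
  expect_error(merge_dmrs(overlapping, a, b, cfg_fast()),
               "overlapping", class = "mdmr_data_error")
})

test_that("size and cytosine-count filters act as configured", {
  d1 <- mk_dmr_granges(100, 100)           # width 1
  d120 <- mk_dmr_granges(100, 219)         # width 120, 5 cytosines
  cfg <- dmr_config("bins", "CG")          # min_size 50, min_cytosines 1
  expect_equal(length(filter_dmrs(d1, cfg)), 0L)
  expect_equal(length(filter_dmrs(d120, cfg)), 1L)
  cfg2 <- dmr_config("bins", "CG", min_size = 1, min_cytosines = 1)
  both <- c(d1, d120)
  expect_equal(length(filter_dmrs(both, cfg2)), 2L)
  cfg6 <- dmr_config("bins", "CG", min_size = 1, min_cytosines = 6)
  expect_equal(length(filter_dmrs(both, cfg6)), 0L)
})

test_that("genome coverage sums widths and rejects overlap", {
  gr <- GenomicRanges::GRanges("chr1",
                               IRanges::IRanges(c(101, 301), c(200, 350)))
  expect_equal(dmr_genome_coverage(gr), 150)
  expect_equal(dmr_genome_coverage(gr[0]), 0)
  bad <- GenomicRanges::GRanges("chr1",
                                IRanges::IRanges(c(101, 150), c(200, 250)))
  expect_error(dmr_genome_coverage(bad), class = "mdmr_data_error")
  # per-base occupancy oracle on random non-overlapping intervals
  set.seed(4)
  starts <- sort(sample.int(1e5, 500)) * 10
  widths <- sample(1:9, 500, TRUE)
  rnd <- GenomicRanges::GRanges("chr1",
                                IRanges::IRanges(starts, starts + widths - 1))
  occupied <- unique(unlist(Map(seq, starts, starts + widths - 1)))
  expect_equal(dmr_genome_coverage(rnd), length(occupied))
})

test_that("emitted DMRs satisfy the configured thresholds", {
  pair <- small_planted_pair(seed = 31, L = 2e5, n_dmrs = 4)
  for (m in c("neighbourhood", "bins", "noise_filter")) {
    cfg <- dmr_config(m, "CG")
    d <- call_dmrs(pair$condition1, pair$condition2, cfg)
    expect_gt(length(d), 0)
    df <- as.data.frame(d)
    expect_true(all(df$width >= cfg$min_size))
    expect_true(all(df$cytosinesCount >= cfg$min_cytosines))
    expect_true(all(df$adjustedPValue <= cfg$p_value))
    # sorted and non-overlapping
    expect_true(all(diff(df$start) > 0))
    expect_equal(dmr_genome_coverage(d), sum(df$width))
    # merged regions were re-checked on raw pooled counts
    mg <- df[df$regionType == "merged", ]
    expect_true(all(abs(mg$proportion2 - mg$proportion1) >= cfg$min_diff))
    expect_true(all((mg$readsN1 + mg$readsN2) / (2 * mg$cytosinesCount) >=
                      cfg$min_reads))
    expect_true(all(mg$pValue <= cfg$p_value))
  }
})

test_that("calls are deterministic and independent of input row order", {
  pair <- small_planted_pair(seed = 13, L = 1e5, n_dmrs = 2)
  cfg <- dmr_config("bins", "CG")
  d1 <- call_dmrs(pair$condition1, pair$condition2, cfg)
  d2 <- call_dmrs(pair$condition1, pair$condition2, cfg)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_dmrs(d1, f1); write_dmrs(d2, f2)
  expect_identical(readLines(f1), readLines(f2))
  # shuffling record order (two interleaved chromosomes) changes nothing
  shuffle <- function(x) {
    dt <- meth_dt(x)
    o <- sample(nrow(dt))
    methylome(dt$chrom[o], dt$pos[o], dt$strand[o], dt$readsM[o],
              dt$readsN[o], dt$context[o])
  }
  two_chrom <- function(x) {
    dt <- meth_dt(x)
    half <- dt$pos > 5e4
    methylome(ifelse(half, "chr2", "chr1"), ifelse(half, dt$pos - 5e4, dt$pos),
              dt$strand, dt$readsM, dt$readsN, dt$context)
  }
  a <- two_chrom(pair$condition1); b <- two_chrom(pair$condition2)
  set.seed(1)
  d3 <- call_dmrs(a, b, cfg)
  d4 <- call_dmrs(shuffle(a), shuffle(b), cfg)
  expect_equal(as.data.frame(d3), as.data.frame(d4))
})

test_that("beta regression engine needs replicates and finds dense signal", {
  pair <- small_planted_pair(seed = 41, L = 2e4, n_dmrs = 1)
  expect_error(call_dmrs(pair$condition1, pair$condition2,
                         dmr_config("bins", "CG", "beta_regression")),
               class = "mdmr_usage_error")
  # three replicates per condition over a mostly differential genome
  L <- 3e4
  mkrep <- function(seed) generate_pair(synthetic_spec(
    L, "CG", data.frame(start = 1000, end = 21000, context = "CG",
                        target = 0), seed = seed))
  ps <- lapply(c(61, 62, 63), mkrep)
  d1 <- lapply(ps, `[[`, "condition1")
  d2 <- lapply(ps, `[[`, "condition2")
  d <- call_dmrs(d1, d2, dmr_config("bins", "CG", "beta_regression"))
  expect_gt(dmr_genome_coverage(d), 0)
  expect_gt(recovered_fraction(d, ps[[1]]$truth), 0.3)
  expect_lt(false_fraction(d, ps[[1]]$truth), 0.1)
})
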