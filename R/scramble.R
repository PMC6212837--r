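#' @title Scrambled-methylome null and window-size selection
#' @name scramble_select
NULL

# run code with a private RNG stream, restoring the caller's state
.with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

# deterministic sub-seed from a base seed and a text label (< 2^31)
.sub_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 1000003 + h) %% 2147483647)
}

#' Scramble a methylome
#'
#' Builds a null methylome by randomly permuting the per-cytosine
#' `(readsM, readsN)` count pairs over the positions of each methylation
#' context (genome-wide, within the sample). Positions, strands, contexts
#' and trinucleotides stay in place, so the multiset of count pairs per
#' context -- and hence the global methylation level and the coverage
#' distribution -- is exactly preserved while any association between
#' methylation and position is destroyed.
#'
#' @param data a methylome `GRanges`.
#' @param seed integer seed; the permutation is deterministic given the
#'   seed.
#' @return the scrambled methylome.
#' @export
scramble_methylome <- function(data, seed) {
  dt <- .as_dt(data)
  .with_seed(seed, {
    for (cx in unique(dt$ctx)) {
      idx <- which(dt$ctx == cx)
      perm <- idx[sample.int(length(idx))]
      data.table::set(dt, i = idx, j = "M", value = dt$M[perm])
      data.table::set(dt, i = idx, j = "N", value = dt$N[perm])
    }
  })
  .from_dt(dt, sample = paste0(S4Vectors::metadata(data)$sample,
                               ":scrambled"))
}

#' Global methylation level per context
#'
#' `sum(readsM) / sum(readsN)` per context; a position-free summary that
#' scrambling preserves exactly.
#'
#' @param data a methylome `GRanges`.
#' @return a named numeric vector, one entry per context present.
#' @export
global_methylation <- function(data) {
  dt <- .as_dt(data)
  s <- dt[, list(level = sum(M) / sum(N)), by = "ctx"]
  stats::setNames(s$level, s$ctx)
}

#' Select the window/bin size with a scrambled-methylome null
#'
#' For each candidate size, calls DMRs on the real sample pair and on a
#' scrambled pair (each sample permuted independently with seeds derived
#' from `seed`), and records the DMR genome coverage of both. The
#' difference `coverage_real - coverage_scrambled` balances sensitivity
#' (large real coverage) against accuracy (small scrambled coverage);
#' the selected size maximises it, ties broken toward the smaller size.
#'
#' The scrambled null is only meaningful when the two samples have
#' similar global methylation in the analysed context; a warning is
#' issued when the levels differ by more than 0.10.
#'
#' @param data1,data2 methylome `GRanges` (or replicate lists; replicates
#'   are pooled before scrambling).
#' @param cfg a [dmr_config()]; its window/bin size and merge gap are
#'   overridden by each candidate size (gap = twice the size).
#' @param sizes candidate window/bin sizes in bp.
#' @param seed integer seed for the scrambling permutations.
#' @return a list with `table` (data.frame: size, coverage_real,
#'   coverage_scrambled, difference) and `size` (the selected size).
#' @export
select_window_size <- function(data1, data2, cfg, sizes, seed = 1L) {
  stopifnot(inherits(cfg, "dmr_config"))
  if (length(sizes) == 0L) mdmr_usage_error("empty size list")
  pooled1 <- .as_condition(data1, "condition1")$pooled
  pooled2 <- .as_condition(data2, "condition2")$pooled
  g1 <- global_methylation(pooled1)[cfg$context]
  g2 <- global_methylation(pooled2)[cfg$context]
  if (is.finite(g1) && is.finite(g2) && abs(g1 - g2) > 0.10)
    warning(sprintf(
      paste("global %s methylation differs by %.2f between samples;",
            "the scrambled null assumes similar global levels"),
      cfg$context, abs(g1 - g2)))
  s1 <- scramble_methylome(pooled1, .sub_seed(seed, "condition1"))
  s2 <- scramble_methylome(pooled2, .sub_seed(seed, "condition2"))
  sizes <- sort(unique(as.numeric(sizes)))
  tab <- data.frame(size = sizes, coverage_real = NA_real_,
                    coverage_scrambled = NA_real_, difference = NA_real_)
  for (k in seq_along(sizes)) {
    cfg_k <- .with_size(cfg, sizes[k])
    tab$coverage_real[k] <-
      dmr_genome_coverage(call_dmrs(pooled1, pooled2, cfg_k))
    tab$coverage_scrambled[k] <-
      dmr_genome_coverage(call_dmrs(s1, s2, cfg_k))
  }
  tab$difference <- tab$coverage_real - tab$coverage_scrambled
  list(table = tab, size = sizes[which.max(tab$difference)])
}
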