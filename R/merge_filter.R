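#' @title Merging, filtering and coverage of DMRs
#' @name merge_filter
NULL

# scalar raw pooled counts over one interval (lean path for the merge loop)
.region_counts1 <- function(ri, chr, s, e) {
  ci <- ri$idx[[chr]]
  if (is.null(ci)) {
    out <- as.list(stats::setNames(rep(0, length(ri$cols)), ri$cols))
    out$cyt <- 0
    return(out)
  }
  hi <- findInterval(e, ci$pos)
  lo <- findInterval(s - 1, ci$pos)
  out <- lapply(ri$cols, function(cn) {
    cs <- ci[[cn]]
    (if (hi > 0) cs[hi] else 0) - (if (lo > 0) cs[lo] else 0)
  })
  names(out) <- ri$cols
  out$cyt <- hi - lo
  out
}

# test a merged region on its raw pooled counts (rc a named list of
# pooled counts); returns list(statistic, pValue, proportion1/2,
# direction); NA p-value when the region is untestable
.test_region <- function(rc, cfg, rep_cols = NULL) {
  p1 <- if (rc$N1 > 0) rc$M1 / rc$N1 else NA_real_
  p2 <- if (rc$N2 > 0) rc$M2 / rc$N2 else NA_real_
  out <- list(statistic = NA_real_, pValue = NA_real_,
              proportion1 = p1, proportion2 = p2,
              direction = if (is.na(p1) || is.na(p2) || p1 == p2) NA_character_
                          else if (p2 > p1) "gain" else "loss")
  if (is.na(p1) || is.na(p2)) return(out)
  if (cfg$test == "beta_regression") {
    Ms <- unlist(rc[c(rep_cols$m1, rep_cols$m2)], use.names = FALSE)
    Ns <- unlist(rc[c(rep_cols$n1, rep_cols$n2)], use.names = FALSE)
    if (all(Ns > 0)) {
      grp <- rep(c("c1", "c2"), c(length(rep_cols$m1), length(rep_cols$m2)))
      r <- tryCatch(beta_regression_test(Ms / Ns, grp,
                                         p_method = cfg$beta_p_method),
                    error = function(e) NULL)
      if (!is.null(r) && isTRUE(r$converged)) {
        out$statistic <- r$statistic
        out$pValue <- r$pValue
      }
    }
  } else if (cfg$test == "fisher") {
    m1 <- .round_half_up(rc$M1); n1 <- .round_half_up(rc$N1)
    m2 <- .round_half_up(rc$M2); n2 <- .round_half_up(rc$N2)
    K <- m1 + m2
    supp <- max(0, K - n2):min(K, n1)
    pr <- stats::dhyper(supp, n1, n2, K)
    pobs <- pr[match(m1, supp)]
    out$statistic <- m1
    out$pValue <- min(1, sum(pr[pr <= pobs * (1 + 1e-7)]))
  } else {
    phat <- (rc$M1 + rc$M2) / (rc$N1 + rc$N2)
    v <- phat * (1 - phat) * (1 / rc$N1 + 1 / rc$N2)
    z <- if (v > 0) (p1 - p2) / sqrt(v) else 0
    out$statistic <- z
    out$pValue <- 2 * stats::pnorm(-abs(z))
  }
  out
}

# iterative left-to-right merging of sorted, non-overlapping candidates.
# Adjacent same-direction candidates with gap <= max_gap are joined when
# the merged region, on its raw pooled counts, still satisfies the raw
# p-value cutoff and conditions (ii) and (iii). After a merge the scan
# continues from the merged region; passes repeat until stable.
# Linked-list sweep: each merge is O(1) bookkeeping plus one region test.
.merge_candidates <- function(cand, ri, cfg, rep_cols = NULL) {
  n <- nrow(cand)
  if (n == 0L) return(cand)
  chrom <- cand$chrom; start <- cand$start; end <- cand$end
  dir <- cand$direction; stat <- cand$statistic
  pval <- cand$pValue; padj <- cand$padj; rtype <- cand$regionType
  same <- chrom[-n] == chrom[-1]
  if (n > 1L && any(same & (start[-1] <= end[-n])))
    mdmr_data_error("overlapping candidate DMRs (upstream bug)")
  nxt <- c(seq_len(n)[-1], NA_integer_)
  alive <- rep(TRUE, n)
  repeat {
    changed <- FALSE
    i <- 1L
    while (!is.na(i) && !is.na(nxt[i])) {
      j <- nxt[i]
      gap <- start[j] - end[i] - 1
      ok <- FALSE
      if (chrom[i] == chrom[j] && gap <= cfg$max_gap &&
          !is.na(dir[i]) && !is.na(dir[j]) && dir[i] == dir[j]) {
        rc <- .region_counts1(ri, chrom[i], start[i], end[j])
        res <- .test_region(rc, cfg, rep_cols)
        mean_reads <- (rc$N1 + rc$N2) / (2 * max(rc$cyt, 1))
        ok <- !is.na(res$pValue) && res$pValue <= cfg$p_value &&
          !is.na(res$direction) && res$direction == dir[i] &&
          abs(res$proportion2 - res$proportion1) >= cfg$min_diff &&
          mean_reads >= cfg$min_reads
      }
      if (ok) {
        end[i] <- end[j]
        stat[i] <- res$statistic
        pval[i] <- res$pValue
        padj[i] <- min(padj[i], padj[j])
        rtype[i] <- "merged"
        alive[j] <- FALSE
        nxt[i] <- nxt[j]
        changed <- TRUE
        # stay on i: try to extend the merged region further
      } else {
        i <- j
      }
    }
    if (!changed) break
  }
  keep <- which(alive)
  data.table::data.table(chrom = chrom[keep], start = start[keep],
                         end = end[keep], direction = dir[keep],
                         statistic = stat[keep], pValue = pval[keep],
                         padj = padj[keep], regionType = rtype[keep])
}

#' Merge neighbouring candidate DMRs
#'
#' Iteratively joins sorted same-direction candidates of one context that
#' lie within `cfg$max_gap` of each other, keeping a merge only when the
#' merged region -- on its raw pooled counts -- is still significant at
#' the raw p-value cutoff and satisfies the proportion-difference and
#' mean-coverage conditions. The raw (not BH-adjusted) p-value is used
#' because merged regions are not part of the original testing family;
#' the reported `adjustedPValue` of a merged DMR is the smallest adjusted
#' p-value among its constituents.
#'
#' @param dmrs a sorted, non-overlapping `GRanges` of candidate DMRs (as
#'   produced inside [call_dmrs()]; metadata columns direction,
#'   statistic, pValue, adjustedPValue, regionType).
#' @param data1,data2 the condition methylomes (or replicate lists) the
#'   candidates were called from.
#' @param cfg the [dmr_config()] of the call.
#' @return a `GRanges` of merged DMRs (unfiltered).
#' @export
merge_dmrs <- function(dmrs, data1, data2, cfg) {
  stopifnot(inherits(cfg, "dmr_config"))
  cond1 <- .as_condition(data1, "condition1")
  cond2 <- .as_condition(data2, "condition2")
  need_reps <- cfg$test == "beta_regression"
  rep_cols <- if (need_reps) list(
    m1 = sprintf("rM1_%d", seq_along(cond1$reps)),
    n1 = sprintf("rN1_%d", seq_along(cond1$reps)),
    m2 = sprintf("rM2_%d", seq_along(cond2$reps)),
    n2 = sprintf("rN2_%d", seq_along(cond2$reps)))
  u <- .union_table(cond1, cond2, cfg$context, need_reps)
  ri <- .region_index(u)
  mc <- S4Vectors::mcols(dmrs)
  cand <- data.table::data.table(
    chrom = as.character(GenomicRanges::seqnames(dmrs)),
    start = GenomicRanges::start(dmrs),
    end = GenomicRanges::end(dmrs),
    direction = mc$direction, statistic = mc$statistic,
    pValue = mc$pValue, padj = mc$adjustedPValue,
    regionType = mc$regionType)
  data.table::setorder(cand, chrom, start)
  .finalize_dmrs(.merge_candidates(cand, ri, cfg, rep_cols), ri, cfg)
}

#' Filter DMRs by size and cytosine count
#'
#' Keeps DMRs spanning at least `cfg$min_size` bp (1-based closed width)
#' and containing at least `cfg$min_cytosines` context cytosines.
#'
#' @param dmrs a `GRanges` of DMRs with a `cytosinesCount` column.
#' @param cfg a [dmr_config()].
#' @return the filtered `GRanges`.
#' @export
filter_dmrs <- function(dmrs, cfg) {
  stopifnot(inherits(cfg, "dmr_config"))
  keep <- GenomicRanges::width(dmrs) >= cfg$min_size &
    S4Vectors::mcols(dmrs)$cytosinesCount >= cfg$min_cytosines
  dmrs[keep]
}

#' Total genome coverage of a DMR set
#'
#' The total number of base pairs covered, `sum(end - start + 1)`; the
#' package's sensitivity measure for comparing engines and window sizes.
#' Overlapping input is rejected.
#'
#' @param dmrs a `GRanges` of non-overlapping DMRs.
#' @return total length in bp.
#' @export
dmr_genome_coverage <- function(dmrs) {
  if (length(dmrs) == 0L) return(0)
  red <- GenomicRanges::reduce(dmrs, ignore.strand = TRUE)
  if (sum(GenomicRanges::width(red)) != sum(GenomicRanges::width(dmrs)))
    mdmr_data_error("overlapping DMRs in coverage computation")
  sum(GenomicRanges::width(dmrs))
}
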