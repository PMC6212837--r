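#' Test a fixed set of annotated regions for differential methylation
#'
#' For each supplied region (e.g. genes, transposable elements or CpG
#' islands), pools all raw reads over the region's context cytosines in
#' each condition, applies the configured test, adjusts p-values across
#' the region set (Benjamini-Hochberg) and evaluates the three DMR
#' conditions. Every input region is returned with its verdict, so
#' non-significant regions remain reportable.
#'
#' @param data1,data2 methylome `GRanges` (or replicate lists).
#' @param regions a `GRanges` of regions, 1-based closed (see
#'   [read_regions()] for BED/GFF3 import).
#' @param cfg a [dmr_config()]; only `context`, `test` and the three
#'   selection thresholds are used.
#' @return a `GRanges` parallel to `regions` with the pooled counts,
#'   proportions, cytosine count, statistic, raw and adjusted p-value, a
#'   `status` column (`"tested"` / `"untested"`) and a logical
#'   `selected` column. Regions without context cytosines or without
#'   reads in one condition are `"untested"`.
#' @export
analyze_regions <- function(data1, data2, regions, cfg) {
  stopifnot(inherits(cfg, "dmr_config"))
  cond1 <- .as_condition(data1, "condition1")
  cond2 <- .as_condition(data2, "condition2")
  need_reps <- cfg$test == "beta_regression"
  if (need_reps &&
      (length(cond1$reps) < 2L || length(cond2$reps) < 2L))
    mdmr_usage_error(
      "beta_regression requires >= 2 replicates per condition")
  rep_cols <- if (need_reps) list(
    m1 = sprintf("rM1_%d", seq_along(cond1$reps)),
    n1 = sprintf("rN1_%d", seq_along(cond1$reps)),
    m2 = sprintf("rM2_%d", seq_along(cond2$reps)),
    n2 = sprintf("rN2_%d", seq_along(cond2$reps)))
  u <- .union_table(cond1, cond2, cfg$context, need_reps)
  ri <- .region_index(u)
  rc <- .region_counts(ri,
                       as.character(GenomicRanges::seqnames(regions)),
                       GenomicRanges::start(regions),
                       GenomicRanges::end(regions))
  testable <- rc$cyt >= 1 & rc$N1 > 0 & rc$N2 > 0
  units <- data.table::copy(rc)
  units[, `:=`(selM1 = M1, selN1 = N1, selM2 = M2, selN2 = N2)]
  res <- .test_units(units[testable], cfg, rep_cols)
  stat <- p <- prop1 <- prop2 <- rep(NA_real_, nrow(rc))
  dir <- rep(NA_character_, nrow(rc))
  stat[testable] <- res$statistic; p[testable] <- res$pValue
  prop1[testable] <- res$proportion1; prop2[testable] <- res$proportion2
  dir[testable] <- res$direction
  padj <- rep(NA_real_, nrow(rc))
  padj[testable] <- bh_adjust(p[testable])
  selected <- !is.na(padj) & padj <= cfg$p_value &
    !is.na(dir) &
    abs(prop2 - prop1) >= cfg$min_diff &
    (rc$N1 + rc$N2) / (2 * pmax(rc$cyt, 1)) >= cfg$min_reads
  out <- GenomicRanges::granges(regions)
  S4Vectors::mcols(out) <- S4Vectors::DataFrame(
    context = cfg$context, direction = dir,
    readsM1 = rc$M1, readsN1 = rc$N1, readsM2 = rc$M2, readsN2 = rc$N2,
    proportion1 = prop1, proportion2 = prop2,
    cytosinesCount = rc$cyt, statistic = stat, pValue = p,
    adjustedPValue = padj,
    regionType = "annotated",
    status = ifelse(testable & !is.na(p), "tested", "untested"),
    selected = selected)
  out
}
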