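#' @title DMR-calling engines
#' @name dmr_engine
#' @description The three calling engines (noise filter, tiling bins,
#'   per-cytosine neighbourhood), candidate selection, iterative merging,
#'   filtering and per-region testing.
NULL

# --- input normalisation ----------------------------------------------------

# accepts a methylome GRanges or a list of replicate methylomes; returns
# list(reps = list of GRanges, pooled = GRanges)
.as_condition <- function(data, label) {
  if (methods::is(data, "GRanges")) data <- list(data)
  if (!is.list(data) || length(data) == 0L ||
      !all(vapply(data, function(d) methods::is(d, "GRanges"), logical(1))))
    mdmr_usage_error(sprintf(
      "%s must be a methylome GRanges or a list of them", label))
  list(reps = data, pooled = pool_replicates(data, sample = label))
}

# --- union cytosine table ---------------------------------------------------

# full outer join of the two (context-restricted) pooled methylomes on
# (chrom, pos, strand); absent positions contribute zero reads. When
# need_reps, per-replicate count columns rM1_j/rN1_j, rM2_j/rN2_j are added.
.union_table <- function(cond1, cond2, context, need_reps = FALSE) {
  d1 <- .as_dt(cond1$pooled)[ctx == context]
  d2 <- .as_dt(cond2$pooled)[ctx == context]
  u <- merge(
    d1[, list(chrom, pos, strand_, M1 = M, N1 = N, tri1 = tri)],
    d2[, list(chrom, pos, strand_, M2 = M, N2 = N, tri2 = tri)],
    by = c("chrom", "pos", "strand_"), all = TRUE)
  for (cn in c("M1", "N1", "M2", "N2"))
    data.table::set(u, which(is.na(u[[cn]])), cn, 0)
  u[, tri := ifelse(is.na(tri1), tri2, tri1)]
  u[, c("tri1", "tri2") := NULL]
  if (need_reps) {
    add_rep <- function(reps, tag) {
      for (j in seq_along(reps)) {
        r <- .as_dt(reps[[j]])[ctx == context,
                               list(chrom, pos, strand_, M, N)]
        u <<- merge(u, r, by = c("chrom", "pos", "strand_"), all.x = TRUE)
        mcol <- sprintf("rM%s_%d", tag, j); ncol_ <- sprintf("rN%s_%d", tag, j)
        data.table::setnames(u, c("M", "N"), c(mcol, ncol_))
        for (cn in c(mcol, ncol_))
          data.table::set(u, which(is.na(u[[cn]])), cn, 0)
      }
    }
    add_rep(cond1$reps, "1")
    add_rep(cond2$reps, "2")
  }
  data.table::setorder(u, chrom, pos, strand_)
  u
}

# --- region statistics (cumulative sums over the union table) ---------------

# cumulative-sum index over union positions, for O(log n) pooled counts of
# arbitrary intervals (raw counts; merging and final reporting)
.region_index <- function(u) {
  num_cols <- setdiff(names(u), c("chrom", "pos", "strand_", "tri"))
  idx <- list()
  for (chr in unique(u$chrom)) {
    uc <- u[chrom == chr]
    idx[[chr]] <- c(list(pos = uc$pos),
                    lapply(uc[, num_cols, with = FALSE], cumsum))
  }
  structure(list(idx = idx, cols = num_cols), class = "mdmr_region_index")
}

# vectorised pooled counts over 1-based closed intervals
.region_counts <- function(ri, chrom, start, end) {
  out <- data.table::data.table(chrom = chrom, start = start, end = end)
  for (cn in c(ri$cols, "cyt")) out[, (cn) := NA_real_]
  for (chr in unique(chrom)) {
    rows <- which(chrom == chr)
    ci <- ri$idx[[chr]]
    if (is.null(ci)) {
      for (cn in ri$cols) data.table::set(out, rows, cn, 0)
      data.table::set(out, rows, "cyt", 0)
      next
    }
    hi <- findInterval(end[rows], ci$pos)
    lo <- findInterval(start[rows] - 1L, ci$pos)
    for (cn in ri$cols) {
      cs <- c(0, ci[[cn]])
      data.table::set(out, rows, cn, cs[hi + 1L] - cs[lo + 1L])
    }
    data.table::set(out, rows, "cyt", as.numeric(hi - lo))
  }
  out
}

# --- per-unit testing -------------------------------------------------------

# run the configured test on a unit table carrying selection-scale counts
# selM1/selN1/selM2/selN2 (raw or smoothed) and, for beta regression,
# per-replicate columns. Adds statistic, pValue, proportion1/2, direction.
.test_units <- function(units, cfg, rep_cols = NULL) {
  if (cfg$test == "score") {
    res <- score_test_counts(units$selM1, units$selN1,
                             units$selM2, units$selN2)
  } else if (cfg$test == "fisher") {
    res <- fisher_test_counts(units$selM1, units$selN1,
                              units$selM2, units$selN2)
  } else {
    res <- .beta_test_units(units, rep_cols, cfg$beta_p_method)
    # conditions (ii)/(iii) are evaluated on the pooled selection-scale
    # counts for all tests; beta regression only supplies the p-value
    pool <- .test_result(units$selM1, units$selN1, units$selM2, units$selN2,
                         statistic = res$statistic, pValue = res$pValue)
    res <- pool
  }
  units$statistic <- res$statistic
  units$pValue <- res$pValue
  units$proportion1 <- res$proportion1
  units$proportion2 <- res$proportion2
  units$direction <- res$direction
  units
}

# beta regression across replicates, unit by unit; units where any
# replicate has zero total reads are skipped (NA p-value)
.beta_test_units <- function(units, rep_cols, p_method) {
  k <- nrow(units)
  stat <- rep(NA_real_, k); pv <- rep(NA_real_, k)
  mcols1 <- rep_cols$m1; ncols1 <- rep_cols$n1
  mcols2 <- rep_cols$m2; ncols2 <- rep_cols$n2
  grp <- rep(c("cond1", "cond2"), c(length(mcols1), length(mcols2)))
  Nmat <- as.matrix(units[, c(ncols1, ncols2), with = FALSE])
  Mmat <- as.matrix(units[, c(mcols1, mcols2), with = FALSE])
  testable <- rowSums(Nmat > 0) == ncol(Nmat)
  for (i in which(testable)) {
    y <- Mmat[i, ] / Nmat[i, ]
    r <- tryCatch(beta_regression_test(y, grp, p_method = p_method),
                  error = function(e) NULL)
    if (!is.null(r) && isTRUE(r$converged)) {
      stat[i] <- r$statistic; pv[i] <- r$pValue
    }
  }
  list(statistic = stat, pValue = pv)
}

# --- unit construction per engine -------------------------------------------

# neighbourhood: one unit per cytosine present (readsN >= 1) in both samples
.units_neighbourhood <- function(u, rep_cols) {
  units <- u[N1 >= 1 & N2 >= 1]
  units[, `:=`(start = pos, end = pos,
               selM1 = M1, selN1 = N1, selM2 = M2, selN2 = N2,
               cyt = 1)]
  units
}

# bins: pool reads per tiling bin; interval trimmed to the cytosine extent
.units_bins <- function(u, bin_size, rep_cols) {
  u2 <- data.table::copy(u)
  u2[, bin := (pos - 1L) %/% bin_size]
  agg <- c(list(start = quote(min(pos)), end = quote(max(pos)),
                selM1 = quote(sum(M1)), selN1 = quote(sum(N1)),
                selM2 = quote(sum(M2)), selN2 = quote(sum(N2)),
                cyt = quote(as.numeric(.N))))
  rc <- unlist(rep_cols)
  jexp <- as.call(c(quote(list), agg,
                    stats::setNames(lapply(rc, function(cn)
                      bquote(sum(.(as.name(cn))))), rc)))
  units <- u2[, eval(jexp), by = c("chrom", "bin")]
  units[selN1 > 0 & selN2 > 0]
}

# noise filter: per-position tests on the kernel-smoothed (normalised
# weighted-average) counts of each condition, evaluated at the union
# positions; smoothed counts stay on the per-cytosine read scale, so the
# mean-reads condition (selN1 + selN2) / (2 cyt) with cyt = 1 is the
# smoothed mean coverage at the position
.units_noise_filter <- function(u, cond1, cond2, cfg, rep_cols) {
  at <- u[, list(chrom, pos, strand_)]
  units <- data.table::copy(u)
  sm <- function(gr) {
    s <- .smooth_sums(gr, cfg$kernel, cfg$context, at)
    list(M = ifelse(s$wsum > 0, s$wm / s$wsum, NA_real_),
         N = ifelse(s$wsum > 0, s$wn / s$wsum, NA_real_))
  }
  s1 <- sm(cond1$pooled); s2 <- sm(cond2$pooled)
  units[, `:=`(selM1 = s1$M, selN1 = s1$N, selM2 = s2$M, selN2 = s2$N,
               start = pos, end = pos, cyt = 1)]
  if (!is.null(rep_cols)) {
    for (j in seq_along(cond1$reps)) {
      sr <- sm(cond1$reps[[j]])
      units[, (rep_cols$m1[j]) := sr$M][, (rep_cols$n1[j]) := sr$N]
    }
    for (j in seq_along(cond2$reps)) {
      sr <- sm(cond2$reps[[j]])
      units[, (rep_cols$m2[j]) := sr$M][, (rep_cols$n2[j]) := sr$N]
    }
  }
  units[!is.na(selN1) & !is.na(selN2) & selN1 > 0 & selN2 > 0]
}

# --- candidate selection ----------------------------------------------------

#' Select units satisfying the three DMR conditions
#'
#' A tested unit (position, cytosine, bin or region) becomes a candidate
#' DMR when (i) its adjusted p-value is at most `cfg$p_value`, (ii) the
#' absolute difference in methylation proportion is at least
#' `cfg$min_diff`, and (iii) the mean number of reads per cytosine,
#' `(readsN1 + readsN2) / (2 * cytosinesCount)`, is at least
#' `cfg$min_reads`. The three predicates commute: they are applied as one
#' conjunction.
#'
#' @param units a data.frame of tested units with columns
#'   `adjustedPValue`, `proportion1`, `proportion2`, `readsN1`,
#'   `readsN2` and `cytosinesCount` (the count columns on the scale the
#'   engine tested: raw for bins/neighbourhood, smoothed for the noise
#'   filter).
#' @param cfg a [dmr_config()].
#' @return the subset of rows passing all three conditions, order
#'   preserved.
#' @export
select_units <- function(units, cfg) {
  stopifnot(inherits(cfg, "dmr_config"))
  keep <- !is.na(units$adjustedPValue) &
    units$adjustedPValue <= cfg$p_value &
    abs(units$proportion2 - units$proportion1) >= cfg$min_diff &
    (units$readsN1 + units$readsN2) / (2 * units$cytosinesCount) >=
      cfg$min_reads
  units[keep, , drop = FALSE]
}

# internal variant on the engine unit table (selection-scale columns)
.select_units_dt <- function(units, cfg) {
  units[!is.na(padj) & padj <= cfg$p_value &
          abs(proportion2 - proportion1) >= cfg$min_diff &
          (selN1 + selN2) / (2 * cyt) >= cfg$min_reads &
          !is.na(direction)]
}

# --- main entry -------------------------------------------------------------

#' Call differentially methylated regions between two conditions
#'
#' Runs the full pipeline of the configured engine: unit construction
#' (per-cytosine, tiling bin, or kernel-smoothed position), per-unit
#' testing, genome-wide Benjamini-Hochberg adjustment, selection by the
#' three DMR conditions (see [select_units()]), iterative merging of
#' neighbouring candidates ([merge_dmrs()]) and size/cytosine filtering
#' ([filter_dmrs()]).
#'
#' The pooled counts reported on the returned DMRs are always raw
#' (unsmoothed) sums over the region; the noise filter uses smoothed
#' counts only to decide which positions are differentially methylated.
#'
#' @param data1,data2 methylome `GRanges` (or lists of replicate
#'   methylomes) for condition 1 and condition 2. With
#'   `test = "beta_regression"` both conditions need >= 2 replicates.
#' @param cfg a [dmr_config()].
#' @return a sorted, non-overlapping `GRanges` of DMRs with metadata
#'   columns context, direction (`"gain"` = condition 2 more methylated),
#'   readsM1, readsN1, readsM2, readsN2, proportion1, proportion2,
#'   cytosinesCount, statistic, pValue, adjustedPValue and regionType.
#' @examples
#' cfg <- dmr_config("bins", "CG", bin_size = 100, min_size = 10)
#' a <- methylome("chr1", c(10, 60, 110), "+", c(9, 10, 8),
#'                c(10, 12, 9), "CG")
#' b <- methylome("chr1", c(10, 60, 110), "+", c(0, 1, 0),
#'                c(11, 10, 12), "CG")
#' call_dmrs(a, b, cfg)
#' @export
call_dmrs <- function(data1, data2, cfg) {
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
  if (nrow(u) == 0L) {
    warning("no cytosines in the requested context")
    return(.empty_dmrs())
  }
  units <- switch(cfg$method,
    neighbourhood = .units_neighbourhood(u, rep_cols),
    bins = .units_bins(u, cfg$bin_size, rep_cols),
    noise_filter = .units_noise_filter(u, cond1, cond2, cfg, rep_cols))
  if (nrow(units) == 0L) {
    warning("no testable units (no positions covered in both conditions)")
    return(.empty_dmrs())
  }
  units <- .test_units(units, cfg, rep_cols)
  units <- units[!is.na(pValue)]
  units[, padj := bh_adjust(pValue)]
  cand <- .select_units_dt(units, cfg)
  ri <- .region_index(u)
  cand <- cand[, list(chrom, start, end, direction, statistic, pValue,
                      padj, regionType = switch(cfg$method,
                        neighbourhood = "cytosine",
                        bins = "bin", noise_filter = "position"))]
  data.table::setorder(cand, chrom, start)
  merged <- .merge_candidates(cand, ri, cfg, rep_cols)
  filter_dmrs(.finalize_dmrs(merged, ri, cfg), cfg)
}

#' @rdname call_dmrs
#' @export
call_dmrs_noise_filter <- function(data1, data2, cfg) {
  cfg$method <- "noise_filter"; call_dmrs(data1, data2, cfg)
}

#' @rdname call_dmrs
#' @export
call_dmrs_bins <- function(data1, data2, cfg) {
  cfg$method <- "bins"; call_dmrs(data1, data2, cfg)
}

#' @rdname call_dmrs
#' @export
call_dmrs_neighbourhood <- function(data1, data2, cfg) {
  cfg$method <- "neighbourhood"; call_dmrs(data1, data2, cfg)
}

# --- finalisation -----------------------------------------------------------

.empty_dmrs <- function() {
  gr <- GenomicRanges::GRanges()
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    context = character(0), direction = character(0),
    readsM1 = numeric(0), readsN1 = numeric(0),
    readsM2 = numeric(0), readsN2 = numeric(0),
    proportion1 = numeric(0), proportion2 = numeric(0),
    cytosinesCount = numeric(0), statistic = numeric(0),
    pValue = numeric(0), adjustedPValue = numeric(0),
    regionType = character(0))
  gr
}

# attach raw pooled counts and build the output GRanges
.finalize_dmrs <- function(dt, ri, cfg) {
  if (nrow(dt) == 0L) return(.empty_dmrs())
  rc <- .region_counts(ri, dt$chrom, dt$start, dt$end)
  cyt <- pmax(rc$cyt, 1)
  GenomicRanges::GRanges(
    seqnames = dt$chrom,
    ranges = IRanges::IRanges(start = dt$start, end = dt$end),
    strand = "*",
    context = cfg$context,
    direction = dt$direction,
    readsM1 = rc$M1, readsN1 = rc$N1, readsM2 = rc$M2, readsN2 = rc$N2,
    proportion1 = ifelse(rc$N1 > 0, rc$M1 / rc$N1, NA_real_),
    proportion2 = ifelse(rc$N2 > 0, rc$M2 / rc$N2, NA_real_),
    cytosinesCount = cyt,
    statistic = dt$statistic, pValue = dt$pValue,
    adjustedPValue = dt$padj, regionType = dt$regionType)
}
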