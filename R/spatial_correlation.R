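#' Spatial correlation of methylation levels
#'
#' Computes, for each requested distance d, Pearson's correlation between
#' the methylation proportions of all same-context cytosine pairs lying
#' exactly d bp apart on the same chromosome (any strand by default).
#' Only cytosines with at least `min_coverage` total reads enter, to
#' stabilise the proportions. The distance decay of this correlation is
#' the diagnostic for whether the noise-filter engine is applicable:
#' kernel smoothing only helps when neighbouring cytosines carry
#' correlated methylation (typically CG/CHG but not CHH in plants).
#'
#' @param data a methylome `GRanges`.
#' @param context context analysed.
#' @param distances distances in bp (>= 1); pairing is at the exact
#'   distance, not binned.
#' @param min_coverage minimum total reads per cytosine (default 4).
#' @param same_strand restrict pairs to cytosines on the same strand.
#' @return a data.frame with columns `distance`, `r` and `nPairs`; `r`
#'   is `NA` when fewer than 3 pairs exist or either vector is constant.
#' @export
methylation_spatial_correlation <- function(data, context, distances,
                                            min_coverage = 4,
                                            same_strand = FALSE) {
  if (any(distances < 1)) mdmr_usage_error("distances must be >= 1")
  if (min_coverage < 1) mdmr_usage_error("min_coverage must be >= 1")
  dt <- .as_dt(data)[ctx == context & N >= min_coverage]
  dt[, p := M / N]
  data.table::setorder(dt, chrom, pos)
  chroms <- unique(dt$chrom)
  out <- data.frame(distance = as.numeric(distances), r = NA_real_,
                    nPairs = 0L)
  for (k in seq_along(distances)) {
    d <- distances[k]
    xs <- list(); ys <- list()
    for (chr in chroms) {
      dc <- dt[chrom == chr]
      j <- match(dc$pos + d, dc$pos)
      ok <- !is.na(j)
      if (same_strand) ok <- ok & dc$strand_ == dc$strand_[j]
      if (any(ok)) {
        xs[[chr]] <- dc$p[ok]
        ys[[chr]] <- dc$p[j[ok]]
      }
    }
    x <- unlist(xs, use.names = FALSE); y <- unlist(ys, use.names = FALSE)
    n <- length(x)
    out$nPairs[k] <- n
    if (n >= 3 && stats::var(x) > 0 && stats::var(y) > 0)
      out$r[k] <- stats::cor(x, y)
  }
  out
}
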