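#' Kernel specification for the noise-filter engine
#'
#' Defines the smoothing weights used by [smooth_counts()]. With half
#' width `h = window_size / 2` and normalised offset `u = offset / h`,
#' the weight is
#' \describe{
#'   \item{uniform}{1 for |u| <= 1, else 0;}
#'   \item{triangular}{max(0, 1 - |u|);}
#'   \item{gaussian}{exp(-u^2 / (2 sigma^2)) for |u| <= 1 with sigma =
#'     1/3 (i.e. the window edge sits at 3 standard deviations), else 0;}
#'   \item{epanechnikov}{max(0, 1 - u^2).}
#' }
#' All kernels are symmetric, non-negative, maximal at offset 0 and zero
#' outside the window.
#'
#' @param family kernel family.
#' @param window_size full window width in bp (>= 1).
#' @return an object of class `kernel_spec`.
#' @export
kernel_spec <- function(family = c("triangular", "uniform", "gaussian",
                                   "epanechnikov"),
                        window_size = 100) {
  family <- match.arg(family)
  if (!is.numeric(window_size) || length(window_size) != 1L ||
      window_size < 1)
    mdmr_usage_error("window_size must be a positive number")
  structure(list(family = family, window_size = as.numeric(window_size)),
            class = "kernel_spec")
}

#' @export
print.kernel_spec <- function(x, ...) {
  cat(sprintf("<kernel_spec: %s, window %g bp>\n", x$family, x$window_size))
  invisible(x)
}

.KERNEL_CODE <- c(uniform = 0L, triangular = 1L, gaussian = 2L,
                  epanechnikov = 3L)
.GAUSS_SIGMA <- 1 / 3  # in u-units; window edge at 3 sigma

#' Evaluate kernel weights
#'
#' @param spec a [kernel_spec()].
#' @param offset signed distances in bp (vectorised).
#' @return non-negative relative weights (normalisation happens in
#'   [smooth_counts()]).
#' @examples
#' kernel_weight(kernel_spec("epanechnikov", 100), 25)  # 0.75
#' @export
kernel_weight <- function(spec, offset) {
  stopifnot(inherits(spec, "kernel_spec"))
  h <- spec$window_size / 2
  u <- offset / h
  w <- switch(spec$family,
    uniform = as.numeric(abs(u) <= 1),
    triangular = pmax(0, 1 - abs(u)),
    gaussian = ifelse(abs(u) <= 1, exp(-u^2 / (2 * .GAUSS_SIGMA^2)), 0),
    epanechnikov = pmax(0, 1 - u^2))
  w
}

# kernel-weighted window sums (unnormalised) of one sample's counts at
# the given evaluation positions; returns wm, wn, wsum per position.
# The noise-filter engine tests positions on these pooled sums; the
# normalised averages (smooth_counts) supply proportions and the
# mean-coverage condition.
.smooth_sums <- function(data, spec, context, at) {
  dt <- .as_dt(data)
  src <- dt[ctx == context]
  eval_dt <- data.table::as.data.table(at)
  data.table::setorder(eval_dt, chrom, pos, strand_)
  data.table::setorder(src, chrom, pos, strand_)
  h <- spec$window_size / 2
  fam <- .KERNEL_CODE[[spec$family]]
  n <- nrow(eval_dt)
  wm <- numeric(n); wn <- numeric(n); wsum <- numeric(n)
  off <- 0L
  for (chr in unique(eval_dt$chrom)) {
    ev <- eval_dt[chrom == chr]
    sc <- src[chrom == chr]
    res <- .window_weighted_sums(as.numeric(ev$pos), as.numeric(sc$pos),
                                 sc$M, sc$N, h, fam, .GAUSS_SIGMA)
    idx <- off + seq_len(nrow(ev))
    wm[idx] <- res$wm; wn[idx] <- res$wn; wsum[idx] <- res$wsum
    off <- off + nrow(ev)
  }
  data.table::data.table(chrom = eval_dt$chrom, pos = eval_dt$pos,
                         strand_ = eval_dt$strand_,
                         wm = wm, wn = wn, wsum = wsum)
}

#' Kernel-smooth methylated and total read counts
#'
#' For each evaluation position p, computes the weighted averages
#' `smoothedM(p) = sum w(q - p) readsM(q) / sum w(q - p)` (and likewise
#' for `readsN`) over the context cytosines q within `window_size / 2`
#' of p on the same chromosome, including p itself. Smoothed counts stay
#' on the per-cytosine read scale; `0 <= smoothedM <= smoothedN` holds
#' everywhere. Smoothing never crosses chromosome boundaries and ignores
#' strand (neighbouring cytosines on either strand contribute).
#'
#' @param data a methylome `GRanges`.
#' @param spec a [kernel_spec()].
#' @param context single context to smooth (`"CG"`, `"CHG"` or `"CHH"`).
#' @param at optional `GRanges` or data.frame of evaluation positions;
#'   by default the context cytosines of `data` themselves. Positions
#'   with an empty neighbourhood get `NA` smoothed values.
#' @return a methylome-like `GRanges` at the evaluation positions whose
#'   `readsM`/`readsN` columns hold the real-valued smoothed counts.
#' @export
smooth_counts <- function(data, spec, context, at = NULL) {
  stopifnot(inherits(spec, "kernel_spec"))
  if (length(context) != 1L || !context %in% .CONTEXTS)
    mdmr_usage_error("context must be one of CG, CHG, CHH")
  dt <- .as_dt(data)
  src <- dt[ctx == context]
  eval_dt <- if (is.null(at)) {
    data.table::copy(src)
  } else if (methods::is(at, "GRanges")) {
    .as_dt(at)[, c("chrom", "pos", "strand_"), with = FALSE]
  } else {
    data.table::as.data.table(at)
  }
  if (nrow(eval_dt) == 0L)
    return(methylome(character(0), integer(0), character(0), numeric(0),
                     numeric(0), character(0)))
  data.table::setorder(eval_dt, chrom, pos, strand_)
  data.table::setorder(src, chrom, pos, strand_)
  h <- spec$window_size / 2
  fam <- .KERNEL_CODE[[spec$family]]
  out <- vector("list", length(unique(eval_dt$chrom)))
  i <- 0L
  for (chr in unique(eval_dt$chrom)) {
    ev <- eval_dt[chrom == chr]
    sc <- src[chrom == chr]
    res <- .window_weighted_sums(as.numeric(ev$pos), as.numeric(sc$pos),
                                 sc$M, sc$N, h, fam, .GAUSS_SIGMA)
    sm <- ifelse(res$wsum > 0, res$wm / res$wsum, NA_real_)
    sn <- ifelse(res$wsum > 0, res$wn / res$wsum, NA_real_)
    i <- i + 1L
    out[[i]] <- data.table::data.table(
      chrom = chr, pos = ev$pos, strand_ = ev$strand_,
      M = sm, N = sn, ctx = context, tri = context)
  }
  res <- data.table::rbindlist(out)
  # NA-neighbourhood rows kept; caller excludes smoothedN == 0 / NA
  gr <- GenomicRanges::GRanges(
    seqnames = res$chrom,
    ranges = IRanges::IRanges(start = res$pos, width = 1L),
    strand = res$strand_,
    readsM = res$M, readsN = res$N, context = res$ctx,
    trinucleotide = res$tri)
  BiocGenerics::sort(gr, ignore.strand = TRUE)
}
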