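#' @title Synthetic methylome pairs with planted DMRs
#' @name synthetic_fixtures
#' @description Generates CX-report-style methylome pairs with
#'   context-dependent spatial correlation, heterogeneous coverage and
#'   planted differentially methylated regions with known coordinates,
#'   so the calling engines can be validated against a ground truth.
NULL

# per-context generator defaults: mean inter-cytosine spacing (bp),
# baseline methylation level, latent logit-scale SD, and spatial
# correlation length (bp). CG/CHG methylation is strongly correlated
# within ~1 kb; CHH correlation decays within tens of bp.
.CTX_DEFAULTS <- data.frame(
  context = c("CG", "CHG", "CHH"),
  mean_spacing = c(20, 25, 5),
  baseline = c(0.80, 0.65, 0.30),
  logit_sd = c(0.8, 1.0, 1.5),
  corr_length = c(1000, 1000, 10),
  stringsAsFactors = FALSE)

#' Specification of a synthetic methylome pair
#'
#' @param genome_length genome (single chromosome) length in bp.
#' @param contexts contexts to simulate.
#' @param dmrs planted DMRs: a data.frame with columns `start`, `end`,
#'   `context`, `target` (methylation level forced in condition 2 inside
#'   the region); see [plant_dmrs()]. `NULL` plants none.
#' @param coverage_mean,coverage_size negative-binomial read-coverage
#'   mean and dispersion (size) per cytosine.
#' @param zero_coverage extra zero-inflation mass: fraction of cytosines
#'   with no reads at all, mimicking unequal library amplification.
#' @param seed mandatory integer seed; generation is fully deterministic.
#' @param context_params optional data.frame overriding rows of the
#'   per-context defaults (columns as in the `context_params` of the
#'   returned spec).
#' @return an object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(genome_length = 1e6, contexts = "CG",
                           dmrs = NULL, coverage_mean = 20,
                           coverage_size = 1.1, zero_coverage = 0.05,
                           seed, context_params = NULL) {
  if (missing(seed)) mdmr_usage_error("seed is mandatory")
  if (!all(contexts %in% .CONTEXTS))
    mdmr_usage_error("contexts must be a subset of CG, CHG, CHH")
  pars <- .CTX_DEFAULTS
  if (!is.null(context_params)) {
    for (i in seq_len(nrow(context_params))) {
      row <- context_params[i, ]
      k <- match(row$context, pars$context)
      for (cn in setdiff(names(context_params), "context"))
        pars[k, cn] <- row[[cn]]
    }
  }
  if (!is.null(dmrs)) {
    stopifnot(all(c("start", "end", "context", "target") %in% names(dmrs)))
    if (any(dmrs$start < 1 | dmrs$end > genome_length |
            dmrs$start > dmrs$end))
      mdmr_usage_error("planted DMRs must lie within the genome")
    if (any(dmrs$target < 0 | dmrs$target > 1))
      mdmr_usage_error("target levels must lie in [0, 1]")
    for (cx in unique(dmrs$context)) {
      d <- dmrs[dmrs$context == cx, ]
      d <- d[order(d$start), ]
      if (nrow(d) > 1 && any(d$start[-1] <= d$end[-nrow(d)]))
        mdmr_data_error("overlapping planted DMRs in the same context")
    }
  }
  structure(list(genome_length = as.numeric(genome_length),
                 contexts = contexts, dmrs = dmrs,
                 coverage_mean = coverage_mean,
                 coverage_size = coverage_size,
                 zero_coverage = zero_coverage,
                 seed = as.integer(seed),
                 context_params = pars),
            class = "synthetic_spec")
}

#' Evenly spaced planted DMRs
#'
#' Deterministic helper laying out `n` non-overlapping regions of the
#' given width across the genome, for use as the `dmrs` slot of
#' [synthetic_spec()].
#'
#' @param n number of regions.
#' @param width region width in bp.
#' @param context context of the planted regions.
#' @param target methylation level forced in condition 2 (0 = complete
#'   loss).
#' @param genome_length genome length in bp.
#' @return a data.frame with columns start, end, context, target.
#' @export
plant_dmrs <- function(n = 20, width = 1000, context = "CG", target = 0,
                       genome_length = 1e6) {
  starts <- round(seq(0.03, 0.93, length.out = n) * genome_length)
  data.frame(start = starts, end = starts + width - 1L,
             context = context, target = target,
             stringsAsFactors = FALSE)
}

# moving-average Gaussian process on the logit scale: iid normals at the
# cytosine positions, averaged over a +/- corr_length window and
# re-standardised, so correlation decays linearly to zero at twice the
# correlation length
.latent_field <- function(pos, corr_length) {
  e <- stats::rnorm(length(pos))
  ws <- .window_sums(as.numeric(pos), e, as.numeric(corr_length))
  ws$sum / sqrt(pmax(ws$count, 1))
}

#' Generate a synthetic methylome pair with planted DMRs
#'
#' Cytosine positions are laid down per context by a geometric-gap point
#' process; per-cytosine methylation propensities follow a
#' moving-average Gaussian process on the logit scale with the
#' context's correlation length, mapped through the logistic function.
#' Condition 2 equals condition 1 except inside planted DMRs, where the
#' propensity is replaced by the target level. Coverage is negative
#' binomial with extra zero inflation, drawn independently per
#' condition, and methylated reads are binomial in the propensity.
#'
#' @param spec a [synthetic_spec()].
#' @return a list with methylomes `condition1` and `condition2`, a
#'   `truth` `GRanges` of the planted DMRs (metadata columns `context`,
#'   `target`) and the `spec`.
#' @export
generate_pair <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  .with_seed(spec$seed, {
    per_ctx <- lapply(spec$contexts, function(cx) .simulate_context(spec, cx))
  })
  dt <- data.table::rbindlist(per_ctx)
  dup <- duplicated(dt$pos)  # rare collisions across contexts
  dt <- dt[!dup]
  data.table::setorder(dt, pos)
  mk <- function(mcol, ncol_, label)
    methylome(rep("chr1", nrow(dt)), dt$pos, dt$strand_,
              dt[[mcol]], dt[[ncol_]], dt$ctx, dt$tri, sample = label)
  truth <- if (is.null(spec$dmrs) || nrow(spec$dmrs) == 0L) {
    GenomicRanges::GRanges(context = character(0), target = numeric(0))
  } else {
    GenomicRanges::GRanges(
      seqnames = "chr1",
      ranges = IRanges::IRanges(start = spec$dmrs$start,
                                end = spec$dmrs$end),
      strand = "*", context = spec$dmrs$context,
      target = spec$dmrs$target)
  }
  list(condition1 = mk("M1", "N1", "condition1"),
       condition2 = mk("M2", "N2", "condition2"),
       truth = BiocGenerics::sort(truth, ignore.strand = TRUE),
       spec = spec)
}

.simulate_context <- function(spec, cx) {
  p <- spec$context_params[spec$context_params$context == cx, ]
  n_draw <- ceiling(spec$genome_length / p$mean_spacing * 1.3) + 100L
  gaps <- stats::rgeom(n_draw, prob = 1 / p$mean_spacing) + 1
  pos <- cumsum(gaps)
  pos <- pos[pos <= spec$genome_length]
  n <- length(pos)
  strand_ <- sample(c("+", "-"), n, replace = TRUE)
  H <- c("A", "C", "T")
  tri <- switch(cx,
    CG = paste0("CG", sample(c(H, "G"), n, replace = TRUE)),
    CHG = paste0("C", sample(H, n, replace = TRUE), "G"),
    CHH = paste0("C", sample(H, n, replace = TRUE),
                 sample(H, n, replace = TRUE)))
  z <- .latent_field(pos, p$corr_length)
  prop1 <- stats::plogis(stats::qlogis(p$baseline) + p$logit_sd * z)
  prop2 <- prop1
  dmrs <- spec$dmrs
  if (!is.null(dmrs)) {
    for (i in which(dmrs$context == cx)) {
      inside <- pos >= dmrs$start[i] & pos <= dmrs$end[i]
      prop2[inside] <- dmrs$target[i]
    }
  }
  draw_counts <- function(prop) {
    N <- stats::rnbinom(n, mu = spec$coverage_mean,
                        size = spec$coverage_size)
    N[stats::runif(n) < spec$zero_coverage] <- 0L
    M <- stats::rbinom(n, N, prop)
    list(M = M, N = N)
  }
  c1 <- draw_counts(prop1)
  c2 <- draw_counts(prop2)
  data.table::data.table(pos = pos, strand_ = strand_, ctx = cx, tri = tri,
                         M1 = c1$M, N1 = c1$N, M2 = c2$M, N2 = c2$N)
}

#' Fraction of cytosines reaching a coverage threshold
#'
#' @param data a methylome `GRanges`.
#' @param context context considered.
#' @param min_reads coverage threshold.
#' @return the fraction of context cytosines with `readsN >= min_reads`,
#'   or `NA` when the context is absent.
#' @export
empirical_coverage_fraction <- function(data, context, min_reads) {
  dt <- .as_dt(data)[ctx == context]
  if (nrow(dt) == 0L) return(NA_real_)
  mean(dt$N >= min_reads)
}

#' Write a synthetic pair to disk
#'
#' Writes the two CX reports, the planted-DMR truth set as BED (0-based
#' half-open) and a JSON sidecar describing the generator settings.
#'
#' @param pair result of [generate_pair()].
#' @param prefix output path prefix.
#' @return the four file paths, invisibly.
#' @export
write_synthetic_pair <- function(pair, prefix) {
  p1 <- paste0(prefix, "_condition1.cx")
  p2 <- paste0(prefix, "_condition2.cx")
  pb <- paste0(prefix, "_truth.bed")
  pj <- paste0(prefix, "_spec.json")
  write_cx_report(pair$condition1, p1)
  write_cx_report(pair$condition2, p2)
  tr <- pair$truth
  utils::write.table(
    data.frame(as.character(GenomicRanges::seqnames(tr)),
               GenomicRanges::start(tr) - 1L, GenomicRanges::end(tr),
               paste0(S4Vectors::mcols(tr)$context, ":",
                      S4Vectors::mcols(tr)$target),
               0L, "."),
    pb, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  sp <- pair$spec
  jsonlite::write_json(
    list(genome_length = sp$genome_length, contexts = sp$contexts,
         coverage_mean = sp$coverage_mean,
         coverage_size = sp$coverage_size,
         zero_coverage = sp$zero_coverage, seed = sp$seed,
         context_params = sp$context_params,
         dmrs = sp$dmrs),
    pj, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(c(p1, p2, pb, pj))
}
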