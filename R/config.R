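#' Configuration of a DMR call
#'
#' Bundles the engine, context, statistical test and all thresholds of a
#' call. The defaults are the package's standard operating point: DMRs
#' must contain at least one cytosine, span at least 50 bp, show a
#' methylation-level difference of at least 40% and be significant at an
#' adjusted p-value of at most 0.05; neighbouring significant units
#' within twice the window/bin size are joined when the merged region
#' still satisfies all three selection conditions.
#'
#' @param method calling engine: `"noise_filter"` (kernel smoothing of
#'   counts, then per-position tests), `"bins"` (pool reads in tiling
#'   bins) or `"neighbourhood"` (test every cytosine on raw counts).
#' @param context cytosine context analysed by the call.
#' @param test per-unit test: `"score"`, `"fisher"` or
#'   `"beta_regression"` (requires >= 2 replicates per condition).
#' @param kernel_family kernel for the noise filter (see [kernel_spec()]).
#' @param window_size full smoothing-window width in bp (noise filter;
#'   also sets the default merge gap for the neighbourhood engine).
#' @param bin_size tiling-bin width in bp (bins engine). Bins are
#'   anchored at coordinate 1 of each chromosome; the final partial bin
#'   is kept.
#' @param p_value adjusted-p-value cutoff (condition i).
#' @param min_diff minimum |methylation proportion difference|
#'   (condition ii).
#' @param min_reads minimum mean reads per cytosine,
#'   `(readsN1 + readsN2) / (2 * cytosinesCount)` (condition iii). The
#'   noise filter evaluates it on smoothed coverage at selection time.
#' @param min_size minimum DMR width in bp (post-merge filter).
#' @param min_cytosines minimum cytosines per DMR (post-merge filter).
#' @param max_gap maximum merge distance in bp; default twice the
#'   window/bin size.
#' @param beta_p_method p-value flavour for [beta_regression_test()].
#' @return an object of class `dmr_config`.
#' @export
dmr_config <- function(method = c("noise_filter", "bins", "neighbourhood"),
                       context = c("CG", "CHG", "CHH"),
                       test = c("score", "fisher", "beta_regression"),
                       kernel_family = "triangular",
                       window_size = 100,
                       bin_size = 100,
                       p_value = 0.05,
                       min_diff = 0.4,
                       min_reads = 4,
                       min_size = 50,
                       min_cytosines = 1,
                       max_gap = NULL,
                       beta_p_method = c("lrt", "wald")) {
  method <- match.arg(method)
  context <- match.arg(context)
  test <- match.arg(test)
  beta_p_method <- match.arg(beta_p_method)
  if (p_value <= 0 || p_value > 1)
    mdmr_usage_error("p_value must lie in (0, 1]")
  if (min_diff <= 0 || min_diff > 1)
    mdmr_usage_error("min_diff must lie in (0, 1]")
  if (min_reads < 0) mdmr_usage_error("min_reads must be non-negative")
  if (min_size < 1) mdmr_usage_error("min_size must be >= 1")
  if (min_cytosines < 1) mdmr_usage_error("min_cytosines must be >= 1")
  if (bin_size < 1) mdmr_usage_error("bin_size must be >= 1")
  kernel <- kernel_spec(kernel_family, window_size)
  if (is.null(max_gap))
    max_gap <- 2 * if (method == "bins") bin_size else window_size
  if (max_gap < 0) mdmr_usage_error("max_gap must be >= 0")
  structure(list(method = method, context = context, test = test,
                 kernel = kernel, window_size = as.numeric(window_size),
                 bin_size = as.numeric(bin_size), p_value = p_value,
                 min_diff = min_diff, min_reads = min_reads,
                 min_size = as.numeric(min_size),
                 min_cytosines = as.numeric(min_cytosines),
                 max_gap = as.numeric(max_gap),
                 beta_p_method = beta_p_method),
            class = "dmr_config")
}

#' @export
print.dmr_config <- function(x, ...) {
  cat(sprintf(
    "<dmr_config: %s / %s / %s; window %g, bin %g, p<=%g, |diff|>=%g,\n",
    x$method, x$context, x$test, x$window_size, x$bin_size, x$p_value,
    x$min_diff))
  cat(sprintf("  mean reads>=%g, size>=%g bp, cytosines>=%g, gap<=%g bp>\n",
              x$min_reads, x$min_size, x$min_cytosines, x$max_gap))
  invisible(x)
}

# update size-dependent fields (used by select_window_size)
.with_size <- function(cfg, size) {
  cfg$window_size <- size
  cfg$bin_size <- size
  cfg$kernel <- kernel_spec(cfg$kernel$family, size)
  cfg$max_gap <- 2 * size
  cfg
}
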