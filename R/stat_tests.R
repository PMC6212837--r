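#' @title Per-unit tests for differential methylation
#' @name stat_tests
#' @description Vectorised two-proportion tests on pooled counts
#'   (Fisher's exact test and the score z-test), the replicate-aware
#'   beta-regression test, and Benjamini-Hochberg adjustment.
NULL

# round half up (Fisher needs integer tables; smoothed counts are real)
.round_half_up <- function(x) floor(x + 0.5)

#' Fisher's exact test for a two-proportion comparison
#'
#' Two-sided exact test on the 2x2 table
#' `[[readsM1, readsN1 - readsM1], [readsM2, readsN2 - readsM2]]`; the
#' two-sided p-value is the total probability of all tables (with the
#' margins fixed) whose hypergeometric probability does not exceed that
#' of the observed table. Real-valued (smoothed) counts are rounded half
#' up before testing. Vectorised over units.
#'
#' @param readsM1,readsN1 methylated/total counts in condition 1.
#' @param readsM2,readsN2 methylated/total counts in condition 2.
#' @return a data.frame with columns `statistic` (the observed
#'   methylated count in condition 1), `pValue`, `proportion1`,
#'   `proportion2` and `direction` (`"gain"` when condition 2 is more
#'   methylated, `"loss"` when less, `NA` when equal). Units with zero
#'   total reads on either side get `NA` p-values (skipped upstream).
#' @examples
#' fisher_test_counts(10, 10, 0, 10)$pValue  # 2 / choose(20, 10)
#' @export
fisher_test_counts <- function(readsM1, readsN1, readsM2, readsN2) {
  k <- max(length(readsM1), length(readsN1), length(readsM2),
           length(readsN2))
  m1 <- rep_len(.round_half_up(readsM1), k)
  n1 <- rep_len(.round_half_up(readsN1), k)
  m2 <- rep_len(.round_half_up(readsM2), k)
  n2 <- rep_len(.round_half_up(readsN2), k)
  m1 <- pmin(m1, n1); m2 <- pmin(m2, n2)
  p <- rep(NA_real_, k)
  ok <- n1 >= 1 & n2 >= 1
  p[ok] <- vapply(which(ok), function(i) {
    K <- m1[i] + m2[i]          # methylated margin
    lo <- max(0, K - n2[i]); hi <- min(K, n1[i])
    supp <- lo:hi
    pr <- stats::dhyper(supp, n1[i], n2[i], K)
    pobs <- pr[match(m1[i], supp)]
    min(1, sum(pr[pr <= pobs * (1 + 1e-7)]))
  }, numeric(1))
  .test_result(m1, n1, m2, n2, statistic = m1, pValue = p)
}

#' Two-proportion score test (z-test)
#'
#' With p1 = readsM1/readsN1, p2 = readsM2/readsN2 and pooled proportion
#' phat = (readsM1 + readsM2)/(readsN1 + readsN2), the statistic is
#' `z = (p1 - p2) / sqrt(phat (1 - phat) (1/readsN1 + 1/readsN2))` and
#' the two-sided p-value is `2 (1 - Phi(|z|))`. When phat is 0 or 1 the
#' variance vanishes and z = 0, p = 1. Accepts real-valued smoothed
#' counts directly. Vectorised over units.
#'
#' @inheritParams fisher_test_counts
#' @return as [fisher_test_counts()], with `statistic` = z.
#' @examples
#' score_test_counts(10, 10, 0, 10)  # z = 4.472, p = 7.7e-6
#' @export
score_test_counts <- function(readsM1, readsN1, readsM2, readsN2) {
  k <- max(length(readsM1), length(readsN1), length(readsM2),
           length(readsN2))
  readsM1 <- rep_len(as.numeric(readsM1), k)
  readsN1 <- rep_len(as.numeric(readsN1), k)
  readsM2 <- rep_len(as.numeric(readsM2), k)
  readsN2 <- rep_len(as.numeric(readsN2), k)
  ok <- readsN1 > 0 & readsN2 > 0
  phat <- ifelse(ok, (readsM1 + readsM2) / (readsN1 + readsN2), NA_real_)
  p1 <- ifelse(ok, readsM1 / readsN1, NA_real_)
  p2 <- ifelse(ok, readsM2 / readsN2, NA_real_)
  v <- phat * (1 - phat) * (1 / readsN1 + 1 / readsN2)
  z <- ifelse(ok & v > 0, (p1 - p2) / sqrt(v), ifelse(ok, 0, NA_real_))
  p <- ifelse(ok, 2 * stats::pnorm(-abs(z)), NA_real_)
  .test_result(readsM1, readsN1, readsM2, readsN2, statistic = z, pValue = p)
}

.test_result <- function(m1, n1, m2, n2, statistic, pValue) {
  p1 <- ifelse(n1 > 0, m1 / n1, NA_real_)
  p2 <- ifelse(n2 > 0, m2 / n2, NA_real_)
  data.frame(statistic = statistic, pValue = pValue,
             proportion1 = p1, proportion2 = p2,
             direction = ifelse(is.na(p1) | is.na(p2) | p1 == p2, NA,
                                ifelse(p2 > p1, "gain", "loss")),
             stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment across all tested units of a
#' single call (one context, one engine, genome-wide).
#'
#' @param p p-values in `[0, 1]` (`NA` allowed for skipped units).
#' @return adjusted p-values in the original order.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    mdmr_data_error("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Beta-regression test for biological replicates
#'
#' Fits, by maximum likelihood, a beta regression of replicate-level
#' methylation proportions on a condition indicator (logit link, common
#' precision phi): `y_r ~ Beta(mu_r phi, (1 - mu_r) phi)` with
#' `logit(mu_r) = b0 + b1 x_r`. Proportions of exactly 0 or 1 are shrunk
#' to `(y (k - 1) + 0.5) / k` (k = number of observations) before
#' fitting.
#'
#' The default p-value is the signed likelihood-root statistic
#' `r = sign(b1) sqrt(LRT)` referred to a t distribution with k - 1
#' degrees of freedom, a small-sample calibration that holds the type-I
#' error near its nominal level with as few as 3 replicates per
#' condition (see the package vignette); `p_method = "wald"` gives the
#' asymptotic Wald z-test on b1, which is markedly anti-conservative for
#' small replicate numbers.
#'
#' @param proportions replicate-level methylation proportions for one
#'   genomic unit (all replicates, both conditions).
#' @param group condition labels (two levels; the second level is
#'   "condition 2").
#' @param p_method `"lrt"` (default) or `"wald"`.
#' @return a one-row data.frame with `statistic` (signed likelihood root
#'   or Wald z), `pValue`, `estimate` (b1, log-odds difference),
#'   `proportion1`, `proportion2`, `direction` and `converged`.
#' @examples
#' beta_regression_test(c(.05, .1, .08, .9, .95, .88),
#'                      rep(c("a", "b"), each = 3))
#' @export
beta_regression_test <- function(proportions, group,
                                 p_method = c("lrt", "wald")) {
  p_method <- match.arg(p_method)
  y <- as.numeric(proportions)
  g <- as.factor(group)
  if (nlevels(g) != 2L)
    mdmr_usage_error("group must have exactly two levels")
  if (any(tabulate(g) < 2L))
    mdmr_data_error("need at least 2 replicates per condition")
  if (any(y < 0 | y > 1) || anyNA(y))
    mdmr_data_error("proportions must lie in [0, 1]")
  x <- as.numeric(g == levels(g)[2])
  k <- length(y)
  bdry <- y == 0 | y == 1
  y[bdry] <- (y[bdry] * (k - 1) + 0.5) / k
  fit <- .betareg_ml(y, x)
  prop1 <- mean(proportions[x == 0]); prop2 <- mean(proportions[x == 1])
  if (!fit$converged)
    return(data.frame(statistic = NA_real_, pValue = NA_real_,
                      estimate = NA_real_, proportion1 = prop1,
                      proportion2 = prop2, direction = NA,
                      converged = FALSE, stringsAsFactors = FALSE))
  b1 <- fit$coef[2]
  if (p_method == "wald") {
    stat <- b1 / fit$se2
    pv <- 2 * stats::pnorm(-abs(stat))
  } else {
    stat <- sign(b1) * sqrt(max(fit$lrt, 0))
    pv <- 2 * stats::pt(-abs(stat), df = k - 1)
  }
  if (!is.finite(stat) || !is.finite(pv))
    return(data.frame(statistic = NA_real_, pValue = NA_real_,
                      estimate = NA_real_, proportion1 = prop1,
                      proportion2 = prop2, direction = NA,
                      converged = FALSE, stringsAsFactors = FALSE))
  data.frame(statistic = unname(stat), pValue = unname(pv),
             estimate = unname(b1), proportion1 = prop1,
             proportion2 = prop2,
             direction = if (prop1 == prop2) NA
                         else if (prop2 > prop1) "gain" else "loss",
             converged = TRUE, stringsAsFactors = FALSE)
}

# maximum-likelihood beta regression: logit link, common precision.
# Returns coefficients, Wald SE of b1, and the LRT against b1 = 0.
.betareg_ml <- function(y, x) {
  nll_full <- function(par) {
    mu <- stats::plogis(par[1] + par[2] * x)
    phi <- exp(par[3])
    -sum(stats::dbeta(y, mu * phi, (1 - mu) * phi, log = TRUE))
  }
  nll_null <- function(par) {
    mu <- stats::plogis(par[1])
    phi <- exp(par[2])
    -sum(stats::dbeta(y, mu * phi, (1 - mu) * phi, log = TRUE))
  }
  m <- mean(y); v <- stats::var(y)
  phi0 <- max(m * (1 - m) / max(v, 1e-8) - 1, 1)
  start <- c(stats::qlogis(min(max(m, 0.01), 0.99)), 0, log(phi0))
  opF <- tryCatch(stats::optim(start, nll_full, method = "BFGS",
                               hessian = TRUE),
                  error = function(e) NULL)
  op0 <- tryCatch(stats::optim(start[c(1, 3)], nll_null, method = "BFGS"),
                  error = function(e) NULL)
  if (is.null(opF) || is.null(op0) || opF$convergence != 0 ||
      !all(is.finite(opF$par)))
    return(list(converged = FALSE))
  se2 <- tryCatch(sqrt(solve(opF$hessian)[2, 2]), error = function(e) NA_real_)
  list(converged = TRUE, coef = opF$par[1:2], se2 = se2,
       lrt = 2 * (op0$value - opF$value))
}
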