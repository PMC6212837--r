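---
title: "Calling differentially methylated regions with methylDMR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling differentially methylated regions with methylDMR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methylDMR)
```

## The problem

Whole-genome bisulfite sequencing yields, for every cytosine, a count of
reads supporting methylation (`readsM`) and a total read count
(`readsN`). A differentially methylated region (DMR) is a genomic
interval whose methylation level differs consistently between two
samples — for instance a wild type and a methyltransferase mutant, or
two tissues. Two features of real data make this harder than it sounds:
coverage is very uneven (a substantial fraction of cytosines has too few
reads for any per-site test), and methylation is spatially correlated in
a *context-dependent* way. In plants, CG and CHG methylation are
maintained by feedback mechanisms that act regionally, so neighbouring
cytosines carry correlated levels over roughly a kilobase; CHH
methylation is deposited by the RdDM pathway and its correlation decays
within tens of base pairs.

`methylDMR` takes Bismark-style CX reports for two conditions and calls
DMRs per context (CG, CHG, CHH) with one of three engines, sharing a
single selection rule.

## The selection rule

Every engine produces *units* (a cytosine, a smoothed position, a bin,
or an annotated region) with methylated/total counts for both
conditions. A unit becomes part of a DMR when all three of the
following hold:

1. **Significance.** The difference is statistically significant:
   adjusted p-value at most `p_value` (default 0.05), with
   Benjamini–Hochberg adjustment across all tested units of the call.
2. **Effect size.** The absolute difference in methylation proportion is
   at least `min_diff` (default 0.4).
3. **Evidence.** The mean number of reads per cytosine,
   `(readsN1 + readsN2) / (2 * cytosinesCount)`, is at least `min_reads`
   (default 4).

The three predicates commute — they are applied as one conjunction, so
their order is irrelevant. Selected units of equal direction lying
within `max_gap` of each other (default twice the window/bin size) are
then merged iteratively: a merge is kept only when the merged interval,
re-tested on its **raw** pooled counts, still satisfies the raw p-value
cutoff and conditions 2–3. The raw rather than the adjusted p-value is
used because merged intervals are not members of the original testing
family, and re-running the adjustment after every merge would make the
result order-dependent. Finally, DMRs shorter than `min_size` (default
50 bp) or with fewer than `min_cytosines` context cytosines are removed.

Defaults correspond to the package's standard operating point: DMRs of
at least 50 bp containing at least one cytosine, with at least a 40%
methylation difference at an adjusted p ≤ 0.05, merged across gaps of up
to twice the window/bin size.

## The three engines

**Neighbourhood** tests every cytosine present with at least one read in
both samples on its raw counts. It is the only engine that yields
single-cytosine calls (DMCs) and is appropriate for high-coverage data.

**Bins** partitions each chromosome into consecutive tiles (anchored at
coordinate 1; the final partial bin is kept), pools all reads per tile
and condition, and tests tiles containing at least one covered cytosine
on both sides. Reported bin intervals are trimmed to the extent of the
cytosines they actually contain, which matters for genome-coverage
accounting.

**Noise filter** smooths `readsM` and `readsN` along the chromosome with
a kernel before testing. With half-width $h$ = `window_size`/2 and
normalised offset $u = \mathrm{offset}/h$, the available kernels are
uniform ($1$), triangular ($1-|u|$), Epanechnikov ($1-u^2$) and a
truncated Gaussian ($e^{-u^2/2\sigma^2}$, $\sigma = 1/3$ so that the
window edge sits at three standard deviations; the truncation constant
is a package choice). Smoothed values are normalised weighted averages

$$\tilde m(p) = \frac{\sum_q w(q-p)\, m(q)}{\sum_q w(q-p)},$$

evaluated only at cytosine positions (the union of both samples'
context cytosines), never across chromosome boundaries, and ignoring
strand — neighbouring cytosines on either strand contribute. Smoothed
counts therefore stay on the per-cytosine read scale, the proportion
$\tilde m/\tilde n$ is a kernel-local methylation level, and condition 3
evaluates the smoothed mean coverage. Because every position inherits
its neighbourhood's evidence, an isolated 2-read cytosine inside a
confidently differential kilobase is still called. Reported counts on
final DMRs are always raw sums over the region; smoothing only decides
*which* positions are differential.

The per-unit test is either Fisher's exact test (two-sided, by total
probability of tables no more probable than the observed one; smoothed
counts are rounded half up since the exact test needs integer tables) or
the two-proportion score test
$z = (p_1 - p_2)\big/\sqrt{\hat p(1-\hat p)(1/n_1 + 1/n_2)}$ with the
pooled $\hat p$; the two give near-identical DMR sets and the score test
is cheaper, so it is the default. Both operate on pooled counts; with
biological replicates you may pool replicates per condition, or model
them explicitly with the beta-regression test below.

## The replicate test and its small-sample calibration

For each unit, replicate-level methylation proportions are modelled as
$y_r \sim \mathrm{Beta}(\mu_r\phi, (1-\mu_r)\phi)$ with
$\mathrm{logit}(\mu_r) = \beta_0 + \beta_1 x_r$, where $x_r$ indicates
the condition and $\phi$ is a common precision. The fit is plain maximum
likelihood (BFGS on $(\beta_0, \beta_1, \log\phi)$); boundary
proportions are shrunk to $(y(k-1) + 0.5)/k$ first. Conditions 2–3 are
still evaluated on the pooled counts; the beta regression only supplies
the p-value.

With typical replicate numbers (3 vs 3, i.e. six observations and three
parameters) the asymptotic Wald z-test on $\beta_1$ is badly
anti-conservative: in null simulations with beta-distributed
proportions its type-I error was ≈ 0.18 at a nominal 0.05, essentially
independently of $\mu \in \{0.2, 0.5, 0.8\}$ and
$\phi \in \{5, 10, 30\}$. The package therefore refers the signed
likelihood root $r = \mathrm{sign}(\hat\beta_1)\sqrt{\mathrm{LRT}}$ to a
t distribution with $k-1$ degrees of freedom ($k$ = number of
observations). This reference was chosen by null simulation over the
parameter grid above *before* the validation suite was written; it holds
the type-I error at 0.044–0.052 across the grid and converges to the
usual likelihood-ratio test as replicates accumulate. The Wald variant
remains available (`p_method = "wald"`) for comparison with tools that
use it. Two practical consequences are worth knowing: with six
observations the attainable p-values are bounded below (around
$10^{-2.5}$ even for perfect separation), so genome-wide FDR control
can leave isolated differential bins uncalled when only a small fraction
of the genome differs; the test is at its best when differences are
widespread (as in methyltransferase mutants) or when the tested family
is small (a curated region set via `analyze_regions()`).

## Choosing the window size with a scrambled methylome

The window/bin size trades sensitivity against false coverage.
`scramble_methylome()` builds a null methylome by permuting the
per-cytosine `(readsM, readsN)` *pairs* within each context across the
genome of each sample independently — pairs rather than proportions, so
both the coverage landscape and the global methylation level are
preserved exactly while the association between methylation and position
is destroyed. `select_window_size()` runs the configured engine on the
real pair and on the scrambled pair for each candidate size and selects
the size maximising `coverage_real − coverage_scrambled` (ties go to
the smaller size). The scrambled null is only meaningful when the two
samples have similar global methylation; the function warns when the
levels differ by more than 0.10. The scrambled run is a heuristic for
parameter choice, not an analytical FDR calibration.

## The spatial-correlation diagnostic

`methylation_spatial_correlation()` computes Pearson's correlation
between the proportions of same-context cytosine pairs lying exactly a
given distance apart (no distance binning; any strand by default, with a
same-strand option), restricted to cytosines with at least
`min_coverage` reads (default 4, mirroring the mean-coverage condition).
Read-sampling noise attenuates all distances equally, so the *shape* of
the decay is interpretable even though its level is damped. If the
correlation at distances comparable to the intended window is near zero
— the typical CHH picture — the noise filter has nothing to exploit and
the bins engine is the right tool.

## The synthetic-methylome generator

`generate_pair()` produces CX-report-scale fixtures with the properties
the engines care about:

* **Positions** per context from a geometric-gap point process; default
  mean spacings 20 bp (CG), 25 bp (CHG), 5 bp (CHH) on a single
  chromosome.
* **Spatial correlation** from a moving-average Gaussian process on the
  logit scale: i.i.d. normals at the cytosines are averaged over a
  ±`corr_length` window and re-standardised, so the latent correlation
  decays roughly linearly to zero at twice the correlation length.
  Defaults: 1000 bp for CG/CHG, 10 bp for CHH.
* **Levels**: baselines 0.80 (CG), 0.65 (CHG), 0.30 (CHH) with logit-SDs
  0.8/1.0/1.5 — methylated-compartment-like landscapes in which a
  complete loss is detectable against the 40% difference threshold.
* **Coverage**: negative binomial with mean 20 and size 1.1 plus a 5%
  zero mass (mimicking unequal library amplification). The size was
  calibrated once so that ~60% of cytosines have at least 10 reads, the
  figure reported for real Arabidopsis and human BS-seq libraries.
* **Planted DMRs**: inside each planted interval the condition-2
  propensity is replaced by the target level (0 = complete loss);
  condition 1 is untouched, and outside planted intervals both
  conditions share the same propensities, differing only by coverage and
  binomial noise. Generation is fully deterministic given the seed.

What the generator does *not* emulate: bimodal per-cytosine methylation
within one context, strand-asymmetric methylation, mappability gaps,
bisulfite non-conversion, or context-dependent coverage. Passing the
validation suite therefore demonstrates correctness of the machinery and
the expected qualitative orderings, not calibrated performance on any
particular organism.

## Validation-study design

The packaged checks run at desk scale (1 Mb genomes) with these fixed
study conditions:

* **Oracle equivalence.** Fisher's exact test against full
  hypergeometric enumeration for every 2×2 table with total ≤ 40;
  Benjamini–Hochberg against an independent step-up implementation on
  1000 random vectors; uniform-kernel smoothing against a double-loop
  windowed mean on 1000 cytosines.
* **Parameter recovery.** Twenty planted 1 kb complete-loss CG DMRs,
  20× coverage: noise filter and bins (size 100) each recover ≥ 90% of
  planted length with ≤ 2% called length outside, and the neighbourhood
  engine recovers ≥ 90% of DMCs at planted cytosines covered ≥ 10× on
  both sides. Score- and Fisher-based pipelines overlap with
  length-Jaccard ≥ 0.95 on the same data.
* **Scrambled-null selection.** Over sizes {10, 100, 1000, 10000} the
  real-minus-scrambled coverage difference has an interior maximum and
  the scrambled coverage at the selected size is < 10% of the real one.
* **Context dependence.** The engine comparison reproduces the
  wild-type-versus-mutant design on which the orderings were
  established, i.e. genome-wide loss rather than isolated planted
  regions. CG: complete loss over a heterogeneous landscape (baseline
  0.35, logit-SD 1.5, 1 kb correlation — roughly 40% of the genome
  callable, matching the scale of a CG-methyltransferase mutant
  comparison), where the noise filter's granularity and
  strength-borrowing make it at least as sensitive as bins. CHH:
  complete loss at 10 bp correlation and mean coverage 10 (CHH coverage
  in real libraries runs well below the CpG figure), where per-position
  smoothed tests cannot reach significance and the noise filter falls
  clearly behind bins.
* **Replicate-test calibration.** On 1000 null units (3 vs 3 replicates
  drawn from equal-mean beta distributions) the rejection rate at
  α = 0.05 stays within two binomial standard errors of α.

`scripts/acceptance.R` re-runs all of the above from scratch at a
caller-supplied seed and writes the measured quantities as JSON.

## Numerical and design notes

* Coordinates are 1-based closed internally (Bismark convention); BED
  export converts to 0-based half-open. Strands are independent
  positions by default; `pool_cpg_pairs()` optionally collapses
  symmetric CpG pairs.
* Zero-coverage cytosines are kept on input: they carry positional
  information for smoothing windows and cytosine counts. Positions with
  an empty smoothing neighbourhood are excluded from testing.
* The Fisher two-sided rule uses a `1 + 1e-7` slack when comparing table
  probabilities, the standard guard against ties lost to floating-point
  rounding.
* Merging scans left to right and, after a successful merge, retries
  from the merged region; passes repeat until no merge occurs. This
  makes the result deterministic and independent of chromosome
  processing order. The reported `adjustedPValue` of a merged DMR is the
  smallest adjusted p-value among its constituents; its `pValue` is the
  raw re-test of the merged region.
* Cytosine counts of regions are computed on the union of both samples'
  context cytosines — the closest observable proxy for "cytosines in the
  genome" when no reference sequence is supplied.
* `bh_adjust()` delegates to `stats::p.adjust(method = "BH")`; the
  independent implementation used to cross-check it lives in the test
  suite only.
* Beta-regression units are tested only when every replicate has
  positive (smoothed) coverage for the unit; non-converged fits are
  skipped and logged, never silently zeroed.
* The CLI (`inst/scripts/methyldmr`) is a thin wrapper over the exported
  functions: subcommands `call`, `select-window`, `spatial-correlation`,
  `simulate` and `analyze-regions`; exit codes 0/1/2 for
  success/data-error/usage-error; `--threads` is accepted for interface
  compatibility and results are invariant to it.

## Known limitations

* Exactly two conditions; no covariates, no multi-factor designs.
* No dispersion shrinkage or empirical-Bayes moderation across units,
  and no HMM segmentation; units are tested independently and joined by
  the merge rule.
* The scrambled-null selection assumes comparable global methylation
  between samples.
* With few replicates the beta-regression test is deliberately
  conservative (see above); pooled-count tests are the more sensitive
  choice when replicate-level variability is not of interest.
* Performance: all engines are linear-time in the number of cytosines
  (two-pointer window sums in C++; cumulative-sum region queries), but
  the iterative merge re-tests every attempted join, which dominates on
  dense candidate sets.
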