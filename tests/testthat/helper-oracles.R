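# Small fixture builders and independent brute-force oracles used across
# the suite. Oracles are deliberately naive and share no code with the
# implementation paths they check.

mk_methylome <- function(pos, M, N, chrom = "chr1", strand = "+",
                         context = "CG", tri = context) {
  k <- length(pos)
  methylome(rep_len(chrom, k), pos, rep_len(strand, k), M, N,
            rep_len(context, k), rep_len(tri, k))
}

meth_dt <- function(x) {
  data.frame(chrom = as.character(GenomicRanges::seqnames(x)),
             pos = GenomicRanges::start(x),
             strand = as.character(GenomicRanges::strand(x)),
             readsM = S4Vectors::mcols(x)$readsM,
             readsN = S4Vectors::mcols(x)$readsN,
             context = S4Vectors::mcols(x)$context,
             stringsAsFactors = FALSE)
}

# two-sided Fisher p by explicit enumeration of all tables with the
# observed margins, probabilities from log-binomial coefficients
fisher_enum_oracle <- function(m1, n1, m2, n2) {
  K <- m1 + m2
  supp <- max(0, K - n2):min(K, n1)
  logp <- vapply(supp, function(a)
    lchoose(n1, a) + lchoose(n2, K - a) - lchoose(n1 + n2, K), numeric(1))
  pr <- exp(logp)
  pr <- pr / sum(pr)
  pobs <- pr[match(m1, supp)]
  sum(pr[pr <= pobs * (1 + 1e-7)])
}

# step-up FDR adjustment straight from the definition
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  qs <- pmin(1, p[o] * n / seq_len(n))
  qs <- rev(cummin(rev(qs)))
  out <- numeric(n)
  out[o] <- qs
  out
}

# brute-force double-loop windowed mean (uniform kernel)
smooth_brute_uniform <- function(pos, m, n, window_size) {
  h <- window_size / 2
  sm <- sn <- numeric(length(pos))
  for (i in seq_along(pos)) {
    w <- abs(pos - pos[i]) <= h
    sm[i] <- sum(m[w]) / sum(w)
    sn[i] <- sum(n[w]) / sum(w)
  }
  list(M = sm, N = sn)
}

# planted-truth comparison helpers
reduce_all <- function(gr) GenomicRanges::reduce(gr, ignore.strand = TRUE)

recovered_fraction <- function(dmrs, truth) {
  if (length(dmrs) == 0) return(0)
  hit <- GenomicRanges::intersect(reduce_all(dmrs), reduce_all(truth),
                                  ignore.strand = TRUE)
  sum(GenomicRanges::width(hit)) / sum(GenomicRanges::width(truth))
}

false_fraction <- function(dmrs, truth) {
  if (length(dmrs) == 0) return(0)
  out <- GenomicRanges::setdiff(reduce_all(dmrs), reduce_all(truth),
                                ignore.strand = TRUE)
  sum(GenomicRanges::width(out)) / sum(GenomicRanges::width(dmrs))
}

length_jaccard <- function(a, b) {
  i <- sum(GenomicRanges::width(GenomicRanges::intersect(
    reduce_all(a), reduce_all(b), ignore.strand = TRUE)))
  u <- sum(GenomicRanges::width(GenomicRanges::union(
    reduce_all(a), reduce_all(b), ignore.strand = TRUE)))
  if (u == 0) return(1)
  i / u
}

# small synthetic pair shared by engine-level tests
small_planted_pair <- function(seed = 7, L = 2e5, n_dmrs = 4,
                               context = "CG") {
  generate_pair(synthetic_spec(
    L, context, plant_dmrs(n_dmrs, 1000, context, 0, L), seed = seed))
}

# a minimal well-formed DMR GRanges for export/filter tests
mk_dmr_granges <- function(start, end, adjp = 1e-3, dir = "loss") {
  GenomicRanges::GRanges(
    seqnames = "chr1", ranges = IRanges::IRanges(start, end), strand = "*",
    context = "CG", direction = dir,
    readsM1 = 80, readsN1 = 100, readsM2 = 5, readsN2 = 100,
    proportion1 = 0.8, proportion2 = 0.05, cytosinesCount = 5,
    statistic = -10, pValue = adjp / 10, adjustedPValue = adjp,
    regionType = "merged")
}
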