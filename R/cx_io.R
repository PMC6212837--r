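#' @title CX report input/output and replicate pooling
#' @name cx_io
#' @description Readers and writers for Bismark-style CX reports, DMR
#'   tables (TSV/BED) and region annotations, plus pooling of biological
#'   replicates.
NULL

.CONTEXTS <- c("CG", "CHG", "CHH")

# condition constructors: data errors (exit 1) vs usage errors (exit 2)
mdmr_data_error <- function(msg) {
  stop(structure(class = c("mdmr_data_error", "error", "condition"),
                 list(message = msg, call = NULL)))
}
mdmr_usage_error <- function(msg) {
  stop(structure(class = c("mdmr_usage_error", "error", "condition"),
                 list(message = msg, call = NULL)))
}

#' Construct a methylome object
#'
#' A methylome is a [GenomicRanges::GRanges] of width-1 ranges (one per
#' cytosine, 1-based coordinates) carrying the metadata columns `readsM`
#' (methylated read count), `readsN` (total read count), `context`
#' (`"CG"`, `"CHG"` or `"CHH"`) and `trinucleotide`. Cytosines on the two
#' strands are independent positions. Records are sorted by
#' (chromosome, position, strand) and duplicates are rejected.
#'
#' @param chrom chromosome names.
#' @param pos 1-based positions (>= 1).
#' @param strand `"+"` or `"-"`.
#' @param readsM,readsN methylated and total read counts, `0 <= readsM <=
#'   readsN`. Zero-coverage cytosines are retained: they carry positional
#'   information for smoothing and cytosine counting.
#' @param context cytosine context labels.
#' @param trinucleotide trinucleotide labels (defaults to the context).
#' @param sample optional sample label stored in `metadata(x)$sample`.
#' @return a `GRanges` methylome.
#' @export
methylome <- function(chrom, pos, strand, readsM, readsN, context,
                      trinucleotide = context, sample = "") {
  n <- length(pos)
  if (n == 0L) {
    gr <- GenomicRanges::GRanges()
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
      readsM = numeric(0), readsN = numeric(0),
      context = character(0), trinucleotide = character(0))
    S4Vectors::metadata(gr)$sample <- sample
    return(gr)
  }
  chrom <- rep_len(as.character(chrom), n)
  strand <- rep_len(as.character(strand), n)
  readsM <- rep_len(as.numeric(readsM), n)
  readsN <- rep_len(as.numeric(readsN), n)
  context <- rep_len(as.character(context), n)
  trinucleotide <- rep_len(as.character(trinucleotide), n)
  if (any(pos < 1)) mdmr_data_error("positions must be >= 1")
  if (!all(strand %in% c("+", "-")))
    mdmr_data_error("strand must be '+' or '-'")
  if (!all(context %in% .CONTEXTS))
    mdmr_data_error("context must be one of CG, CHG, CHH")
  if (any(readsM < 0) || any(readsM > readsN))
    mdmr_data_error("counts must satisfy 0 <= readsM <= readsN")
  o <- order(chrom, pos, strand, method = "radix")
  key <- paste(chrom, pos, strand, sep = ":")
  if (anyDuplicated(key))
    mdmr_data_error("duplicate (chrom, pos, strand) records")
  gr <- GenomicRanges::GRanges(
    seqnames = chrom[o],
    ranges = IRanges::IRanges(start = pos[o], width = 1L),
    strand = strand[o],
    readsM = readsM[o], readsN = readsN[o],
    context = context[o],
    trinucleotide = trinucleotide[o])
  S4Vectors::metadata(gr)$sample <- sample
  gr
}

# methylome GRanges -> data.table(chrom, pos, strand_, M, N, ctx, tri)
.as_dt <- function(x) {
  data.table::data.table(
    chrom = as.character(GenomicRanges::seqnames(x)),
    pos = GenomicRanges::start(x),
    strand_ = as.character(GenomicRanges::strand(x)),
    M = S4Vectors::mcols(x)$readsM,
    N = S4Vectors::mcols(x)$readsN,
    ctx = S4Vectors::mcols(x)$context,
    tri = S4Vectors::mcols(x)$trinucleotide)
}

.from_dt <- function(dt, sample = "") {
  methylome(dt$chrom, dt$pos, dt$strand_, dt$M, dt$N, dt$ctx, dt$tri,
            sample = sample)
}

.is_gzip <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", n = 2L)
  length(magic) == 2L && magic[1] == as.raw(0x1f) && magic[2] == as.raw(0x8b)
}

#' Read a Bismark-style CX report
#'
#' Parses a 7-column tab-delimited CX report (chromosome, position,
#' strand, methylated read count, total read count, context,
#' trinucleotide; no header). Gzip-compressed files are detected by file
#' magic. Malformed lines are reported with their line numbers.
#'
#' @param path path to the CX report.
#' @param contexts contexts to keep; default all of CG, CHG, CHH.
#' @param sample sample label attached to the result.
#' @return a methylome `GRanges` (see [methylome()]).
#' @examples
#' f <- tempfile(fileext = ".cx")
#' writeLines("chr1\t100\t+\t5\t10\tCG\tCGT", f)
#' read_cx_report(f)
#' @export
read_cx_report <- function(path, contexts = .CONTEXTS, sample = basename(path)) {
  if (!file.exists(path))
    mdmr_data_error(sprintf("CX report not found: %s", path))
  if (!all(contexts %in% .CONTEXTS))
    mdmr_usage_error("contexts must be a subset of CG, CHG, CHH")
  lines <- if (.is_gzip(path)) {
    con <- gzfile(path, "rt"); on.exit(close(con)); readLines(con)
  } else readLines(path)
  keep <- nzchar(lines)
  lineno <- which(keep)   # original line numbers of non-empty lines
  lines <- lines[keep]
  if (length(lines) == 0L) {
    warning(sprintf("empty CX report: %s", path))
    return(methylome(character(0), integer(0), character(0), numeric(0),
                     numeric(0), character(0), sample = sample))
  }
  dt <- data.table::fread(text = lines, sep = "\t", header = FALSE,
                          colClasses = "character", fill = TRUE)
  .bad_line <- function(ok, what) {
    if (!all(ok))
      mdmr_data_error(sprintf("line %d: %s", lineno[which(!ok)[1]], what))
  }
  if (ncol(dt) < 7L) {
    nf <- vapply(strsplit(lines, "\t", fixed = TRUE), length, integer(1))
    .bad_line(nf >= 7L, "fewer than 7 tab-separated fields")
  }
  complete <- !Reduce(`|`, lapply(dt[, 1:7], function(v) is.na(v) | v == ""))
  .bad_line(complete, "fewer than 7 tab-separated fields")
  .bad_line(grepl("^[0-9]+$", dt$V2), "position is not a non-negative integer")
  .bad_line(dt$V3 %in% c("+", "-"), "strand must be '+' or '-'")
  .bad_line(grepl("^[0-9]+$", dt$V4), "non-integer methylated read count")
  .bad_line(grepl("^[0-9]+$", dt$V5), "non-integer total read count")
  .bad_line(dt$V6 %in% .CONTEXTS, "unknown context label")
  pos <- as.integer(dt$V2)
  m <- as.numeric(dt$V4)
  n <- as.numeric(dt$V5)
  .bad_line(pos >= 1L, "position must be >= 1")
  .bad_line(m <= n, "methylated reads exceed total reads")
  # context/trinucleotide consistency (trusted when the trinucleotide has N)
  tri <- toupper(dt$V7)
  noN <- !grepl("N", tri) & nchar(tri) == 3L
  b2 <- substr(tri, 2, 2); b3 <- substr(tri, 3, 3)
  expected <- ifelse(b2 == "G", "CG", ifelse(b3 == "G", "CHG", "CHH"))
  .bad_line(!noN | expected == dt$V6,
            "context label inconsistent with trinucleotide")
  sel <- dt$V6 %in% contexts
  methylome(dt$V1[sel], pos[sel], dt$V3[sel], m[sel], n[sel], dt$V6[sel],
            tri[sel], sample = sample)
}

#' Write a methylome as a CX report
#'
#' Inverse of [read_cx_report()]: 7-column tab-delimited text, no header.
#'
#' @param data a methylome `GRanges`.
#' @param path output path.
#' @export
write_cx_report <- function(data, path) {
  dt <- .as_dt(data)
  dt[, M := as.integer(round(M))][, N := as.integer(round(N))]
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Pool biological replicates
#'
#' Sums methylated and total read counts at each (chromosome, position,
#' strand) over a list of methylomes. Positions absent from a replicate
#' contribute zero reads. Context labels must agree at shared positions.
#'
#' Pooling is commutative and associative in the list of inputs.
#'
#' @param datasets a methylome `GRanges` or a list of them.
#' @param sample sample label of the pooled methylome.
#' @return a methylome `GRanges` with summed counts.
#' @export
pool_replicates <- function(datasets, sample = "pooled") {
  if (methods::is(datasets, "GRanges")) datasets <- list(datasets)
  if (length(datasets) < 1L) mdmr_usage_error("need at least one dataset")
  if (length(datasets) == 1L) return(datasets[[1]])
  dt <- data.table::rbindlist(lapply(datasets, .as_dt))
  nctx <- dt[, list(k = length(unique(ctx))), by = c("chrom", "pos", "strand_")]
  if (any(nctx$k > 1L))
    mdmr_data_error("conflicting context labels at a shared position")
  pooled <- dt[, list(M = sum(M), N = sum(N), ctx = ctx[1], tri = tri[1]),
               by = c("chrom", "pos", "strand_")]
  .from_dt(pooled, sample = sample)
}

#' Pool symmetric CpG strand pairs
#'
#' Optionally collapses a minus-strand CG cytosine at position p+1 onto
#' its plus-strand partner at position p by summing the counts; records
#' without a partner are left unchanged. Off by default throughout the
#' package: strands are treated as independent positions.
#'
#' @param data a methylome `GRanges`.
#' @return a methylome `GRanges` with CG pairs collapsed.
#' @export
pool_cpg_pairs <- function(data) {
  dt <- .as_dt(data)
  cg_plus <- dt[ctx == "CG" & strand_ == "+"]
  cg_minus <- dt[ctx == "CG" & strand_ == "-"]
  key <- paste(cg_plus$chrom, cg_plus$pos + 1L)
  idx <- match(paste(cg_minus$chrom, cg_minus$pos), key)
  hit <- !is.na(idx)
  if (any(hit)) {
    agg <- data.table::data.table(i = idx[hit], M = cg_minus$M[hit],
                                  N = cg_minus$N[hit])
    add <- agg[, list(M = sum(M), N = sum(N)), by = "i"]
    cg_plus[add$i, `:=`(M = M + add$M, N = N + add$N)]
  }
  out <- data.table::rbindlist(list(
    dt[ctx != "CG"], cg_plus, cg_minus[!hit]))
  .from_dt(out, sample = S4Vectors::metadata(data)$sample)
}

.DMR_COLS <- c("chrom", "start", "end", "context", "direction",
               "readsM1", "readsN1", "readsM2", "readsN2",
               "proportion1", "proportion2", "cytosinesCount",
               "statistic", "pValue", "adjustedPValue")

#' Write called DMRs to disk
#'
#' `format = "tsv"` writes a header plus one row per DMR with columns
#' chrom, start, end (1-based closed), context, direction, pooled counts,
#' proportions, cytosine count, statistic, raw and adjusted p-value.
#' `format = "bed"` writes BED6 (0-based half-open), `name =
#' context:direction` and `score = min(1000, round(-10 log10(adjusted
#' p)))` with the p-value clipped at 1e-100.
#'
#' @param dmrs a `GRanges` of DMRs as returned by [call_dmrs()], sorted
#'   and non-overlapping.
#' @param path output path.
#' @param format `"tsv"` or `"bed"`.
#' @export
write_dmrs <- function(dmrs, path, format = c("tsv", "bed")) {
  format <- match.arg(format)
  mc <- S4Vectors::mcols(dmrs)
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(dmrs)),
    start = GenomicRanges::start(dmrs),
    end = GenomicRanges::end(dmrs),
    context = mc$context, direction = mc$direction,
    readsM1 = mc$readsM1, readsN1 = mc$readsN1,
    readsM2 = mc$readsM2, readsN2 = mc$readsN2,
    proportion1 = mc$proportion1, proportion2 = mc$proportion2,
    cytosinesCount = mc$cytosinesCount, statistic = mc$statistic,
    pValue = mc$pValue, adjustedPValue = mc$adjustedPValue,
    stringsAsFactors = FALSE)
  if (format == "tsv") {
    utils::write.table(df[, .DMR_COLS], path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
  } else {
    score <- pmin(1000, round(-10 * log10(pmax(df$adjustedPValue, 1e-100))))
    nm <- if (nrow(df)) paste0(df$context, ":", df$direction) else character(0)
    bed <- data.frame(df$chrom, df$start - 1L, df$end, nm, score,
                      rep(".", nrow(df)))
    utils::write.table(bed, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Read a region annotation (BED or GFF3)
#'
#' Regions are normalised to 1-based closed coordinates (the internal
#' convention); BED input (0-based half-open) is converted on import.
#'
#' @param path a `.bed`, `.gff`, `.gff3` or `.gtf` file.
#' @return a `GRanges` of regions.
#' @export
read_regions <- function(path) {
  if (!file.exists(path))
    mdmr_data_error(sprintf("region annotation not found: %s", path))
  ext <- tolower(tools::file_ext(sub("[.]gz$", "", path)))
  fmt <- switch(ext, bed = "BED", gff = "GFF3", gff3 = "GFF3",
                gtf = "GTF", NULL)
  if (is.null(fmt))
    mdmr_usage_error("region annotation must be BED, GFF3 or GTF")
  rtracklayer::import(path, format = fmt)
}
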