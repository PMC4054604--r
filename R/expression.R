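# Evaluate code under a temporary RNG state when seed is non-NULL.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has_old) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Down-sample a count vector to a target library size
#'
#' Multivariate hypergeometric sampling without replacement: reads are
#' removed uniformly at random until exactly `target_total` remain, so
#' relative abundances are preserved in expectation.
#'
#' @param counts non-negative integer vector (per-locus read counts).
#' @param target_total required total after down-sampling (<= sum(counts)).
#' @param seed optional integer for reproducibility.
#' @return integer-valued vector, same length, summing to `target_total`.
#' @export
downsample_counts <- function(counts, target_total, seed = NULL) {
  total <- sum(counts)
  if (target_total > total) stop("target exceeds total read count")
  if (target_total == total) return(counts)
  with_seed(seed, {
    out <- numeric(length(counts))
    remaining_total <- total
    k <- target_total
    for (i in seq_along(counts)) {
      if (k == 0) break
      remaining_total <- remaining_total - counts[i]
      # draws from locus i given k still to allocate among i..n
      xi <- stats::rhyper(1, counts[i], remaining_total, k)
      out[i] <- xi
      k <- k - xi
    }
    out
  })
}

#' Simplified trimmed-mean-of-M-values normalisation factors
#'
#' For each library against a reference (the library whose size is closest
#' to the median library size), M = log2(x/ref) and A = 0.5 log2(x * ref)
#' are computed on loci expressed in both; the central `stable_fraction`
#' by M and by A is retained (symmetric trimming) and the factor is
#' `2^mean(M)`. Dividing a library's counts by its factor equalises the
#' stably expressed core across libraries (the factor plays the role of a
#' normalised library-size ratio; it equals 1 for identical libraries and
#' stays near 1 when a trimmed minority of loci changes). This is an
#' unweighted reimplementation assuming most loci are stably expressed; it
#' deliberately omits edgeR's precision weights and library-size
#' pre-division.
#'
#' @param count_matrix loci x libraries count matrix (>= 2 columns).
#' @param stable_fraction fraction of loci assumed stably expressed.
#' @param reference optional library index; default is the median-size one.
#' @return named numeric vector of per-library scale factors (reference 1).
#' @export
tmm_factors <- function(count_matrix, stable_fraction = 0.6,
                        reference = NULL) {
  m <- as.matrix(count_matrix)
  if (ncol(m) < 2L) stop("need at least 2 libraries")
  N <- colSums(m)
  if (is.null(reference))
    reference <- which.min(abs(N - stats::median(N)))
  r <- m[, reference]
  lo <- (1 - stable_fraction) / 2
  hi <- 1 - lo
  f <- vapply(seq_len(ncol(m)), function(j) {
    if (j == reference) return(1)
    x <- m[, j]
    both <- x > 0 & r > 0
    if (!any(both)) stop("library ", j, " shares no expressed loci with the reference")
    M <- log2(x[both] / r[both])
    A <- 0.5 * log2(x[both] * r[both])
    qm <- stats::quantile(M, c(lo, hi), names = FALSE)
    qa <- stats::quantile(A, c(lo, hi), names = FALSE)
    keep <- M >= qm[1] & M <= qm[2] & A >= qa[1] & A <= qa[2]
    if (!any(keep)) keep <- rep(TRUE, length(M))
    2^mean(M[keep])
  }, numeric(1))
  names(f) <- colnames(m)
  f
}

#' Fragments per kilobase per million mapped reads
#'
#' @param counts reads mapped to the locus (its constitutive exons).
#' @param length_bp summed constitutive exon length (> 0).
#' @param mapped_reads total mapped reads in the library (> 0).
#' @return FPKM values.
#' @export
fpkm <- function(counts, length_bp, mapped_reads) {
  if (any(length_bp <= 0)) stop("length_bp must be > 0")
  if (any(mapped_reads <= 0)) stop("mapped_reads must be > 0")
  counts / (length_bp / 1e3) / (mapped_reads / 1e6)
}

#' Constitutive exonic bases of a gene
#'
#' Genomic bases present in every isoform's exon set. When the isoforms
#' share no base, falls back to the exon union with a warning.
#'
#' @param exons exon table of one gene (transcript_id, chrom, start, end).
#' @return `data.table` of disjoint intervals (chrom, start, end).
#' @export
constitutive_exons <- function(exons) {
  ex <- data.table::as.data.table(exons)
  if (nrow(ex) == 0L) stop("no exons supplied")
  n_iso <- length(unique(ex$transcript_id))
  ir <- IRanges::IRanges(ex$start + 1, ex$end)
  cov <- IRanges::coverage(ir)
  core <- IRanges::slice(cov, lower = n_iso, rangesOnly = TRUE)
  if (length(core) == 0L) {
    warning("isoforms share no constitutive base; using exon union")
    core <- IRanges::reduce(ir)
  }
  data.table::data.table(chrom = ex$chrom[1L],
                         start = IRanges::start(core) - 1,
                         end = as.numeric(IRanges::end(core)))
}

#' Tissue-specificity scores for one locus
#'
#' `Ts_i = x_i / sum(x)`: the fractional expression in each condition;
#' `max_ts` is its maximum (1/N for uniform expression, 1 for single-tissue
#' expression). The alternate fold-over-median score is
#' `max(x) / max(median(x), pseudocount)`.
#'
#' @param x non-negative expression vector over N >= 2 conditions.
#' @param pseudocount floor for the median in the alternate score.
#' @return list with `ts` (vector summing to 1), `max_ts`, `argmax`
#'   (condition index), `fold_over_median`; all `NA` for an all-zero vector.
#' @export
tissue_specificity <- function(x, pseudocount = 0.01) {
  if (length(x) < 2L) stop("need at least 2 conditions")
  if (any(x < 0)) stop("negative expression")
  if (sum(x) == 0)
    return(list(ts = rep(NA_real_, length(x)), max_ts = NA_real_,
                argmax = NA_integer_, fold_over_median = NA_real_))
  ts <- x / sum(x)
  list(ts = ts, max_ts = max(ts), argmax = which.max(ts),
       fold_over_median = max(x) / max(stats::median(x), pseudocount))
}

#' Tissue specificity over a matrix of loci
#'
#' @param m loci x conditions matrix.
#' @inheritParams tissue_specificity
#' @return `data.table`: locus, max_ts, top_condition, fold_over_median.
#' @export
tissue_specificity_matrix <- function(m, pseudocount = 0.01) {
  res <- apply(m, 1L, tissue_specificity, pseudocount = pseudocount,
               simplify = FALSE)
  data.table::data.table(
    locus = rownames(m),
    max_ts = vapply(res, `[[`, numeric(1), "max_ts"),
    top_condition = colnames(m)[vapply(res, function(r)
      ifelse(is.na(r$argmax), NA_integer_, r$argmax), integer(1))],
    fold_over_median = vapply(res, `[[`, numeric(1), "fold_over_median"))
}

#' Number of developmental stages with detectable expression
#'
#' @param x expression vector (or loci x stages matrix) over stages.
#' @param threshold detection threshold; a stage counts when value is
#'   strictly greater.
#' @return integer count(s) in 0..n_stages.
#' @export
stage_detection <- function(x, threshold = 0) {
  if (is.matrix(x)) return(rowSums(x > threshold))
  sum(x > threshold)
}
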