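#' Chromatin coverage track for one mark
#'
#' Piecewise-constant coverage (bedGraph segments at any bin size) plus the
#' library size used for per-million normalisation. Coverage between
#' segments is 0.
#'
#' @param cov `data.table` with chrom, start, end, value (0-based half-open).
#' @param mark mark name, e.g. `"H3K4me1"`.
#' @param library_size total read-equivalents in the library (> 0).
#' @return object of class `chromatin_track`.
#' @export
chromatin_track <- function(cov, mark, library_size) {
  cov <- data.table::as.data.table(cov)
  if (!all(c("chrom", "start", "end", "value") %in% names(cov)))
    stop("coverage needs chrom/start/end/value columns")
  if (nrow(cov) && any(cov$value < 0)) stop("coverage must be >= 0")
  if (!is.finite(library_size) || library_size <= 0)
    stop("library_size must be > 0")
  data.table::setorder(cov, chrom, start)
  structure(list(cov = cov[], mark = mark, library_size = library_size),
            class = "chromatin_track")
}

#' @export
print.chromatin_track <- function(x, ...) {
  cat("chromatin_track:", x$mark, "-", nrow(x$cov), "segments, library",
      format(x$library_size, big.mark = ","), "\n")
  invisible(x)
}

# Summed coverage over arbitrary windows (clipped below 0 by caller).
# Returns one sum per window row.
track_window_sums <- function(track, chrom, w_start, w_end) {
  n <- length(w_start)
  out <- numeric(n)
  keep <- w_end > w_start
  if (!any(keep) || nrow(track$cov) == 0L) return(out)
  qg <- GenomicRanges::GRanges(chrom[keep],
                               IRanges::IRanges(w_start[keep] + 1,
                                                w_end[keep]))
  sg <- GenomicRanges::GRanges(track$cov$chrom,
                               IRanges::IRanges(track$cov$start + 1,
                                                track$cov$end))
  ov <- GenomicRanges::findOverlaps(qg, sg, ignore.strand = TRUE)
  if (length(ov)) {
    qi <- S4Vectors::queryHits(ov)
    si <- S4Vectors::subjectHits(ov)
    isect <- pmin(w_end[keep][qi], track$cov$end[si]) -
      pmax(w_start[keep][qi], track$cov$start[si])
    sums <- tapply(isect * track$cov$value[si], qi, sum)
    out[keep][as.integer(names(sums))] <- as.numeric(sums)
  }
  out
}

#' Per-region normalised mark score
#'
#' Coverage summed in a window of `window` bp centred on each region's
#' midpoint, scaled to reads-per-million by the track's library size. The
#' window is clipped at chromosome edges.
#'
#' @param track a [chromatin_track()].
#' @param regions interval table with chrom/start/end.
#' @param window full window width (bp).
#' @param genome optional [genome_model()] for right-edge clipping.
#' @return numeric vector of scores, one per region.
#' @export
quantify_mark <- function(track, regions, window = 2000, genome = NULL) {
  if (track$library_size <= 0) stop("library_size must be > 0")
  mid <- floor((regions$start + regions$end) / 2)
  ws <- pmax(0, mid - window / 2)
  we <- mid + window / 2
  if (!is.null(genome)) we <- pmin(we, genome$chrom_lengths[regions$chrom])
  track_window_sums(track, regions$chrom, ws, we) * 1e6 / track$library_size
}

#' Classify regions as enhancer-like or promoter-like
#'
#' Label by the sign of `me1_score - me3_score`: positive is enhancer-like
#' (H3K4me1-dominant), negative promoter-like, exact ties ambiguous.
#'
#' @param me1_scores,me3_scores paired per-region normalised scores.
#' @param pseudocount added to both scores for the reported log2 ratio.
#' @param ids optional region ids.
#' @return `data.table`: id, me1_score, me3_score, diff, log2_ratio, label.
#' @export
classify_regions <- function(me1_scores, me3_scores, pseudocount = 1.0,
                             ids = NULL) {
  if (length(me1_scores) != length(me3_scores))
    stop("score vectors differ in length")
  if (any(me1_scores < 0) || any(me3_scores < 0))
    stop("scores must be non-negative")
  if (is.null(ids)) ids <- sprintf("region_%05d", seq_along(me1_scores))
  diff <- me1_scores - me3_scores
  label <- ifelse(diff > 0, "enhancer_like",
                  ifelse(diff < 0, "promoter_like", "ambiguous"))
  data.table::data.table(
    id = ids, me1_score = me1_scores, me3_score = me3_scores, diff = diff,
    log2_ratio = log2((me1_scores + pseudocount) /
                        (me3_scores + pseudocount)),
    label = label)
}

#' Region-by-offset signal matrix around region midpoints
#'
#' For each region, per-million-normalised mean coverage in `window/bin`
#' bins across a `window` bp span centred on the region midpoint. Rows are
#' ordered by decreasing `sort_by` when given. Out-of-chromosome bases
#' contribute 0, so row sums times `bin` equal the clipped window totals of
#' [quantify_mark()].
#'
#' @param track a [chromatin_track()].
#' @param regions interval table (chrom/start/end; ids taken from `name` or
#'   `id` column when present).
#' @param window full span (bp); must be divisible by `bin`.
#' @param bin bin width (bp).
#' @param sort_by numeric vector (length = regions); rows sorted decreasing.
#' @return object of class `signal_matrix`: list with `matrix` (rownames =
#'   region ids), `offsets` (bin start offsets from midpoint), `order`
#'   (permutation applied), `window`, `bin`.
#' @export
signal_matrix <- function(track, regions, window = 4000, bin = 50,
                          sort_by = NULL) {
  if (window %% bin != 0) stop("window must be divisible by bin")
  n <- nrow(regions)
  if (n == 0L) stop("empty region set")
  nb <- window %/% bin
  ids <- if ("id" %in% names(regions)) regions$id
         else if ("name" %in% names(regions) &&
                  !all(regions$name == ".")) regions$name
         else sprintf("region_%05d", seq_len(n))
  mid <- floor((regions$start + regions$end) / 2)
  offsets <- seq(-window / 2, window / 2 - bin, by = bin)
  bstart <- rep(mid, each = nb) + rep(offsets, times = n)
  bchrom <- rep(regions$chrom, each = nb)
  sums <- track_window_sums(track, bchrom, pmax(0, bstart),
                            pmax(0, bstart + bin))
  m <- matrix(sums * 1e6 / track$library_size / bin,
              nrow = n, ncol = nb, byrow = TRUE,
              dimnames = list(ids, offsets))
  ord <- if (is.null(sort_by)) seq_len(n) else order(-sort_by)
  structure(list(matrix = m[ord, , drop = FALSE], offsets = offsets,
                 order = ord, window = window, bin = bin),
            class = "signal_matrix")
}

#' Strand-aware metaprofile over a region set
#'
#' Column means of the [signal_matrix()], with rows of minus-strand regions
#' reversed first so positive offsets always point downstream of
#' transcription.
#'
#' @inheritParams signal_matrix
#' @return named numeric vector (names = bin start offsets, 5' to 3').
#' @export
metaprofile <- function(track, regions, window = 4000, bin = 50) {
  if (nrow(regions) == 0L) stop("empty region set")
  sm <- signal_matrix(track, regions, window, bin)
  m <- sm$matrix
  if ("strand" %in% names(regions)) {
    neg <- which(regions$strand == "-")
    if (length(neg)) m[neg, ] <- m[neg, ncol(m):1, drop = FALSE]
  }
  stats::setNames(colMeans(m), colnames(m))
}

#' Strand-specific read 5'-end profile around TSSs
#'
#' Counts tag 5' ends at each offset in \[-flank, +flank\] relative to each
#' TSS, in transcription orientation, split into sense (tag strand equals
#' TSS strand) and antisense, summed over all TSSs.
#'
#' @param tags a [tag_set()] of read 5'-end positions.
#' @param tss_list `data.table` with chrom, pos (0-based), strand.
#' @param flank half-window (bp): 50 for poly(A)+, 200 for poly(A)- data.
#' @return list with `offsets` (-flank..flank), `sense`, `antisense`
#'   (count vectors).
#' @export
stranded_tss_profile <- function(tags, tss_list, flank = 50) {
  offsets <- seq(-flank, flank)
  sense <- antisense <- stats::setNames(numeric(length(offsets)), offsets)
  if (nrow(tags) == 0L || nrow(tss_list) == 0L)
    return(list(offsets = offsets, sense = sense, antisense = antisense))
  tg <- data.table::as.data.table(tags)
  for (i in seq_len(nrow(tss_list))) {
    ch <- tss_list$chrom[i]; p <- tss_list$pos[i]; st <- tss_list$strand[i]
    near <- tg[tg$chrom == ch & abs(tg$pos - p) <= flank, ]
    if (nrow(near) == 0L) next
    off <- if (st == "-") p - near$pos else near$pos - p
    is_sense <- near$strand == st
    idx <- off + flank + 1L
    for (j in seq_len(nrow(near))) {
      if (is_sense[j]) sense[idx[j]] <- sense[idx[j]] + near$count[j]
      else antisense[idx[j]] <- antisense[idx[j]] + near$count[j]
    }
  }
  list(offsets = offsets, sense = sense, antisense = antisense)
}

#' Sliding-window tag density track
#'
#' Tag counts per strand in windows of `window` bp advanced by `step` bp on
#' a step-aligned grid; windows with no tags are omitted.
#'
#' @param tags a [tag_set()].
#' @param window window width (bp); must be divisible by `step`.
#' @param step window increment (bp).
#' @return `data.table` with chrom, strand, start, end, value (tag count).
#' @export
tag_density_track <- function(tags, window = 100, step = 10) {
  empty <- data.table::data.table(chrom = character(), strand = character(),
                                  start = numeric(), end = numeric(),
                                  value = numeric())
  if (nrow(tags) == 0L) return(empty)
  if (window %% step != 0) stop("window must be divisible by step")
  dt <- data.table::as.data.table(tags)
  k <- window %/% step
  # tag at p falls in windows starting at step*j for j in [ceil((p-window+1)/step), floor(p/step)]
  expand <- dt[rep(seq_len(.N), each = k)]
  expand[, wj := rep(seq_len(k) - 1L, times = nrow(dt))]
  expand[, wstart := (pos %/% step - wj) * step]
  expand <- expand[wstart >= 0 & pos < wstart + window & pos >= wstart]
  out <- expand[, list(value = sum(count)),
                by = list(chrom, strand, start = wstart)]
  out[, end := start + window]
  data.table::setorder(out, chrom, strand, start)
  out[, list(chrom, strand, start, end, value)]
}
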