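#' Tag set: strand-specific single-base 5'-end positions
#'
#' @param chrom,pos,strand,count vectors (pos is 0-based bp; count >= 1).
#' @param genome optional [genome_model()] for bounds checking.
#' @return `data.table` of class `tag_set`, aggregated per
#'   (chrom, strand, pos) and sorted.
#' @export
tag_set <- function(chrom, pos, strand, count = 1L, genome = NULL) {
  dt <- data.table::data.table(chrom = as.character(chrom),
                               pos = as.numeric(pos),
                               strand = as.character(strand),
                               count = as.numeric(count))
  if (nrow(dt)) {
    if (any(!dt$strand %in% c("+", "-"))) stop("tag strand must be + or -")
    if (any(dt$count < 1)) stop("tag multiplicity must be >= 1")
    if (any(dt$pos < 0)) stop("negative tag position")
    if (!is.null(genome)) {
      if (any(!dt$chrom %in% genome$chrom_names))
        stop("tag chromosome not in genome model")
      if (any(dt$pos >= genome$chrom_lengths[dt$chrom]))
        stop("tag position beyond chromosome end")
    }
  }
  dt <- dt[, list(count = sum(count)), by = c("chrom", "strand", "pos")]
  data.table::setorder(dt, chrom, strand, pos)
  data.table::setattr(dt, "class", c("tag_set", class(dt)))
  dt[]
}

#' Read tag 5'-end positions from BED6
#'
#' Each record must be a single-base interval; the score column, when
#' positive, is taken as read multiplicity (0 or absent means 1).
#' @param path BED6 file.
#' @param genome optional [genome_model()].
#' @return a [tag_set()].
#' @export
read_tags_bed <- function(path, genome = NULL) {
  bed <- read_bed(path, genome)
  if (nrow(bed) && any(bed$end - bed$start != 1))
    stop("tag BED must contain single-base records")
  count <- ifelse(bed$score > 0, bed$score, 1)
  tag_set(bed$chrom, bed$start, bed$strand, count, genome = genome)
}

#' Cluster tag positions by single linkage
#'
#' Tags on the same chromosome and strand whose positions differ by at most
#' `max_gap` bp are chained into one cluster (single linkage, transitive).
#' The boundary is inclusive: positions exactly `max_gap` apart join.
#'
#' @param tags a [tag_set()].
#' @param max_gap maximum position difference joining consecutive tags (bp).
#' @return `data.table` with chrom, strand, start, end (half-open hull of
#'   member positions), n_reads, n_positions, positions (list column).
#' @export
cluster_tags <- function(tags, max_gap = 20) {
  empty <- data.table::data.table(chrom = character(), strand = character(),
                                  start = numeric(), end = numeric(),
                                  n_reads = numeric(), n_positions = integer(),
                                  positions = list())
  if (nrow(tags) == 0L) return(empty)
  dt <- data.table::as.data.table(tags)
  data.table::setorder(dt, chrom, strand, pos)
  dt[, cl := cumsum(c(1L, (diff(pos) > max_gap))), by = c("chrom", "strand")]
  out <- dt[, list(start = min(pos), end = max(pos) + 1,
                   n_reads = sum(count), n_positions = .N,
                   positions = list(pos)),
            by = c("chrom", "strand", "cl")]
  out[, cl := NULL]
  data.table::setorder(out, chrom, start, strand)
  out[]
}

#' Merge tag clusters into TIRs
#'
#' Same-strand clusters whose edge-to-edge gap is at most `merge_dist` bp are
#' merged transitively; the TIR span is the hull of its member clusters and
#' read support is summed. Strands never mix.
#'
#' @param clusters output of [cluster_tags()].
#' @param merge_dist maximum edge-to-edge gap merged (bp, inclusive).
#' @return `data.table` with id, chrom, strand, start, end, n_reads,
#'   n_clusters, dhs_overlap (NA until [filter_tirs()]).
#' @export
merge_clusters <- function(clusters, merge_dist = 400) {
  empty <- data.table::data.table(id = character(), chrom = character(),
                                  strand = character(), start = numeric(),
                                  end = numeric(), n_reads = numeric(),
                                  n_clusters = integer(),
                                  dhs_overlap = logical())
  if (nrow(clusters) == 0L) return(empty)
  dt <- data.table::as.data.table(clusters)
  data.table::setorder(dt, chrom, strand, start)
  dt[, grp := {
    hi <- cummax(data.table::shift(end, fill = -Inf))
    cumsum(start - hi > merge_dist)
  }, by = c("chrom", "strand")]
  out <- dt[, list(start = min(start), end = max(end),
                   n_reads = sum(n_reads), n_clusters = .N),
            by = c("chrom", "strand", "grp")]
  out[, grp := NULL]
  data.table::setorder(out, chrom, start, strand)
  out[, id := sprintf("TIR_%05d", seq_len(.N))]
  out[, dhs_overlap := NA]
  data.table::setcolorder(out, c("id", "chrom", "strand", "start", "end",
                                 "n_reads", "n_clusters", "dhs_overlap"))
  out[]
}

#' Filter TIRs by read support and DHS overlap
#'
#' Retains TIRs supported by at least `min_reads` tags that overlap at least
#' one DNase hypersensitive site peak by `min_overlap` bp or more.
#'
#' @param tirs output of [merge_clusters()].
#' @param min_reads minimum read support (kept when `n_reads >= min_reads`).
#' @param dhs_peaks strandless peak intervals ([gintervals()] or data.table).
#' @param min_overlap minimum overlap with a peak in bp.
#' @return filtered TIR table with `dhs_overlap` filled in.
#' @export
filter_tirs <- function(tirs, min_reads = 5, dhs_peaks, min_overlap = 1) {
  dt <- data.table::as.data.table(tirs)
  if (nrow(dt) == 0L) return(dt)
  if (nrow(dhs_peaks) == 0L) {
    dt[, dhs_overlap := FALSE]
  } else {
    q <- GenomicRanges::GRanges(dt$chrom,
                                IRanges::IRanges(dt$start + 1L, dt$end))
    s <- GenomicRanges::GRanges(dhs_peaks$chrom,
                                IRanges::IRanges(dhs_peaks$start + 1L,
                                                 dhs_peaks$end))
    hit <- suppressWarnings(
      GenomicRanges::countOverlaps(q, s, minoverlap = min_overlap,
                                   ignore.strand = TRUE)) > 0L
    dt[, dhs_overlap := hit]
  }
  out <- dt[dt$n_reads >= min_reads & dt$dhs_overlap, ]
  out[]
}

# 5' end position (0-based single base) of a stranded span
tss_position <- function(start, end, strand) {
  ifelse(strand == "-", end - 1, start)
}

#' Associate TIRs with transcript models
#'
#' A TIR is linked to a stranded transcript when (i) it overlaps one of the
#' transcript's exons by at least `min_overlap` bp, (ii) strands match, and
#' (iii) the TIR intersects a window of `tss_window` bp around the
#' transcript's 5' end (so internal-exon tags cannot claim a transcript).
#' Mono-exonic transcripts with strand `.` are linked only when exactly one
#' of their two possible 5' ends has a candidate TIR; their strand is then
#' imputed so that end is 5'. Transcripts with no linked TIR are dropped.
#'
#' @param tirs filtered TIR table.
#' @param txs a `transcript_set` (see [read_gtf()]).
#' @param min_overlap minimum exon overlap (bp).
#' @param tss_window half-width of the 5'-end window (bp).
#' @return list with `links` (tir_id, transcript_id), `transcripts` (a
#'   `transcript_set` of linked transcripts, strands imputed) and `dropped`
#'   (transcript_id, reason).
#' @export
associate_transcripts <- function(tirs, txs, min_overlap = 1,
                                  tss_window = 50) {
  tir <- data.table::as.data.table(tirs)
  tx <- data.table::copy(txs$transcripts)
  ex <- data.table::copy(txs$exons)
  no_links <- data.table::data.table(tir_id = character(),
                                     transcript_id = character())
  if (nrow(tir) == 0L || nrow(tx) == 0L) {
    return(list(links = no_links,
                transcripts = transcript_set(ex[0L]),
                dropped = data.table::data.table(
                  transcript_id = tx$transcript_id,
                  reason = rep("no_tir", nrow(tx)))))
  }

  # candidate (tir, transcript) pairs via exon overlap, strand-blind
  qg <- GenomicRanges::GRanges(tir$chrom,
                               IRanges::IRanges(tir$start + 1L, tir$end))
  eg <- GenomicRanges::GRanges(ex$chrom,
                               IRanges::IRanges(ex$start + 1L, ex$end))
  ov <- GenomicRanges::findOverlaps(qg, eg, minoverlap = min_overlap,
                                    ignore.strand = TRUE)
  cand <- data.table::data.table(
    tir_id = tir$id[S4Vectors::queryHits(ov)],
    tir_strand = tir$strand[S4Vectors::queryHits(ov)],
    tir_start = tir$start[S4Vectors::queryHits(ov)],
    tir_end = tir$end[S4Vectors::queryHits(ov)],
    transcript_id = ex$transcript_id[S4Vectors::subjectHits(ov)])
  cand <- unique(cand)
  cand <- merge(cand,
                tx[, list(transcript_id, tx_start = start, tx_end = end,
                          tx_strand = strand)],
                by = "transcript_id")

  hits_window <- function(tir_start, tir_end, tss) {
    tir_start <= tss + tss_window & tir_end >= tss - tss_window + 1
  }

  # stranded transcripts: strand match + 5'-window intersection
  st <- cand[tx_strand != "."]
  st <- st[tir_strand == tx_strand]
  st <- st[hits_window(tir_start, tir_end,
                       tss_position(tx_start, tx_end, tx_strand))]
  links <- st[, list(tir_id, transcript_id)]

  # unstranded mono-exonic transcripts: test both 5'-end interpretations
  un <- cand[tx_strand == "."]
  imputed <- data.table::data.table(transcript_id = character(),
                                    strand = character())
  ambiguous <- character()
  if (nrow(un)) {
    un[, plus_ok := tir_strand == "+" & hits_window(tir_start, tir_end,
                                                    tx_start)]
    un[, minus_ok := tir_strand == "-" & hits_window(tir_start, tir_end,
                                                     tx_end - 1)]
    res <- un[, list(has_plus = any(plus_ok), has_minus = any(minus_ok)),
              by = "transcript_id"]
    ambiguous <- res$transcript_id[res$has_plus & res$has_minus]
    plus_ids <- res$transcript_id[res$has_plus & !res$has_minus]
    minus_ids <- res$transcript_id[res$has_minus & !res$has_plus]
    imputed <- data.table::data.table(
      transcript_id = c(plus_ids, minus_ids),
      strand = c(rep("+", length(plus_ids)), rep("-", length(minus_ids))))
    links <- rbind(links,
                   un[plus_ok & transcript_id %in% plus_ids,
                      list(tir_id, transcript_id)],
                   un[minus_ok & transcript_id %in% minus_ids,
                      list(tir_id, transcript_id)])
  }
  links <- unique(links)
  data.table::setorder(links, tir_id, transcript_id)

  kept_ids <- unique(links$transcript_id)
  dropped <- data.table::data.table(
    transcript_id = setdiff(tx$transcript_id, kept_ids),
    reason = "no_tir")
  if (length(ambiguous))
    dropped[dropped$transcript_id %in% ambiguous,
            reason := "ambiguous_bidirectional_tir"]

  ex_kept <- ex[ex$transcript_id %in% kept_ids, ]
  if (nrow(imputed)) {
    ex_kept <- merge(ex_kept, imputed, by = "transcript_id",
                     all.x = TRUE, suffixes = c("", ".imp"))
    ex_kept[!is.na(strand.imp), strand := strand.imp]
    ex_kept[, strand.imp := NULL]
  }
  list(links = links,
       transcripts = transcript_set(ex_kept[, list(transcript_id, gene_id,
                                                   chrom, start, end,
                                                   strand)]),
       dropped = dropped)
}

#' Correlation between TIR read support and transcript expression
#'
#' Pearson correlation of log10 read support against log10(FPKM +
#' pseudocount) over linked TIR/transcript pairs.
#'
#' @param tirs TIR table with `id` and `n_reads`.
#' @param links linkage table (tir_id, transcript_id) from
#'   [associate_transcripts()].
#' @param fpkm named numeric vector of per-transcript FPKM.
#' @param pseudocount added to FPKM before log transform.
#' @return Pearson r in \[-1, 1\].
#' @export
tir_support_expression_correlation <- function(tirs, links, fpkm,
                                               pseudocount = 0.01) {
  dt <- merge(data.table::as.data.table(links),
              data.table::as.data.table(tirs)[, list(tir_id = id, n_reads)],
              by = "tir_id")
  dt <- dt[dt$transcript_id %in% names(fpkm), ]
  if (nrow(dt) < 3L) stop("need at least 3 linked TIR/transcript pairs")
  x <- log10(dt$n_reads)
  y <- log10(fpkm[dt$transcript_id] + pseudocount)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in support or expression")
  stats::cor(x, y)
}

#' Export TIRs as BED6 (score = read support)
#' @param tirs TIR table.
#' @param path output BED file.
#' @export
write_tir_bed <- function(tirs, path) {
  write_bed(gintervals(tirs$chrom, tirs$start, tirs$end, name = tirs$id,
                       score = tirs$n_reads, strand = tirs$strand), path)
}
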