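#' Locate transcripts relative to protein-coding annotation
#'
#' Decision order per transcript: *intragenic* when its span overlaps a
#' coding gene body by at least 1 bp on either strand; otherwise
#' *bidirectional* when its TIR lies on the opposite strand within
#' `bidirectional_window` bp (edge-to-edge) of a coding-gene-linked TIR, or
#' overlaps one; otherwise *intergenic*.
#'
#' @param tx_spans interval table of transcript spans (chrom/start/end).
#' @param tx_tirs matching interval table of each transcript's TIR
#'   (chrom/start/end/strand; one row per transcript).
#' @param coding_genes coding gene body intervals.
#' @param coding_tirs intervals of TIRs linked to coding genes (stranded).
#' @param bidirectional_window bp window for the bidirectional call.
#' @return character vector in {intragenic, bidirectional, intergenic}.
#' @export
locate_transcript <- function(tx_spans, tx_tirs, coding_genes, coding_tirs,
                              bidirectional_window = 1000) {
  n <- nrow(tx_spans)
  out <- rep("intergenic", n)
  if (n == 0L) return(character())
  if (!is.null(coding_genes) && nrow(coding_genes)) {
    sp <- GenomicRanges::GRanges(tx_spans$chrom,
                                 IRanges::IRanges(tx_spans$start + 1,
                                                  tx_spans$end))
    cg <- GenomicRanges::GRanges(coding_genes$chrom,
                                 IRanges::IRanges(coding_genes$start + 1,
                                                  coding_genes$end))
    intra <- GenomicRanges::countOverlaps(sp, cg, ignore.strand = TRUE) > 0L
    out[intra] <- "intragenic"
  }
  if (!is.null(coding_tirs) && nrow(coding_tirs)) {
    tg <- GenomicRanges::GRanges(tx_tirs$chrom,
                                 IRanges::IRanges(tx_tirs$start + 1,
                                                  tx_tirs$end))
    ct <- GenomicRanges::GRanges(coding_tirs$chrom,
                                 IRanges::IRanges(coding_tirs$start + 1,
                                                  coding_tirs$end))
    ov <- GenomicRanges::findOverlaps(tg, ct, maxgap = bidirectional_window,
                                      ignore.strand = TRUE)
    opp <- tx_tirs$strand[S4Vectors::queryHits(ov)] !=
      coding_tirs$strand[S4Vectors::subjectHits(ov)]
    bidi <- unique(S4Vectors::queryHits(ov)[opp])
    out[bidi[out[bidi] != "intragenic"]] <- "bidirectional"
  }
  out
}

#' lncRNA inclusion filter
#'
#' True for transcripts whose mature (spliced) length strictly exceeds
#' `min_len`, flagged noncoding, and free of pseudogene overlap.
#' Transcripts with unknown coding potential are excluded with a warning.
#'
#' @param mature_length summed exon length per transcript (nt).
#' @param coding_potential character in {coding, noncoding, unknown}.
#' @param pseudogene_overlap logical vector.
#' @param min_len minimum mature length, exclusive (nt).
#' @return logical vector.
#' @export
lncrna_filter <- function(mature_length, coding_potential,
                          pseudogene_overlap, min_len = 200) {
  if (any(coding_potential == "unknown"))
    warning(sum(coding_potential == "unknown"),
            " transcript(s) with unknown coding potential excluded")
  mature_length > min_len & coding_potential == "noncoding" &
    !pseudogene_overlap
}

#' Map TIR chromatin label to lncRNA class
#'
#' @param category transcript category from [locate_transcript()].
#' @param tir_label TIR label from [classify_regions()]; `NA` not allowed
#'   for intergenic records.
#' @return character in {elncRNA, plncRNA, none}.
#' @export
assign_class <- function(category, tir_label) {
  if (any(category == "intergenic" & is.na(tir_label)))
    stop("intergenic transcript without TIR classification")
  out <- rep("none", length(category))
  inter <- category == "intergenic"
  out[inter & tir_label == "enhancer_like"] <- "elncRNA"
  out[inter & tir_label == "promoter_like"] <- "plncRNA"
  out
}

#' Relative orientation of a lncRNA and a non-overlapping gene
#'
#' With "head" the 5' terminus: facing 5' ends give head_to_head
#' (divergent), facing 3' ends tail_to_tail (convergent), lncRNA 3' facing
#' gene 5' tail_to_head, lncRNA 5' facing gene 3' head_to_tail.
#'
#' @param lnc,gene stranded interval tables (vectorised, recycled pairwise).
#' @return character vector of orientation classes.
#' @export
orientation <- function(lnc, gene) {
  if (any(lnc$chrom == gene$chrom &
          pmin(lnc$end, gene$end) > pmax(lnc$start, gene$start)))
    stop("orientation undefined for overlapping pairs")
  gene_right <- gene$start >= lnc$end
  # end of each element facing the other: head (5') or tail (3')
  lnc_head <- ifelse(gene_right, lnc$strand == "-", lnc$strand == "+")
  gene_head <- ifelse(gene_right, gene$strand == "+", gene$strand == "-")
  ifelse(lnc_head & gene_head, "head_to_head",
         ifelse(!lnc_head & !gene_head, "tail_to_tail",
                ifelse(!lnc_head & gene_head, "tail_to_head",
                       "head_to_tail")))
}

#' Fraction of interval bases covered by transposable elements
#'
#' Overlapping TE annotations are collapsed to their union first.
#'
#' @param intervals interval table.
#' @param te_annotation TE interval table (strandless).
#' @return numeric vector of covered fractions in \[0, 1\].
#' @export
te_density <- function(intervals, te_annotation) {
  n <- nrow(intervals)
  if (n == 0L) return(numeric())
  if (is.null(te_annotation) || nrow(te_annotation) == 0L) return(numeric(n))
  q <- GenomicRanges::GRanges(intervals$chrom,
                              IRanges::IRanges(intervals$start + 1,
                                               intervals$end))
  te <- GenomicRanges::reduce(GenomicRanges::GRanges(
    te_annotation$chrom,
    IRanges::IRanges(te_annotation$start + 1, te_annotation$end)))
  ov <- GenomicRanges::findOverlaps(q, te, ignore.strand = TRUE)
  covered <- numeric(n)
  if (length(ov)) {
    qi <- S4Vectors::queryHits(ov); si <- S4Vectors::subjectHits(ov)
    isect <- pmin(intervals$end[qi], GenomicRanges::end(te)[si]) -
      pmax(intervals$start[qi], GenomicRanges::start(te)[si] - 1)
    s <- tapply(isect, qi, sum)
    covered[as.integer(names(s))] <- as.numeric(s)
  }
  covered / (intervals$end - intervals$start)
}

#' CpG-island overlap flag
#'
#' @param tir interval table.
#' @param cpg_islands CpG-island intervals.
#' @param min_overlap minimum overlap in bp (default 2, i.e. strictly more
#'   than one nucleotide).
#' @return logical vector.
#' @export
cpg_overlap <- function(tir, cpg_islands, min_overlap = 2) {
  n <- nrow(tir)
  if (n == 0L) return(logical())
  if (is.null(cpg_islands) || nrow(cpg_islands) == 0L) return(logical(n))
  q <- GenomicRanges::GRanges(tir$chrom,
                              IRanges::IRanges(tir$start + 1, tir$end))
  s <- GenomicRanges::GRanges(cpg_islands$chrom,
                              IRanges::IRanges(cpg_islands$start + 1,
                                               cpg_islands$end))
  GenomicRanges::countOverlaps(q, s, minoverlap = min_overlap,
                               ignore.strand = TRUE) > 0L
}

#' Per-class catalogue summary
#'
#' @param records lncRNA record table with columns lnc_class, mature_length,
#'   n_exons, tss_distance.
#' @return `data.table`: one row per class with n, fraction, monoexonic
#'   fraction, median mature length and median TSS distance (`NA` where a
#'   class is empty).
#' @export
catalog_summary <- function(records) {
  dt <- data.table::as.data.table(records)
  if (nrow(dt) == 0L)
    return(data.table::data.table(lnc_class = character(), n = integer(),
                                  fraction = numeric(),
                                  monoexonic_fraction = numeric(),
                                  median_length = numeric(),
                                  median_tss_distance = numeric()))
  out <- dt[, list(n = .N,
                   monoexonic_fraction = mean(n_exons == 1L),
                   median_length = stats::median(mature_length),
                   median_tss_distance = stats::median(tss_distance,
                                                       na.rm = TRUE)),
            by = "lnc_class"]
  out[, fraction := n / sum(n)]
  data.table::setcolorder(out, c("lnc_class", "n", "fraction"))
  out[]
}

#' Build the full lncRNA catalogue
#'
#' Applies the classification decision tree to TIR-linked transcripts:
#' category (intragenic / bidirectional / intergenic), the lncRNA filter,
#' elncRNA/plncRNA assignment from TIR chromatin, orientation and TSS
#' distance to the nearest coding gene, TE density and CpG overlap.
#' When a transcript has several linked TIRs the best-supported one
#' (highest `n_reads`, ties by id) is used.
#'
#' @param txs `transcript_set` of candidate (non-coding-annotation)
#'   transcripts, TIR-linked.
#' @param links tir_id/transcript_id table from [associate_transcripts()].
#' @param tirs filtered TIR table.
#' @param classifications output of [classify_regions()] keyed by TIR id.
#' @param coding_genes coding gene body intervals (with `name`, `strand`).
#' @param coding_tirs stranded intervals of coding-gene TIRs.
#' @param coding_potential named character vector per transcript
#'   ({coding, noncoding, unknown}).
#' @param pseudogenes,te_annotation,cpg_islands annotation interval tables
#'   (may be empty).
#' @param bidirectional_window bp (see [locate_transcript()]).
#' @param min_len lncRNA length filter (nt, exclusive).
#' @return `data.table` of lncRNA records (one row per transcript that
#'   passes the category and lncRNA filters, category != intragenic), with
#'   attribute `category_counts` giving the full category partition.
#' @export
build_lncrna_catalog <- function(txs, links, tirs, classifications,
                                 coding_genes, coding_tirs,
                                 coding_potential, pseudogenes = NULL,
                                 te_annotation = NULL, cpg_islands = NULL,
                                 bidirectional_window = 1000,
                                 min_len = 200) {
  tx <- data.table::copy(txs$transcripts)
  if (nrow(tx) == 0L) return(data.table::data.table())
  tirdt <- data.table::as.data.table(tirs)

  # one TIR per transcript: best-supported, ties by id
  lk <- merge(data.table::as.data.table(links),
              tirdt[, list(tir_id = id, tir_chrom = chrom, tir_start = start,
                           tir_end = end, tir_strand = strand, n_reads)],
              by = "tir_id")
  data.table::setorder(lk, transcript_id, -n_reads, tir_id)
  lk <- lk[!duplicated(transcript_id)]
  tx <- merge(tx, lk, by = "transcript_id")
  data.table::setorder(tx, chrom, start, strand)

  tx[, category := locate_transcript(
    tx[, list(chrom, start, end)],
    tx[, list(chrom = tir_chrom, start = tir_start, end = tir_end,
              strand = tir_strand)],
    coding_genes, coding_tirs, bidirectional_window)]

  pg <- if (is.null(pseudogenes) || nrow(pseudogenes) == 0L)
    rep(FALSE, nrow(tx))
  else {
    q <- GenomicRanges::GRanges(tx$chrom,
                                IRanges::IRanges(tx$start + 1, tx$end))
    s <- GenomicRanges::GRanges(pseudogenes$chrom,
                                IRanges::IRanges(pseudogenes$start + 1,
                                                 pseudogenes$end))
    GenomicRanges::countOverlaps(q, s, ignore.strand = TRUE) > 0L
  }
  pot <- coding_potential[tx$transcript_id]
  pot[is.na(pot)] <- "unknown"
  tx[, is_lnc := lncrna_filter(mature_length, pot, pg, min_len)]

  cat_counts <- table(factor(tx$category, levels = c("intragenic",
                                                     "bidirectional",
                                                     "intergenic")))
  rec <- tx[category != "intragenic" & is_lnc]
  if (nrow(rec) == 0L) {
    out <- data.table::data.table()
    data.table::setattr(out, "category_counts", cat_counts)
    return(out)
  }

  cls <- data.table::as.data.table(classifications)[, list(tir_id = id,
                                                           tir_label = label)]
  rec <- merge(rec, cls, by = "tir_id", all.x = TRUE)
  rec[, lnc_class := assign_class(category, tir_label)]

  # nearest coding gene, orientation, TSS-to-TSS distance
  rec[, c("nearest_gene", "gene_distance", "orient", "tss_distance") := {
    ng <- character(.N); gd <- rep(NA_real_, .N)
    ori <- rep(NA_character_, .N); td <- rep(NA_real_, .N)
    for (i in seq_len(.N)) {
      nf <- nearest_feature(list(chrom = chrom[i], start = start[i],
                                 end = end[i]), coding_genes)
      if (is.null(nf$feature)) { ng[i] <- NA_character_; next }
      ng[i] <- nf$feature$name; gd[i] <- nf$distance
      if (nf$distance > 0)
        ori[i] <- orientation(
          data.table::data.table(chrom = chrom[i], start = start[i],
                                 end = end[i], strand = strand[i]),
          nf$feature)
      td[i] <- abs(tss_position(start[i], end[i], strand[i]) -
                     tss_position(nf$feature$start, nf$feature$end,
                                  nf$feature$strand))
    }
    list(ng, gd, ori, td)
  }]

  rec[, te_density_tir := te_density(
    rec[, list(chrom = tir_chrom, start = tir_start, end = tir_end)],
    te_annotation)]
  rec[, te_density_exons := {
    ex <- txs$exons[txs$exons$transcript_id %in% rec$transcript_id, ]
    perbp <- te_density(ex, te_annotation) * (ex$end - ex$start)
    s <- tapply(perbp, ex$transcript_id, sum)
    len <- tapply(ex$end - ex$start, ex$transcript_id, sum)
    as.numeric(s[transcript_id] / len[transcript_id])
  }]
  rec[, cpg := cpg_overlap(
    rec[, list(chrom = tir_chrom, start = tir_start, end = tir_end)],
    cpg_islands)]

  out <- rec[, list(transcript_id, chrom, start, end, strand, mature_length,
                    n_exons, tir_id, category, lnc_class, nearest_gene,
                    gene_distance, orientation = orient, tss_distance,
                    te_density_tir, te_density_exons, cpg_overlap = cpg)]
  data.table::setorder(out, chrom, start, strand)
  data.table::setattr(out, "category_counts", cat_counts)
  out[]
}
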