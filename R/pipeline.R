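#' Pipeline parameters
#'
#' All thresholds of the analysis as named constants with their standard
#' defaults: 20 bp tag clustering, 400 bp cluster merging, >= 5 supporting
#' reads, any-overlap (1 bp) DHS gating, a 50 bp 5'-end association
#' window, +-1 kb mark quantification, a 1 kb bidirectional window, the
#' > 200 nt lncRNA length filter, and < 500 kb ancestral-repeat matching.
#'
#' @param max_gap tag clustering linkage distance (bp).
#' @param merge_dist cluster-to-TIR merge distance (bp, edge-to-edge).
#' @param min_reads minimum TIR read support.
#' @param min_overlap minimum DHS / exon overlap (bp).
#' @param tss_window half-width of the TIR-TSS association window (bp).
#' @param quant_window mark quantification window (bp, full width).
#' @param pseudocount pseudocount for the me1/me3 log2 ratio.
#' @param bidirectional_window opposite-strand TIR window (bp).
#' @param min_len lncRNA mature length filter (nt, exclusive).
#' @param detect_threshold expression detection threshold.
#' @param epsilon denominator floor of the delta statistic.
#' @param expr_fold fold-over-median cutoff selecting highly expressed
#'   genes for territory enrichment.
#' @param n_perm permutations for enrichment tests.
#' @param model substitution model for the constraint test.
#' @param max_dist_ar,gc_tol ancestral-repeat matching parameters.
#' @param seed seed for the permutation tests.
#' @return a list of class `pipeline_params`.
#' @export
pipeline_params <- function(max_gap = 20, merge_dist = 400, min_reads = 5,
                            min_overlap = 1, tss_window = 50,
                            quant_window = 2000, pseudocount = 1,
                            bidirectional_window = 1000, min_len = 200,
                            detect_threshold = 0, epsilon = 0.01,
                            expr_fold = 2, n_perm = 200, model = "GTR",
                            max_dist_ar = 500000, gc_tol = 0.05,
                            seed = 1) {
  structure(as.list(environment()), class = "pipeline_params")
}

# Complement of gene bodies within the genome: the intergenic workspace.
intergenic_space <- function(coding_genes, genome) {
  gg <- GenomicRanges::GRanges(
    coding_genes$chrom,
    IRanges::IRanges(coding_genes$start + 1, coding_genes$end),
    seqlengths = genome$chrom_lengths)
  gaps <- GenomicRanges::gaps(GenomicRanges::reduce(gg,
                                                    ignore.strand = TRUE))
  gaps <- gaps[GenomicRanges::strand(gaps) == "*"]
  data.table::data.table(
    chrom = as.character(GenomicRanges::seqnames(gaps)),
    start = GenomicRanges::start(gaps) - 1,
    end = as.numeric(GenomicRanges::end(gaps)))
}

#' Run the full analysis pipeline on an input bundle
#'
#' Stage order: tag clustering -> TIR merging -> support/DHS filtering ->
#' transcript association -> chromatin classification -> lncRNA catalogue
#' -> expression statistics -> neighbour association -> constraint test.
#' Deterministic given `params$seed` (the only stage using randomness is
#' permutation enrichment).
#'
#' @param bundle a `sim_bundle` from [simulate_bundle()] / [read_bundle()],
#'   or any list with the same elements.
#' @param params a [pipeline_params()].
#' @return a `pipeline_report`: nested list of per-stage counts, class
#'   summaries, statistics and the parameter echo.
#' @export
run_pipeline <- function(bundle, params = pipeline_params()) {
  clusters <- cluster_tags(bundle$tags, params$max_gap)
  tirs_all <- merge_clusters(clusters, params$merge_dist)
  tirs <- filter_tirs(tirs_all, params$min_reads, bundle$dhs,
                      params$min_overlap)
  assoc <- associate_transcripts(tirs, bundle$transcripts,
                                 params$min_overlap, params$tss_window)

  me1 <- quantify_mark(bundle$tracks$me1, tirs, params$quant_window,
                       bundle$genome)
  me3 <- quantify_mark(bundle$tracks$me3, tirs, params$quant_window,
                       bundle$genome)
  cls <- classify_regions(me1, me3, params$pseudocount, ids = tirs$id)

  # TIRs linked to transcripts lying in coding annotation
  tx <- assoc$transcripts$transcripts
  if (nrow(tx)) {
    txg <- GenomicRanges::GRanges(tx$chrom,
                                  IRanges::IRanges(tx$start + 1, tx$end))
    cgg <- GenomicRanges::GRanges(
      bundle$coding_genes$chrom,
      IRanges::IRanges(bundle$coding_genes$start + 1,
                       bundle$coding_genes$end))
    is_coding_tx <- GenomicRanges::countOverlaps(txg, cgg,
                                                 ignore.strand = TRUE) > 0L
    coding_tir_ids <- unique(
      assoc$links$tir_id[assoc$links$transcript_id %in%
                           tx$transcript_id[is_coding_tx]])
  } else coding_tir_ids <- character()
  coding_tirs <- tirs[tirs$id %in% coding_tir_ids, ]

  catalog <- build_lncrna_catalog(
    assoc$transcripts, assoc$links, tirs, cls, bundle$coding_genes,
    coding_tirs, bundle$coding_potential, bundle$pseudogenes, bundle$te,
    bundle$cpg, params$bidirectional_window, params$min_len)
  cat_counts <- attr(catalog, "category_counts")

  # expression statistics per class
  has_cat <- nrow(catalog) > 0L
  ts_by_class <- stage_by_class <- NULL
  if (has_cat && !is.null(bundle$expression)) {
    cdt <- data.table::as.data.table(catalog)
    cdt[, gene_locus := sub("\\.t[0-9]+$", "", transcript_id)]
    tsm <- tissue_specificity_matrix(bundle$expression$tissue)
    cdt <- merge(cdt, tsm, by.x = "gene_locus", by.y = "locus",
                 all.x = TRUE)
    ts_by_class <- cdt[lnc_class != "none",
                       list(n = .N,
                            median_max_ts = stats::median(max_ts,
                                                          na.rm = TRUE)),
                       by = "lnc_class"]
    st <- bundle$expression$stage
    det <- stage_detection(st[intersect(cdt$gene_locus, rownames(st)), ,
                              drop = FALSE],
                           params$detect_threshold)
    stage_by_class <- cdt[gene_locus %in% names(det) & lnc_class != "none",
                          list(n_stages = det[gene_locus]),
                          by = c("lnc_class", "gene_locus")][
      , list(n = .N), by = c("lnc_class", "n_stages")]
  }

  # neighbour association
  territories <- gene_territories(bundle$coding_genes, bundle$genome)
  workspace <- intergenic_space(bundle$coding_genes, bundle$genome)
  enrichment <- delta_cmp <- deltas <- NULL
  if (has_cat && !is.null(bundle$expression)) {
    st <- bundle$expression$stage
    gmean <- rowMeans(st[rownames(st) %in% bundle$coding_genes$name, ,
                         drop = FALSE])
    high <- names(gmean)[gmean > params$expr_fold * stats::median(gmean)]
    sel <- territories[vapply(strsplit(territories$gene, ","),
                              function(g) any(g %in% high), logical(1)), ]
    lnc_loci <- catalog[catalog$lnc_class != "none", ]
    if (nrow(lnc_loci) && nrow(sel)) {
      enrichment <- territory_enrichment(lnc_loci, sel, workspace,
                                         params$n_perm, params$seed)
    }
    # delta per class against the nearest gene
    dl <- lapply(seq_len(nrow(lnc_loci)), function(i) {
      g <- lnc_loci$nearest_gene[i]
      l <- sub("\\.t[0-9]+$", "", lnc_loci$transcript_id[i])
      if (is.na(g) || !g %in% rownames(st) || !l %in% rownames(st))
        return(NULL)
      if (stage_detection(st[l, ], params$detect_threshold) == 0L ||
          stage_detection(st[g, ], params$detect_threshold) == 0L)
        return(NULL)
      d <- suppressWarnings(delta_statistic(st[l, ], st[g, ],
                                            params$epsilon))
      data.table::data.table(lnc_class = lnc_loci$lnc_class[i],
                             locus = l, neighbor = g, delta = d$delta)
    })
    deltas <- data.table::rbindlist(dl)
    if (nrow(deltas)) {
      de <- deltas$delta[deltas$lnc_class == "elncRNA"]
      dp <- deltas$delta[deltas$lnc_class == "plncRNA"]
      if (sum(!is.na(de)) >= 3L && sum(!is.na(dp)) >= 3L)
        delta_cmp <- compare_delta_distributions(de, dp)
    }
  }

  # selective constraint per class
  constraint <- NULL
  if (has_cat && length(bundle$alignments$elements)) {
    el_class <- stats::setNames(catalog$lnc_class,
                                sub("\\.t[0-9]+$", "",
                                    catalog$transcript_id))
    constraint <- list()
    for (cl in c("elncRNA", "plncRNA")) {
      ids <- names(el_class)[el_class == cl]
      els <- Filter(function(e) sub("_tir$", "", e$id) %in% ids,
                    bundle$alignments$elements)
      constraint[[cl]] <- tryCatch(
        suppressWarnings(constraint_test(els, bundle$alignments$ars,
                                         params$model, params$max_dist_ar,
                                         params$gc_tol)),
        error = function(e) NULL)
    }
  }

  n_inter <- if (has_cat) sum(catalog$category == "intergenic") else 0L
  report <- list(
    counts = list(
      tags = sum(bundle$tags$count),
      clusters = nrow(clusters),
      tirs_premerge = nrow(clusters),
      tirs = nrow(tirs_all),
      tirs_filtered = nrow(tirs),
      linked_transcripts = length(unique(assoc$links$transcript_id)),
      dropped_transcripts = nrow(assoc$dropped),
      categories = as.list(cat_counts),
      lncRNA_records = if (has_cat) nrow(catalog) else 0L,
      intergenic_lncRNA = n_inter,
      elncRNA = if (has_cat) sum(catalog$lnc_class == "elncRNA") else 0L,
      plncRNA = if (has_cat) sum(catalog$lnc_class == "plncRNA") else 0L,
      ambiguous = if (has_cat)
        sum(catalog$category == "intergenic" &
              catalog$lnc_class == "none") else 0L),
    catalog_summary = if (has_cat)
      catalog_summary(catalog[catalog$lnc_class != "none", ]) else NULL,
    tissue_specificity = ts_by_class,
    stage_detection = stage_by_class,
    enrichment = if (!is.null(enrichment)) unclass(enrichment) else NULL,
    delta = delta_cmp,
    constraint = if (!is.null(constraint)) lapply(constraint, function(x)
      if (is.null(x)) NULL else x[c("median_d_element", "median_d_ar",
                                    "median_relative_rate", "p")]) else NULL,
    params = unclass(params),
    version = as.character(utils::packageVersion("tircat")))
  structure(list(report = report, tirs = tirs, clusters = clusters,
                 links = assoc$links, classifications = cls,
                 catalog = catalog, deltas = deltas,
                 territories = territories),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cnt <- x$report$counts
  cat("tircat pipeline:", cnt$tags, "tags ->", cnt$tirs, "TIRs ->",
      cnt$tirs_filtered, "filtered ->", cnt$linked_transcripts,
      "linked transcripts ->", cnt$intergenic_lncRNA,
      "intergenic lncRNAs (", cnt$elncRNA, "elncRNA /", cnt$plncRNA,
      "plncRNA )\n")
  invisible(x)
}

#' Write a pipeline report as JSON
#'
#' The report contains no timestamps, so identical runs serialize to
#' byte-identical files.
#'
#' @param result a `pipeline_result` (or its `$report`).
#' @param path output JSON path.
#' @export
write_report <- function(result, path) {
  rep <- if (inherits(result, "pipeline_result")) result$report else result
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                       na = "null", null = "null")
  invisible(path)
}

#' Read a synthetic bundle back from a directory
#'
#' Counterpart of [write_bundle()]; reconstructs the in-memory bundle from
#' the plain-text files (library sizes and the truth table come from
#' truth.json).
#'
#' @param dir directory written by [write_bundle()].
#' @return a `sim_bundle`-shaped list.
#' @export
read_bundle <- function(dir) {
  p <- function(...) file.path(dir, ...)
  genome <- read_chrom_sizes(p("chrom.sizes"))
  truth <- jsonlite::read_json(p("truth.json"), simplifyVector = TRUE)
  cg_bed <- read_bed(p("coding_genes.bed"), genome)
  pot <- data.table::fread(p("coding_potential.tsv"))
  man <- data.table::fread(p("alignments.tsv"))
  pairs <- lapply(seq_len(nrow(man)), function(i)
    read_aligned_pair(p(man$file[i]), id = man$id[i], kind = man$kind[i],
                      chrom = man$chrom[i], start = man$start[i],
                      end = man$end[i]))
  structure(list(
    genome = genome,
    tags = read_tags_bed(p("tags.bed"), genome),
    dhs = read_bed(p("dhs.bed"), genome),
    tracks = list(
      me1 = chromatin_track(read_bedgraph(p("me1.bedgraph")), "H3K4me1",
                            truth$library_sizes$me1),
      me3 = chromatin_track(read_bedgraph(p("me3.bedgraph")), "H3K4me3",
                            truth$library_sizes$me3)),
    transcripts = read_gtf(p("transcripts.gtf")),
    coding_genes = data.table::data.table(
      chrom = cg_bed$chrom, start = cg_bed$start, end = cg_bed$end,
      name = cg_bed$name, score = cg_bed$score, strand = cg_bed$strand),
    te = read_bed(p("te.bed"), genome),
    cpg = read_bed(p("cpg.bed"), genome),
    pseudogenes = read_bed(p("pseudogenes.bed"), genome),
    coding_potential = stats::setNames(pot$potential, pot$transcript_id),
    expression = list(tissue = read_matrix_tsv(p("tissue_expression.tsv")),
                      stage = read_matrix_tsv(p("stage_expression.tsv"))),
    alignments = list(elements = Filter(function(x) x$kind != "AR", pairs),
                      ars = Filter(function(x) x$kind == "AR", pairs)),
    truth = list(loci = data.table::as.data.table(truth$loci),
                 config = truth$config)),
    class = "sim_bundle")
}
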