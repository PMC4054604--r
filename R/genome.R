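#' Genome model
#'
#' A minimal genome description: chromosome names and lengths. All interval
#' containers in the package are validated against one of these when supplied.
#'
#' @param chrom_names character vector of unique chromosome identifiers.
#' @param chrom_lengths integer vector of chromosome lengths in bp (> 0).
#' @return An object of class `genome_model` with fields `chrom_names` and
#'   `chrom_lengths` (named integer vector).
#' @export
genome_model <- function(chrom_names, chrom_lengths) {
  chrom_names <- as.character(chrom_names)
  chrom_lengths <- as.numeric(chrom_lengths)
  if (anyDuplicated(chrom_names)) stop("chromosome names must be unique")
  if (length(chrom_names) != length(chrom_lengths))
    stop("names and lengths differ in length")
  if (any(!is.finite(chrom_lengths)) || any(chrom_lengths <= 0))
    stop("chromosome lengths must be positive")
  names(chrom_lengths) <- chrom_names
  structure(list(chrom_names = chrom_names, chrom_lengths = chrom_lengths),
            class = "genome_model")
}

#' @export
print.genome_model <- function(x, ...) {
  cat("genome_model:", length(x$chrom_names), "chromosomes,",
      format(sum(x$chrom_lengths), big.mark = ","), "bp total\n")
  invisible(x)
}

#' Read a two-column chrom.sizes file as a genome model
#' @param path file with lines `<chrom>\t<length>`.
#' @return a [genome_model()].
#' @export
read_chrom_sizes <- function(path) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          col.names = c("chrom", "length"))
  genome_model(dt$chrom, dt$length)
}

#' @rdname read_chrom_sizes
#' @param genome a `genome_model`.
#' @export
write_chrom_sizes <- function(genome, path) {
  data.table::fwrite(
    data.table::data.table(chrom = genome$chrom_names,
                           length = as.integer(genome$chrom_lengths)),
    path, sep = "\t", col.names = FALSE)
  invisible(path)
}

STRANDS <- c("+", "-", ".")

#' Genomic interval table
#'
#' The package-wide interval container: a `data.table` with columns
#' `chrom`, `start`, `end` (0-based half-open), `name`, `score`, `strand`.
#' This is BED's native coordinate convention; GTF input is shifted on read.
#'
#' @param chrom,start,end,name,score,strand vectors, recycled to a common
#'   length. `strand` must be one of `+`, `-`, `.`.
#' @param genome optional [genome_model()]; when given, intervals must lie
#'   within chromosome bounds.
#' @return a `data.table` of class `gintervals`.
#' @export
gintervals <- function(chrom, start, end, name = ".", score = 0L,
                       strand = ".", genome = NULL) {
  dt <- data.table::data.table(chrom = as.character(chrom),
                               start = as.numeric(start),
                               end = as.numeric(end),
                               name = as.character(name),
                               score = as.numeric(score),
                               strand = as.character(strand))
  validate_gintervals(dt, genome)
  data.table::setattr(dt, "class", c("gintervals", class(dt)))
  dt[]
}

validate_gintervals <- function(dt, genome = NULL) {
  if (nrow(dt) == 0L) return(invisible(dt))
  if (any(!dt$strand %in% STRANDS))
    stop("strand must be one of '+', '-', '.'")
  bad <- which(!(dt$start >= 0 & dt$start < dt$end))
  if (length(bad))
    stop(sprintf("invalid interval at row %d: start %s, end %s",
                 bad[1L], dt$start[bad[1L]], dt$end[bad[1L]]))
  if (!is.null(genome)) {
    if (any(!dt$chrom %in% genome$chrom_names))
      stop("interval chromosome not in genome model")
    if (any(dt$end > genome$chrom_lengths[dt$chrom]))
      stop("interval end exceeds chromosome length")
  }
  invisible(dt)
}

#' Read a BED3/BED6 file
#'
#' Comment, `track` and `browser` lines are skipped. Malformed records raise
#' an error naming the offending line number.
#'
#' @param path BED file path.
#' @param genome optional [genome_model()] for bounds checking.
#' @return a [gintervals()] table.
#' @export
read_bed <- function(path, genome = NULL) {
  lines <- readLines(path)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  fields <- strsplit(lines[keep], "[ \t]+")
  nf <- lengths(fields)
  if (length(nf) && any(nf < 3L))
    stop(sprintf("BED parse error at line %d: fewer than 3 fields",
                 lineno[which(nf < 3L)[1L]]))
  get_col <- function(i, default) {
    vapply(fields, function(f) if (length(f) >= i) f[i] else default, "")
  }
  if (length(fields) == 0L) return(gintervals(character(), numeric(), numeric()))
  start <- suppressWarnings(as.numeric(get_col(2L, NA)))
  end <- suppressWarnings(as.numeric(get_col(3L, NA)))
  bad <- which(is.na(start) | is.na(end) | start < 0 | start >= end)
  if (length(bad))
    stop(sprintf("BED parse error at line %d: invalid coordinates '%s'",
                 lineno[bad[1L]], lines[lineno[bad[1L]]]))
  strand <- get_col(6L, ".")
  if (any(!strand %in% STRANDS))
    stop(sprintf("BED parse error at line %d: bad strand",
                 lineno[which(!strand %in% STRANDS)[1L]]))
  score <- suppressWarnings(as.numeric(get_col(5L, "0")))
  score[is.na(score)] <- 0
  gintervals(get_col(1L, NA), start, end, name = get_col(4L, "."),
             score = score, strand = strand, genome = genome)
}

#' Write intervals as BED6
#' @param intervals a [gintervals()] table.
#' @param path output file.
#' @export
write_bed <- function(intervals, path) {
  dt <- data.table::as.data.table(intervals)[
    , list(chrom, start = as.integer(start), end = as.integer(end),
           name, score, strand)]
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read/write a bedGraph file
#' @param path bedGraph path (4 columns: chrom, start, end, value).
#' @return `data.table` with those columns, 0-based half-open.
#' @export
read_bedgraph <- function(path) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          col.names = c("chrom", "start", "end", "value"))
  if (nrow(dt) && any(dt$start >= dt$end))
    stop("bedGraph with start >= end at row ", which(dt$start >= dt$end)[1L])
  dt
}

#' @rdname read_bedgraph
#' @param dt a bedGraph-like `data.table`.
#' @export
write_bedgraph <- function(dt, path) {
  data.table::fwrite(
    dt[, list(chrom, start = as.integer(start), end = as.integer(end), value)],
    path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Pairwise overlap length of two intervals
#'
#' Vectorised over rows; intervals on different chromosomes overlap by 0 bp.
#' Half-open convention: abutting intervals do not overlap.
#'
#' @param a,b interval tables (recycled to common length).
#' @return numeric vector of overlap lengths in bp.
#' @export
overlap_length <- function(a, b) {
  ol <- pmax(0, pmin(a$end, b$end) - pmax(a$start, b$start))
  ol[a$chrom != b$chrom] <- 0
  ol
}

# Edge-to-edge distance between disjoint intervals; 0 if overlapping/abutting.
edge_distance <- function(a_start, a_end, b_start, b_end) {
  pmax(0, pmax(a_start, b_start) - pmin(a_end, b_end))
}

#' Nearest feature to a query interval
#'
#' Minimal edge-to-edge distance (0 when overlapping or abutting). Ties are
#' broken deterministically: leftmost feature start, then lexicographic name.
#'
#' @param query single-row interval table (or list with chrom/start/end).
#' @param features a [gintervals()] table.
#' @param exclude_self drop features whose name equals the query's name.
#' @return list with `feature` (one-row table or `NULL`) and `distance`
#'   (bp, `NA` when no feature exists on the query chromosome).
#' @export
nearest_feature <- function(query, features, exclude_self = FALSE) {
  f <- data.table::as.data.table(features)
  f <- f[f$chrom == query$chrom[1L], ]
  if (exclude_self && "name" %in% names(f)) f <- f[f$name != query$name[1L], ]
  if (nrow(f) == 0L) return(list(feature = NULL, distance = NA_real_))
  d <- edge_distance(query$start[1L], query$end[1L], f$start, f$end)
  cand <- which(d == min(d))
  if (length(cand) > 1L) {
    o <- order(f$start[cand], f$name[cand])
    cand <- cand[o[1L]]
  }
  list(feature = f[cand[1L], ], distance = d[cand[1L]])
}

gi_to_granges <- function(dt) {
  n <- nrow(dt)
  strand <- if ("strand" %in% names(dt)) {
    s <- dt$strand
    s[s == "."] <- "*"
    s
  } else rep("*", n)
  GenomicRanges::GRanges(
    seqnames = dt$chrom,
    ranges = IRanges::IRanges(start = dt$start + 1L, end = dt$end),
    strand = strand)
}

#' Read transcript models from GTF
#'
#' Parses `exon` records; transcript span, strand and exon structure are
#' assembled per `transcript_id`. Coordinates are converted to the internal
#' 0-based half-open convention (GTF is 1-based closed).
#'
#' @param path GTF file.
#' @return a `transcript_set`: list with `transcripts` (one row per
#'   transcript: transcript_id, gene_id, chrom, start, end, strand, n_exons,
#'   mature_length) and `exons` (transcript_id, chrom, start, end, strand,
#'   exon_rank).
#' @export
read_gtf <- function(path) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          col.names = c("chrom", "source", "feature", "start",
                                        "end", "score", "strand", "frame",
                                        "attributes"))
  dt <- dt[dt$feature == "exon", ]
  if (nrow(dt) && any(dt$start > dt$end))
    stop("GTF exon with start > end at row ", which(dt$start > dt$end)[1L])
  ex_att <- function(att, key) {
    m <- regmatches(att, regexpr(paste0(key, ' "[^"]*"'), att))
    out <- rep(NA_character_, length(att))
    hit <- grepl(paste0(key, ' "'), att)
    out[hit] <- sub(paste0(key, ' "([^"]*)"'), "\\1",
                    regmatches(att, regexpr(paste0(key, ' "[^"]*"'), att)))
    out
  }
  exons <- data.table::data.table(
    transcript_id = ex_att(dt$attributes, "transcript_id"),
    gene_id = ex_att(dt$attributes, "gene_id"),
    chrom = dt$chrom, start = dt$start - 1, end = as.numeric(dt$end),
    strand = dt$strand)
  transcript_set(exons)
}

#' Build a transcript set from an exon table
#'
#' @param exons `data.table` with transcript_id, gene_id, chrom, start, end,
#'   strand (0-based half-open).
#' @return a `transcript_set` list (see [read_gtf()]).
#' @export
transcript_set <- function(exons) {
  exons <- data.table::as.data.table(exons)
  if (nrow(exons) == 0L) {
    empty <- data.table::data.table(
      transcript_id = character(), gene_id = character(),
      chrom = character(), start = numeric(), end = numeric(),
      strand = character(), exon_rank = integer())
    return(structure(list(
      transcripts = data.table::data.table(
        transcript_id = character(), gene_id = character(),
        chrom = character(), start = numeric(), end = numeric(),
        strand = character(), n_exons = integer(),
        mature_length = numeric()),
      exons = empty), class = "transcript_set"))
  }
  if (any(!exons$strand %in% STRANDS))
    stop("exon strand must be one of '+', '-', '.'")
  data.table::setorder(exons, transcript_id, start)
  exons[, exon_rank := seq_len(.N), by = "transcript_id"]
  # exons of one transcript must be disjoint and on one chrom/strand
  chk <- exons[, list(ok = all(diff(start) > 0) && all(end[-.N] <= start[-1L]),
                      one = length(unique(chrom)) == 1L &&
                        length(unique(strand)) == 1L),
               by = "transcript_id"]
  if (nrow(chk) && any(!chk$ok | !chk$one))
    stop("overlapping or mixed-chromosome exons in transcript ",
         chk$transcript_id[which(!chk$ok | !chk$one)[1L]])
  tx <- exons[, list(gene_id = gene_id[1L], chrom = chrom[1L],
                     start = min(start), end = max(end),
                     strand = strand[1L], n_exons = .N,
                     mature_length = sum(end - start)),
              by = "transcript_id"]
  data.table::setorder(tx, chrom, start, strand)
  structure(list(transcripts = tx[], exons = exons[]),
            class = "transcript_set")
}

#' @export
print.transcript_set <- function(x, ...) {
  cat("transcript_set:", nrow(x$transcripts), "transcripts,",
      nrow(x$exons), "exons\n")
  invisible(x)
}

#' Write a transcript set as GTF (exon records)
#' @param txs a `transcript_set`.
#' @param path output file.
#' @export
write_gtf <- function(txs, path) {
  e <- txs$exons
  lines <- sprintf(
    '%s\ttircat\texon\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s";',
    e$chrom, as.integer(e$start) + 1L, as.integer(e$end), e$strand,
    e$gene_id, e$transcript_id)
  writeLines(lines, path)
  invisible(path)
}

#' Read/write a loci x conditions abundance matrix (TSV)
#'
#' First column holds locus ids; the header row holds condition names.
#' @param path TSV file.
#' @return numeric matrix with locus rownames and condition colnames.
#' @export
read_matrix_tsv <- function(path) {
  dt <- data.table::fread(path, header = TRUE, sep = "\t")
  m <- as.matrix(dt[, -1, with = FALSE])
  rownames(m) <- as.character(dt[[1L]])
  storage.mode(m) <- "numeric"
  if (any(m < 0, na.rm = TRUE)) stop("negative abundance in matrix")
  m
}

#' @rdname read_matrix_tsv
#' @param m numeric matrix (locus rownames, condition colnames).
#' @export
write_matrix_tsv <- function(m, path) {
  dt <- data.table::data.table(locus = rownames(m))
  for (j in colnames(m)) dt[[j]] <- m[, j]
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}
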