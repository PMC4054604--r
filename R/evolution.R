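DNA_BASES <- c("A", "C", "G", "T")

#' Aligned sequence pair
#'
#' Two gap-aligned sequences (e.g. a mouse element and its rat orthologue)
#' with a genomic anchor and element kind. G+C content is computed on the
#' ungapped first (reference) sequence.
#'
#' @param id element identifier.
#' @param seq1,seq2 aligned sequences, equal length, alphabet `ACGTN-`.
#' @param kind one of TIR, locus, exon, intron, AR.
#' @param chrom,start,end genomic anchor of the reference element.
#' @return object of class `aligned_pair`.
#' @export
aligned_pair <- function(id, seq1, seq2, kind = "locus",
                         chrom = NA_character_, start = NA_real_,
                         end = NA_real_) {
  seq1 <- toupper(seq1); seq2 <- toupper(seq2)
  if (nchar(seq1) != nchar(seq2)) stop("aligned lengths differ")
  if (grepl("[^ACGTN-]", seq1) || grepl("[^ACGTN-]", seq2))
    stop("alphabet must be A/C/G/T/N/-")
  ungapped <- gsub("-", "", seq1)
  structure(list(id = id, seq1 = seq1, seq2 = seq2, kind = kind,
                 chrom = chrom, start = start, end = end,
                 gc = if (nchar(gsub("[^ACGT]", "", ungapped)) > 0)
                   gc_content(ungapped) else NA_real_),
            class = "aligned_pair")
}

#' Read one pairwise alignment from FASTA
#'
#' The file must contain exactly two equal-length records.
#' @param path FASTA file.
#' @inheritParams aligned_pair
#' @return an [aligned_pair()] (id defaults to the first record name).
#' @export
read_aligned_pair <- function(path, id = NULL, kind = "locus",
                              chrom = NA_character_, start = NA_real_,
                              end = NA_real_) {
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) != 2L) stop("expected exactly 2 FASTA records in ", path)
  aligned_pair(if (is.null(id)) names(ss)[1L] else id,
               as.character(ss[[1L]]), as.character(ss[[2L]]),
               kind = kind, chrom = chrom, start = start, end = end)
}

#' @rdname read_aligned_pair
#' @param pair an `aligned_pair`.
#' @export
write_aligned_pair <- function(pair, path) {
  writeLines(c(paste0(">", pair$id, "_ref"), pair$seq1,
               paste0(">", pair$id, "_alt"), pair$seq2), path)
  invisible(path)
}

#' Joint site-pattern counts of an aligned pair
#'
#' Columns containing a gap or N in either sequence are excluded.
#' @param pair an [aligned_pair()].
#' @return 4x4 integer matrix (rows: reference base, cols: other base)
#'   whose sum is the number of usable sites.
#' @export
count_site_patterns <- function(pair) {
  a <- strsplit(pair$seq1, "")[[1L]]
  b <- strsplit(pair$seq2, "")[[1L]]
  use <- a %in% DNA_BASES & b %in% DNA_BASES
  if (!any(use)) stop("no usable (gap/N-free) sites")
  table(factor(a[use], levels = DNA_BASES),
        factor(b[use], levels = DNA_BASES))
}

#' Pairwise substitution distance from site-pattern counts
#'
#' Closed-form estimators: JC69 `d = -(3/4) log(1 - 4p/3)`; K80 from
#' transition/transversion proportions; GTR (REV) as the generalised
#' paralinear distance `d = -trace(Pi %*% logm(Pi^-1 F))` on the symmetrised
#' joint frequency matrix `F` with `Pi = diag(base frequencies)`. On
#' numerical failure the estimator falls back GTR -> K80 -> JC69 and records
#' the model actually used.
#'
#' @param counts 4x4 site-pattern matrix from [count_site_patterns()].
#' @param model requested model.
#' @return list of class `distance_estimate`: `d`, `model` (requested),
#'   `model_used`, `sites`, `p_distance`.
#' @export
estimate_distance <- function(counts, model = c("GTR", "K80", "JC69")) {
  model <- match.arg(model)
  counts <- as.matrix(counts)
  n <- sum(counts)
  if (n < 1) stop("no sites")
  p <- (n - sum(diag(counts))) / n
  chain <- switch(model, GTR = c("GTR", "K80", "JC69"),
                  K80 = c("K80", "JC69"), JC69 = "JC69")
  d <- NA_real_
  used <- NA_character_
  for (m in chain) {
    d <- switch(
      m,
      JC69 = {
        if (p >= 0.75) stop("saturated: p-distance ", signif(p, 4),
                            " at or beyond the JC69 bound 0.75")
        -0.75 * log(1 - 4 * p / 3)
      },
      K80 = {
        P <- (counts["A", "G"] + counts["G", "A"] +
                counts["C", "T"] + counts["T", "C"]) / n
        Q <- p - P
        a1 <- 1 - 2 * P - Q; a2 <- 1 - 2 * Q
        if (a1 <= 0 || a2 <= 0) NA_real_
        else -0.5 * log(a1) - 0.25 * log(a2)
      },
      GTR = {
        FM <- (counts + t(counts)) / (2 * n)
        pi_f <- rowSums(FM)
        if (any(pi_f <= 0)) NA_real_ else {
          s <- 1 / sqrt(pi_f)
          S <- diag(s) %*% FM %*% diag(s)   # symmetric similarity of Pi^-1 F
          eg <- eigen(S, symmetric = TRUE)
          if (any(eg$values <= 0)) NA_real_ else {
            # trace(Pi logm(Pi^-1 F)) via the symmetric form
            L <- eg$vectors %*% diag(log(eg$values)) %*% t(eg$vectors)
            -sum(diag(diag(sqrt(pi_f)) %*% L %*% diag(sqrt(pi_f))))
          }
        }
      })
    if (is.finite(d)) { used <- m; break }
  }
  if (!is.finite(d)) stop("saturated alignment: no estimator defined")
  structure(list(d = d, model = model, model_used = used, sites = n,
                 p_distance = p),
            class = "distance_estimate")
}

#' G+C content of a sequence
#'
#' @param sequence character string; gaps and Ns are excluded.
#' @return fraction (G+C)/(A+C+G+T).
#' @export
gc_content <- function(sequence) {
  chars <- strsplit(toupper(sequence), "")[[1L]]
  acgt <- chars[chars %in% DNA_BASES]
  if (length(acgt) == 0L) stop("no A/C/G/T bases in sequence")
  sum(acgt %in% c("G", "C")) / length(acgt)
}

#' Match neighbouring ancestral repeats by distance and G+C content
#'
#' Selects ancestral repeats anchored within `max_dist` bp (edge-to-edge) of
#' the element, not overlapping it, with G+C content within `gc_tol` of the
#' element's. When none falls inside the tolerance, the single nearest-GC
#' repeat in range is used with a warning; when none is in range the
#' element is skipped (`NULL` return, with a warning).
#'
#' @param element an [aligned_pair()] with a genomic anchor.
#' @param ars list of AR [aligned_pair()]s.
#' @param max_dist maximum anchor distance (bp).
#' @param gc_tol absolute G+C tolerance.
#' @return list with `counts` (pooled site patterns), `ar_ids`, `fallback`
#'   (logical), or `NULL` when no AR is in range.
#' @export
match_ancestral_repeats <- function(element, ars, max_dist = 500000,
                                    gc_tol = 0.05) {
  same <- vapply(ars, function(a) identical(a$chrom, element$chrom),
                 logical(1))
  dist <- vapply(ars, function(a)
    edge_distance(element$start, element$end, a$start, a$end), numeric(1))
  overl <- vapply(ars, function(a)
    a$chrom == element$chrom &&
      min(a$end, element$end) > max(a$start, element$start), logical(1))
  in_range <- same & !overl & dist <= max_dist
  if (!any(in_range)) {
    warning("no ancestral repeat within ", max_dist, " bp of ", element$id)
    return(NULL)
  }
  gcd <- abs(vapply(ars, `[[`, numeric(1), "gc") - element$gc)
  sel <- which(in_range & gcd <= gc_tol)
  fallback <- FALSE
  if (length(sel) == 0L) {
    sel <- which(in_range)[which.min(gcd[in_range])]
    fallback <- TRUE
    warning("no G+C-matched ancestral repeat for ", element$id,
            "; using nearest-GC repeat ", ars[[sel]]$id)
  }
  pooled <- Reduce(`+`, lapply(ars[sel], count_site_patterns))
  list(counts = pooled, ar_ids = vapply(ars[sel], `[[`, character(1), "id"),
       fallback = fallback)
}

#' Constraint test against matched ancestral repeats
#'
#' Estimates each element's substitution distance and that of its pooled
#' G+C-matched neighbouring ancestral repeats, reports per-element relative
#' rates (element / AR; values below 1 indicate purifying selection), and a
#' two-tailed rank test comparing the element and AR distance
#' distributions.
#'
#' @param elements list of [aligned_pair()]s.
#' @param ars list of AR [aligned_pair()]s.
#' @param model substitution model for [estimate_distance()].
#' @param max_dist,gc_tol see [match_ancestral_repeats()].
#' @return list: `per_element` (`data.table`: id, kind, d_element, d_ar,
#'   relative_rate, n_ars, fallback), `median_d_element`, `median_d_ar`,
#'   `median_relative_rate`, `p` (Mann-Whitney, two-tailed).
#' @export
constraint_test <- function(elements, ars, model = "GTR",
                            max_dist = 500000, gc_tol = 0.05) {
  rows <- vector("list", length(elements))
  for (i in seq_along(elements)) {
    el <- elements[[i]]
    m <- withCallingHandlers(
      match_ancestral_repeats(el, ars, max_dist, gc_tol),
      warning = function(w) invokeRestart("muffleWarning"))
    if (is.null(m)) next
    de <- estimate_distance(count_site_patterns(el), model)
    da <- estimate_distance(m$counts, model)
    rows[[i]] <- data.table::data.table(
      id = el$id, kind = el$kind, d_element = de$d, d_ar = da$d,
      relative_rate = if (da$d > 0) de$d / da$d else NA_real_,
      n_ars = length(m$ar_ids), fallback = m$fallback)
  }
  per <- data.table::rbindlist(rows)
  if (nrow(per) < 3L) stop("fewer than 3 elements with matched ARs")
  wt <- stats::wilcox.test(per$d_element, per$d_ar,
                           alternative = "two.sided", exact = FALSE)
  list(per_element = per,
       median_d_element = stats::median(per$d_element),
       median_d_ar = stats::median(per$d_ar),
       median_relative_rate = stats::median(per$relative_rate, na.rm = TRUE),
       p = wt$p.value)
}
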