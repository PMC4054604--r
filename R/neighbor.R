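#' Protein-coding gene territories
#'
#' Each gene's territory spans every base closer (edge-to-edge, ties to the
#' upstream/leftmost gene) to that gene than to its flanking coding genes;
#' chromosome ends belong to the terminal genes. Overlapping genes are
#' merged into a single territory holder (names joined with ",").
#' Territories tile every chromosome that carries at least one gene.
#'
#' @param coding_genes interval table with `name`.
#' @param genome a [genome_model()].
#' @return `data.table`: gene (holder name), chrom, start, end.
#' @export
gene_territories <- function(coding_genes, genome) {
  g <- data.table::as.data.table(coding_genes)
  if (nrow(g) == 0L)
    return(data.table::data.table(gene = character(), chrom = character(),
                                  start = numeric(), end = numeric()))
  data.table::setorder(g, chrom, start)
  out <- g[, {
    # merge overlapping/abutting gene bodies into territory holders
    grp <- cumsum(c(1, start[-1] > cummax(head(end, -1))))
    mg <- data.table::data.table(start = start, end = end, name = name,
                                 grp = grp)[
      , list(start = min(start), end = max(end),
             gene = paste(name, collapse = ",")), by = "grp"]
    clen <- genome$chrom_lengths[[chrom[1L]]]
    n <- nrow(mg)
    gaps <- if (n > 1L) mg$start[-1L] - mg$end[-n] else numeric()
    bounds <- c(0, if (n > 1L) mg$end[-n] + ceiling(gaps / 2), clen)
    list(gene = mg$gene, start = bounds[-length(bounds)], end = bounds[-1L])
  }, by = "chrom"]
  out[, list(gene, chrom, start, end)]
}

# Place n_perm random copies of each query length uniformly in the workspace
# segments; returns data.table(perm, chrom, start, end).
random_placements <- function(q_len, workspace, n_perm) {
  ws <- data.table::as.data.table(workspace)
  ws[, len := end - start]
  total <- n_perm * length(q_len)
  res <- vector("list", length(q_len))
  for (i in seq_along(q_len)) {
    fit <- ws[ws$len >= q_len[i], ]
    if (nrow(fit) == 0L)
      stop("query of length ", q_len[i],
           " longer than every workspace segment")
    w <- fit$len - q_len[i] + 1
    seg <- sample.int(nrow(fit), n_perm, replace = TRUE, prob = w)
    off <- floor(stats::runif(n_perm) * w[seg])
    res[[i]] <- data.table::data.table(
      perm = seq_len(n_perm), chrom = fit$chrom[seg],
      start = fit$start[seg] + off, end = fit$start[seg] + off + q_len[i])
  }
  data.table::rbindlist(res)
}

count_target_hits <- function(q, targets, mode) {
  if (nrow(q) == 0L || nrow(targets) == 0L) return(integer(nrow(q)))
  if (mode == "midpoint") {
    mid <- floor((q$start + q$end) / 2)
    qg <- GenomicRanges::GRanges(q$chrom, IRanges::IRanges(mid + 1, mid + 1))
  } else {
    qg <- GenomicRanges::GRanges(q$chrom,
                                 IRanges::IRanges(q$start + 1, q$end))
  }
  tg <- GenomicRanges::GRanges(targets$chrom,
                               IRanges::IRanges(targets$start + 1,
                                                targets$end))
  GenomicRanges::countOverlaps(qg, tg, ignore.strand = TRUE) > 0L
}

permutation_enrichment <- function(query_intervals, targets, workspace,
                                   n_perm, seed, mode) {
  q <- data.table::as.data.table(query_intervals)
  observed <- sum(count_target_hits(q, targets, mode))
  perm_counts <- with_seed(seed, {
    pl <- random_placements(q$end - q$start, workspace, n_perm)
    hit <- count_target_hits(pl, targets, mode)
    tab <- tapply(hit, pl$perm, sum)
    out <- integer(n_perm)
    out[as.integer(names(tab))] <- as.integer(tab)
    out
  })
  pm <- mean(perm_counts)
  structure(list(observed = observed, perm_mean = pm,
                 fold = if (pm > 0) observed / pm else Inf,
                 p = (1 + sum(perm_counts >= observed)) / (n_perm + 1),
                 n_perm = n_perm, seed = seed),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("enrichment: observed %d, permuted mean %.2f, fold %.2f, p = %.4g (%d permutations)\n",
              x$observed, x$perm_mean, x$fold, x$p, x$n_perm))
  invisible(x)
}

#' Permutation enrichment of queries in selected gene territories
#'
#' Observed statistic: number of query intervals hitting the selected
#' territories. The null re-places intervals of the same lengths uniformly
#' at random within the intergenic workspace (independent draws, overlaps
#' among placements allowed); the empirical p uses the add-one estimator
#' `(1 + #[perm >= obs]) / (n_perm + 1)`.
#'
#' @param query_intervals interval table (e.g. lncRNA TIRs or loci).
#' @param selected_territories territory intervals tested for enrichment.
#' @param intergenic_space workspace segments the null draws from.
#' @param n_perm number of permutations.
#' @param seed optional integer seed.
#' @param mode `"overlap"` counts any-overlap hits; `"midpoint"` requires
#'   the query midpoint inside a territory.
#' @return an `enrichment_result`: observed, perm_mean, fold, p, n_perm.
#' @export
territory_enrichment <- function(query_intervals, selected_territories,
                                 intergenic_space, n_perm = 1000,
                                 seed = NULL,
                                 mode = c("overlap", "midpoint")) {
  permutation_enrichment(query_intervals, selected_territories,
                         intergenic_space, n_perm, seed, match.arg(mode))
}

#' Permutation enrichment of overlap between two interval sets
#'
#' Same machinery as [territory_enrichment()] with `set_b` as the targets.
#' @param set_a,set_b interval tables.
#' @inheritParams territory_enrichment
#' @export
overlap_enrichment <- function(set_a, set_b, intergenic_space,
                               n_perm = 1000, seed = NULL,
                               mode = c("overlap", "midpoint")) {
  permutation_enrichment(set_a, set_b, intergenic_space, n_perm, seed,
                         match.arg(mode))
}

#' Pair loci with their nearest (or next-but-one) protein-coding gene
#'
#' Nearest is by edge-to-edge distance with the deterministic tie-break of
#' [nearest_feature()]. The next-but-one gene is the closest gene on the
#' far side of the nearest gene; `NA` when none exists.
#'
#' @param loci interval table with `name`.
#' @param coding_genes interval table with `name`.
#' @return `data.table`: locus, nearest_gene, nearest_distance,
#'   next_but_one_gene, next_but_one_distance.
#' @export
pair_loci <- function(loci, coding_genes) {
  l <- data.table::as.data.table(loci)
  g <- data.table::as.data.table(coding_genes)
  res <- vector("list", nrow(l))
  for (i in seq_len(nrow(l))) {
    nf <- nearest_feature(l[i, ], g)
    if (is.null(nf$feature)) {
      res[[i]] <- data.table::data.table(
        locus = l$name[i], nearest_gene = NA_character_,
        nearest_distance = NA_real_, next_but_one_gene = NA_character_,
        next_but_one_distance = NA_real_)
      next
    }
    ng <- nf$feature
    lmid <- (l$start[i] + l$end[i]) / 2
    gmid <- (ng$start + ng$end) / 2
    far <- g[g$chrom == l$chrom[i] & g$name != ng$name, ]
    far <- if (gmid >= lmid) far[far$start >= ng$end, ]
           else far[far$end <= ng$start, ]
    if (nrow(far)) {
      nb <- nearest_feature(l[i, ], far)
      res[[i]] <- data.table::data.table(
        locus = l$name[i], nearest_gene = ng$name,
        nearest_distance = nf$distance, next_but_one_gene = nb$feature$name,
        next_but_one_distance = nb$distance)
    } else {
      res[[i]] <- data.table::data.table(
        locus = l$name[i], nearest_gene = ng$name,
        nearest_distance = nf$distance, next_but_one_gene = NA_character_,
        next_but_one_distance = NA_real_)
    }
  }
  data.table::rbindlist(res)
}

#' Neighbor-expression fold difference (delta statistic)
#'
#' Finds the stages where the reference locus is maximally and minimally
#' expressed (ties broken by earliest stage) and reports the neighbor's
#' relative change between them,
#' `delta = (neighbor[max] - neighbor[min]) / neighbor[min]`,
#' with both neighbor values floored at `epsilon` so the ratio never
#' divides by zero (e.g. neighbor 0 -> 1 with `epsilon` 0.01 gives 99).
#'
#' @param reference_expr reference locus expression across stages.
#' @param neighbor_expr neighbor expression, same stages.
#' @param epsilon expression floor (same units as the input).
#' @return list: stage_min, stage_max, delta (`NA` with a warning when the
#'   reference is constant across stages).
#' @export
delta_statistic <- function(reference_expr, neighbor_expr, epsilon = 0.01) {
  if (length(reference_expr) != length(neighbor_expr))
    stop("stage vectors differ in length")
  if (all(reference_expr <= 0) || all(neighbor_expr <= 0))
    stop("both loci must be detected in at least one stage")
  if (max(reference_expr) == min(reference_expr)) {
    warning("reference constant across stages; delta undefined")
    return(list(stage_min = NA_integer_, stage_max = NA_integer_,
                delta = NA_real_))
  }
  smin <- which.min(reference_expr)
  smax <- which.max(reference_expr)
  nb <- pmax(neighbor_expr, epsilon)
  d <- (nb[smax] - nb[smin]) / nb[smin]
  list(stage_min = smin, stage_max = smax, delta = d)
}

#' Compare two delta distributions
#'
#' Two-tailed Mann-Whitney (Wilcoxon rank-sum) test plus group medians.
#' @param deltas_a,deltas_b numeric vectors (>= 3 values each).
#' @return list: median_a, median_b, p.
#' @export
compare_delta_distributions <- function(deltas_a, deltas_b) {
  deltas_a <- deltas_a[!is.na(deltas_a)]
  deltas_b <- deltas_b[!is.na(deltas_b)]
  if (length(deltas_a) < 3L || length(deltas_b) < 3L)
    stop("need at least 3 values per group")
  # exact distribution for small tie-free samples, normal approx otherwise
  wt <- suppressWarnings(
    stats::wilcox.test(deltas_a, deltas_b, alternative = "two.sided"))
  list(median_a = stats::median(deltas_a),
       median_b = stats::median(deltas_b), p = wt$p.value)
}

#' Pearson correlation of paired fold-changes
#'
#' @param lnc_fc,gene_fc paired fold-change vectors (n >= 3).
#' @return Pearson r.
#' @export
foldchange_correlation <- function(lnc_fc, gene_fc) {
  if (length(lnc_fc) != length(gene_fc)) stop("vectors differ in length")
  if (length(lnc_fc) < 3L) stop("need at least 3 pairs")
  if (stats::sd(lnc_fc) == 0 || stats::sd(gene_fc) == 0)
    stop("zero variance")
  stats::cor(lnc_fc, gene_fc)
}
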