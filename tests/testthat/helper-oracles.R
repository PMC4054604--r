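# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own data structures and algorithms.

# O(n^2) single-linkage clustering of positions: pairwise linkage, transitive
# closure. Returns a list of sorted position vectors.
brute_cluster <- function(pos, max_gap) {
  if (length(pos) == 0L) return(list())
  pos <- sort(pos)
  n <- length(pos)
  grp <- seq_len(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (abs(pos[i] - pos[j]) <= max_gap && grp[i] != grp[j]) {
      grp[grp == grp[j]] <- grp[i]
    }
  }
  unname(lapply(split(pos, grp), sort))
}

# O(n^2) merge of intervals by edge-to-edge gap (transitive closure).
brute_merge <- function(starts, ends, merge_dist) {
  n <- length(starts)
  if (n == 0L) return(list(starts = numeric(), ends = numeric(),
                           members = list()))
  grp <- seq_len(n)
  gap <- function(i, j) max(0, max(starts[i], starts[j]) -
                              min(ends[i], ends[j]))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (gap(i, j) <= merge_dist && grp[i] != grp[j])
      grp[grp == grp[j]] <- grp[i]
  }
  sp <- split(seq_len(n), grp)
  o <- order(vapply(sp, function(ix) min(starts[ix]), numeric(1)))
  sp <- sp[o]
  list(starts = vapply(sp, function(ix) min(starts[ix]), numeric(1)),
       ends = vapply(sp, function(ix) max(ends[ix]), numeric(1)),
       members = sp)
}

# Per-base overlap / coverage oracles on tiny chromosomes.
brute_overlap_len <- function(a, b) {
  if (a$chrom != b$chrom) return(0)
  sum(seq(a$start, a$end - 1) %in% seq(b$start, b$end - 1))
}

brute_covered_fraction <- function(start, end, te_starts, te_ends) {
  bases <- seq(start, end - 1)
  cov <- rep(FALSE, length(bases))
  for (k in seq_along(te_starts))
    cov <- cov | (bases >= te_starts[k] & bases < te_ends[k])
  mean(cov)
}

# Per-base nearest-gene oracle (edge distance; ties to the earlier gene).
brute_territories <- function(gene_starts, gene_ends, chrom_len) {
  dist_to <- function(b, s, e) {
    if (b < s) s - b else if (b >= e) b - e + 1 else 0
  }
  owner <- integer(chrom_len)
  for (b in seq_len(chrom_len) - 1L) {
    d <- mapply(dist_to, b, gene_starts, gene_ends)
    owner[b + 1L] <- which.min(d)   # which.min takes the first (earlier) tie
  }
  owner
}

# Exact two-sample rank-sum p-value by enumeration of group assignments.
brute_ranksum_p <- function(x, y) {
  all_v <- c(x, y)
  n <- length(all_v); nx <- length(x)
  r <- rank(all_v)
  obs <- sum(r[seq_len(nx)])
  combs <- utils::combn(n, nx)
  stats_all <- apply(combs, 2L, function(ix) sum(r[ix]))
  mu <- mean(stats_all)
  mean(abs(stats_all - mu) >= abs(obs - mu) - 1e-12)
}

# Brute-force ML distance for the GTR family on a grid: maximise the
# multinomial likelihood of the joint counts under P(d) = exp(Q d) with Q
# the GTR rate matrix fitted from the symmetrised frequencies; here we use
# the simpler JC generator as the simulation truth, so the grid search is
# over JC likelihood.
brute_ml_jc <- function(counts, step = 1e-4, dmax = 1) {
  n <- sum(counts)
  mismatch <- n - sum(diag(counts))
  grid <- seq(step, dmax, by = step)
  ll <- vapply(grid, function(d) {
    pm <- 0.25 - 0.25 * exp(-4 * d / 3)   # per off-diagonal cell prob is pm*...
    psame <- 0.25 + 0.75 * exp(-4 * d / 3)
    mismatch * log(pm) + sum(diag(counts)) * log(psame)
  }, numeric(1))
  grid[which.max(ll)]
}

# Deterministic random interval sets for property tests.
random_tagset <- function(n, chrom_len = 10000, n_chrom = 2) {
  tag_set(chrom = paste0("c", sample.int(n_chrom, n, replace = TRUE)),
          pos = sample.int(chrom_len, n, replace = TRUE) - 1L,
          strand = sample(c("+", "-"), n, replace = TRUE),
          count = sample.int(3L, n, replace = TRUE))
}
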