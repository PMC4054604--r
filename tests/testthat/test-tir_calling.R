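make_tags <- function(pos, count = 1, strand = "+", chrom = "chr1") {
  tag_set(chrom = rep(chrom, length(pos)), pos = pos,
          strand = rep(strand, length.out = length(pos)), count = count)
}

test_that("cluster_tags chains positions by inclusive gap", {
  tg <- make_tags(c(100, 110, 135), count = c(3, 2, 1))
  cl <- cluster_tags(tg, max_gap = 20)
  expect_equal(nrow(cl), 2L)
  expect_equal(cl$start, c(100, 135))
  expect_equal(cl$end, c(111, 136))
  expect_equal(cl$n_reads, c(5, 1))

  # boundary: exactly 20 apart joins
  cl2 <- cluster_tags(make_tags(c(100, 120)), max_gap = 20)
  expect_equal(nrow(cl2), 1L)
  # 21 apart does not
  expect_equal(nrow(cluster_tags(make_tags(c(100, 121)), max_gap = 20)), 2L)

  expect_equal(nrow(cluster_tags(make_tags(integer()))), 0L)
})

test_that("strands never mix during clustering or merging", {
  tg <- tag_set(chrom = c("chr1", "chr1"), pos = c(100, 105),
                strand = c("+", "-"))
  expect_equal(nrow(cluster_tags(tg)), 2L)
  cl <- cluster_tags(tag_set(chrom = c("chr1", "chr1"), pos = c(100, 120),
                             strand = c("+", "-")))
  expect_equal(nrow(merge_clusters(cl, 400)), 2L)
})

test_that("merge_clusters merges by edge-to-edge gap up to 400", {
  cl <- cluster_tags(make_tags(c(100:110, 380:389)))
  tir <- merge_clusters(cl, merge_dist = 400)
  expect_equal(nrow(tir), 1L)
  expect_equal(tir$start, 100)
  expect_equal(tir$end, 390)
  expect_equal(tir$n_reads, 21)

  far <- cluster_tags(make_tags(c(100, 600)))
  expect_equal(nrow(merge_clusters(far, 400)), 2L)   # gap 499 > 400

  # boundary: gap exactly 400 merges, 401 does not
  b <- cluster_tags(make_tags(c(100, 501)))          # [100,101) and [501,502)
  expect_equal(nrow(merge_clusters(b, 400)), 1L)
  b2 <- cluster_tags(make_tags(c(100, 502)))
  expect_equal(nrow(merge_clusters(b2, 400)), 2L)
})

test_that("filter_tirs applies read support and DHS overlap", {
  cl <- cluster_tags(tag_set(chrom = rep("chr1", 9),
                             pos = c(rep(100, 4), rep(1000, 5)),
                             strand = "+"))
  tirs <- merge_clusters(cl, 400)
  expect_equal(tirs$n_reads, c(4, 5))
  dhs <- gintervals("chr1", c(95, 995), c(105, 1005))
  kept <- filter_tirs(tirs, min_reads = 5, dhs_peaks = dhs)
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$n_reads, 5)

  # 1-bp DHS overlap is enough at min_overlap = 1
  dhs1 <- gintervals("chr1", 1000, 1001)
  expect_equal(nrow(filter_tirs(tirs, 5, dhs1, min_overlap = 1)), 1L)

  # no DHS anywhere removes everything
  expect_equal(nrow(filter_tirs(tirs, 1, gintervals("chr9", 1, 2))), 0L)
})

test_that("tag conservation holds through clustering and merging", {
  set.seed(11)
  for (rep in 1:20) {
    tg <- random_tagset(sample.int(200, 1))
    total <- sum(tg$count)
    cl <- cluster_tags(tg)
    expect_equal(sum(cl$n_reads), total)
    expect_equal(sum(merge_clusters(cl)$n_reads), total)
  }
})

test_that("clustering equals the brute-force linkage oracle (small n)", {
  set.seed(5)
  for (rep in 1:25) {
    pos <- sample.int(500, sample.int(40, 1), replace = TRUE)
    tg <- make_tags(pos)
    cl <- cluster_tags(tg, max_gap = 20)
    oracle <- brute_cluster(unique(sort(pos)), 20)
    expect_equal(nrow(cl), length(oracle))
    expect_equal(cl$start, vapply(oracle, min, numeric(1)))
    expect_equal(cl$end, vapply(oracle, max, numeric(1)) + 1)
  }
})

test_that("TIR count is monotone in min_reads", {
  set.seed(8)
  tg <- random_tagset(300)
  tirs <- merge_clusters(cluster_tags(tg))
  dhs <- gintervals(rep(c("c1", "c2"), each = 1),
                    c(0, 0), c(10000, 10000))
  n_kept <- vapply(c(1, 2, 5, 10),
                   function(m) nrow(filter_tirs(tirs, m, dhs)), numeric(1))
  expect_true(all(diff(n_kept) <= 0))
})

test_that("associate_transcripts links TIRs at transcript 5' ends only", {
  ex <- data.table::data.table(
    transcript_id = "t_plus", gene_id = "g1", chrom = "chr1",
    start = c(1000, 2000), end = c(1200, 2400), strand = "+")
  txs <- transcript_set(ex)
  tirs <- data.table::data.table(
    id = c("TIR_A", "TIR_B"), chrom = "chr1", strand = "+",
    start = c(980, 2100), end = c(1040, 2160),
    n_reads = c(10, 10), n_clusters = 1L, dhs_overlap = TRUE)
  res <- associate_transcripts(tirs, txs)
  # TIR_A covers the 5' end; TIR_B only an internal/3' exon
  expect_equal(res$links$tir_id, "TIR_A")
  expect_equal(res$links$transcript_id, "t_plus")
  expect_equal(res$transcripts$transcripts$transcript_id, "t_plus")
})

test_that("strand mismatch prevents linkage", {
  ex <- data.table::data.table(transcript_id = "t1", gene_id = "g",
                               chrom = "chr1", start = 1000, end = 1500,
                               strand = "+")
  tirs <- data.table::data.table(id = "TIR_A", chrom = "chr1",
                                 strand = "-", start = 980, end = 1040,
                                 n_reads = 5, n_clusters = 1L,
                                 dhs_overlap = TRUE)
  res <- associate_transcripts(tirs, transcript_set(ex))
  expect_equal(nrow(res$links), 0L)
  expect_equal(res$dropped$reason, "no_tir")
})

test_that("mono-exonic strand imputation follows the single-candidate rule", {
  ex <- data.table::data.table(transcript_id = "mono", gene_id = "g",
                               chrom = "chr1", start = 1000, end = 1600,
                               strand = ".")
  txs <- transcript_set(ex)
  base <- data.table::data.table(n_reads = 5, n_clusters = 1L,
                                 dhs_overlap = TRUE)

  # one minus-strand TIR at the right end -> strand imputed to minus
  tir_r <- cbind(data.table::data.table(id = "TIR_R", chrom = "chr1",
                                        strand = "-", start = 1570,
                                        end = 1620), base)
  res <- associate_transcripts(tir_r, txs)
  expect_equal(res$links$transcript_id, "mono")
  expect_equal(res$transcripts$transcripts$strand, "-")

  # candidate TIRs at both ends -> excluded as ambiguous
  tir_b <- rbind(tir_r,
                 cbind(data.table::data.table(id = "TIR_L", chrom = "chr1",
                                              strand = "+", start = 990,
                                              end = 1040), base))
  res2 <- associate_transcripts(tir_b, txs)
  expect_equal(nrow(res2$links), 0L)
  expect_equal(res2$dropped$reason, "ambiguous_bidirectional_tir")
})

test_that("support/expression correlation behaves", {
  tirs <- data.table::data.table(id = paste0("T", 1:5),
                                 n_reads = c(10, 100, 1000, 10, 100))
  links <- data.table::data.table(tir_id = paste0("T", 1:5),
                                  transcript_id = paste0("x", 1:5))
  fpkm <- stats::setNames(tirs$n_reads * 2, links$transcript_id)
  expect_gt(tir_support_expression_correlation(tirs, links, fpkm), 0.999)

  expect_error(tir_support_expression_correlation(
    tirs[1:2], links[1:2], fpkm), "at least 3")
  const <- stats::setNames(rep(5, 5), links$transcript_id)
  expect_error(tir_support_expression_correlation(tirs, links, const),
               "zero variance")
})

test_that("planted log-scale correlation is recovered", {
  set.seed(21)
  n <- 500
  rho <- 0.5
  lx <- rnorm(n)
  ly <- rho * lx + sqrt(1 - rho^2) * rnorm(n)
  tirs <- data.table::data.table(id = paste0("T", 1:n),
                                 n_reads = pmax(1, round(10^(lx + 2))))
  links <- data.table::data.table(tir_id = tirs$id,
                                  transcript_id = paste0("x", 1:n))
  fpkm <- stats::setNames(10^(ly + 1), links$transcript_id)
  r <- tir_support_expression_correlation(tirs, links, fpkm,
                                          pseudocount = 0)
  expect_lt(abs(r - rho), 0.1)
})
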