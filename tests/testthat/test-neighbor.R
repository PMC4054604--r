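test_that("gene_territories splits gaps at the midpoint", {
  g <- genome_model("chr1", 1000)
  genes <- data.table::data.table(chrom = "chr1", start = c(100, 600),
                                  end = c(200, 700), name = c("A", "B"))
  tt <- gene_territories(genes, g)
  expect_equal(tt$start, c(0, 400))
  expect_equal(tt$end, c(400, 1000))

  single <- gene_territories(genes[1, ], g)
  expect_equal(single$start, 0)
  expect_equal(single$end, 1000)

  # no gene on a chromosome -> no territory there
  g2 <- genome_model(c("chr1", "chr2"), c(1000, 1000))
  expect_equal(unique(gene_territories(genes, g2)$chrom), "chr1")
})

test_that("territories agree with the per-base nearest-gene oracle", {
  set.seed(41)
  for (rep in 1:5) {
    L <- 10000
    n <- sample(2:5, 1)
    s <- sort(sample.int(L - 500, n))
    e <- pmin(s + sample.int(300, n) + 50, L)
    # drop overlaps to keep the oracle simple
    keep <- c(TRUE, s[-1] > e[-n])
    s <- s[keep]; e <- e[keep]; n <- length(s)
    genes <- data.table::data.table(chrom = "chr1", start = s, end = e,
                                    name = paste0("g", seq_len(n)))
    tt <- gene_territories(genes, genome_model("chr1", L))
    owner <- brute_territories(s, e, L)
    got <- integer(L)
    for (i in seq_len(nrow(tt)))
      got[(tt$start[i] + 1):tt$end[i]] <- match(tt$gene[i], genes$name)
    expect_equal(got, owner)
    # tiling: disjoint and complete
    expect_equal(sum(tt$end - tt$start), L)
  }
})

test_that("planted territory enrichment is detected and saturates", {
  set.seed(1)
  ws <- data.table::data.table(chrom = "chr1",
                               start = seq(0, 90000, by = 10000),
                               end = seq(0, 90000, by = 10000) + 8000)
  sel <- ws[1, ]                       # 10% of the workspace
  queries <- gintervals("chr1", sel$start + seq(100, 4100, by = 500),
                        sel$start + seq(100, 4100, by = 500) + 200)
  er <- territory_enrichment(queries, sel, ws, n_perm = 999, seed = 2)
  expect_equal(er$observed, 9L)
  expect_gt(er$fold, 5)
  expect_equal(er$p, 1 / 1000)

  # targets covering everything give fold ~ 1
  sat <- territory_enrichment(queries, ws, ws, n_perm = 199, seed = 3)
  expect_equal(sat$fold, 1)
  expect_equal(sat$p, 1)

  expect_error(territory_enrichment(gintervals("chr1", 0, 9000), sel, ws,
                                    10, 1), "longer than")
})

test_that("overlap_enrichment flags identical sets and not random ones", {
  set.seed(4)
  ws <- data.table::data.table(chrom = "chr1", start = 0, end = 1e6)
  a <- gintervals("chr1", s <- sort(sample.int(9e5, 20)) , s + 500)
  ident <- overlap_enrichment(a, a, ws, n_perm = 199, seed = 5)
  expect_equal(ident$observed, 20L)
  expect_equal(ident$p, 1 / 200)
  expect_gt(ident$fold, 5)

  b <- gintervals("chr1", s2 <- sort(sample.int(9e5, 200)), s2 + 500)
  indep <- overlap_enrichment(a, b, ws, n_perm = 399, seed = 6)
  expect_lt(abs(indep$fold - 1), 0.5)
  expect_gt(indep$p, 0.01)
})

test_that("pair_loci finds nearest and next-but-one genes", {
  genes <- data.table::data.table(chrom = "chr1",
                                  start = c(0, 10000, 30000, 80000),
                                  end = c(2000, 12000, 32000, 82000),
                                  name = c("outer", "near", "right", "far"))
  lnc <- data.table::data.table(chrom = "chr1", start = 20000, end = 20500,
                                name = "lnc1")
  pr <- pair_loci(lnc, genes)
  expect_equal(pr$nearest_gene, "near")
  expect_equal(pr$nearest_distance, 8000)
  # next-but-one: the gene on the far side of the nearest gene
  expect_equal(pr$next_but_one_gene, "outer")

  # nearest on the right: next-but-one lies further right
  lnc2 <- data.table::data.table(chrom = "chr1", start = 28000,
                                 end = 28500, name = "lnc2")
  pr2 <- pair_loci(lnc2, genes)
  expect_equal(pr2$nearest_gene, "right")
  expect_equal(pr2$next_but_one_gene, "far")

  # chromosome end: only one gene, nothing beyond it
  solo <- pair_loci(lnc, genes[2, ])
  expect_equal(solo$nearest_gene, "near")
  expect_true(is.na(solo$next_but_one_gene))
})

test_that("delta_statistic implements the fold-difference formula", {
  d <- delta_statistic(c(1, 5, 2), c(2, 3, 2))
  expect_equal(d$stage_min, 1L)
  expect_equal(d$stage_max, 2L)
  expect_equal(d$delta, 0.5)

  expect_equal(delta_statistic(c(1, 5, 2), c(7, 7, 7))$delta, 0)
  expect_equal(delta_statistic(c(1, 5, 2), c(0, 1, 0))$delta, 99)
  expect_warning(dc <- delta_statistic(c(2, 2, 2), c(1, 5, 1)), "constant")
  expect_true(is.na(dc$delta))
  expect_error(delta_statistic(c(0, 0, 0), c(1, 1, 1)), "detected")

  # scale invariance of the neighbor (denominator above epsilon)
  d1 <- delta_statistic(c(1, 5, 2), c(2, 3, 2))
  d2 <- delta_statistic(c(1, 5, 2), c(2, 3, 2) * 1000)
  expect_equal(d1$delta, d2$delta)
})

test_that("compare_delta_distributions matches exact rank enumeration", {
  a <- c(1.2, 3.4, 0.5)
  b <- c(2.2, 5.1, 4.4)
  got <- compare_delta_distributions(a, b)
  expect_equal(got$p, brute_ranksum_p(a, b), tolerance = 1e-12)
  expect_equal(got$median_a, 1.2)

  same <- compare_delta_distributions(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_gt(same$p, 0.9)
  expect_error(compare_delta_distributions(c(1, 2), c(1, 2, 3)),
               "at least 3")
})

test_that("foldchange_correlation handles exact and planted cases", {
  expect_equal(foldchange_correlation(1:5, 2 * (1:5)), 1)
  expect_equal(foldchange_correlation(1:5, -(1:5)), -1)
  expect_error(foldchange_correlation(1:5, rep(1, 5)), "zero variance")
  set.seed(33)
  x <- rnorm(200)
  y <- 0.8 * x + sqrt(1 - 0.64) * rnorm(200)
  expect_lt(abs(foldchange_correlation(x, y) - 0.8), 0.1)
})
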