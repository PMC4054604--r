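test_that("locate_transcript applies the decision order", {
  spans <- data.table::data.table(chrom = "chr1",
                                  start = c(999, 5000, 50000),
                                  end = c(1500, 5800, 50800))
  tirs <- data.table::data.table(chrom = "chr1",
                                 start = c(990, 5000, 50000),
                                 end = c(1050, 5060, 50060),
                                 strand = c("+", "-", "+"))
  coding_genes <- data.table::data.table(chrom = "chr1", start = 0,
                                         end = 1000, name = "g1",
                                         strand = "+")
  coding_tirs <- data.table::data.table(chrom = "chr1", start = 5200,
                                        end = 5260, strand = "+")
  cat <- locate_transcript(spans, tirs, coding_genes, coding_tirs)
  # 1 bp gene-body overlap -> intragenic; opposite-strand TIR 140 bp from a
  # coding TIR -> bidirectional; far locus -> intergenic
  expect_equal(cat, c("intragenic", "bidirectional", "intergenic"))

  # same-strand nearby TIR is not bidirectional
  tirs2 <- data.table::copy(tirs)[2, strand := "+"]
  expect_equal(locate_transcript(spans, tirs2, coding_genes,
                                 coding_tirs)[2], "intergenic")

  # window boundary: edge-to-edge 1000 is inside, 1001 is not
  ct <- data.table::data.table(chrom = "chr1", start = 5800 + 260,
                               end = 5800 + 320, strand = "+")
  ct$start <- tirs$end[2] + 1000; ct$end <- ct$start + 60
  expect_equal(locate_transcript(spans[2, ], tirs[2, ], coding_genes,
                                 ct)[1], "bidirectional")
  ct$start <- tirs$end[2] + 1001; ct$end <- ct$start + 60
  expect_equal(locate_transcript(spans[2, ], tirs[2, ], coding_genes,
                                 ct)[1], "intergenic")
})

test_that("lncrna_filter applies the strict >200 nt rule", {
  expect_false(lncrna_filter(200, "noncoding", FALSE))
  expect_true(lncrna_filter(201, "noncoding", FALSE))
  expect_false(lncrna_filter(1000, "noncoding", TRUE))
  expect_false(lncrna_filter(1000, "coding", FALSE))
  expect_warning(out <- lncrna_filter(1000, "unknown", FALSE), "unknown")
  expect_false(out)
})

test_that("assign_class maps chromatin labels to lncRNA classes", {
  expect_equal(
    assign_class(rep("intergenic", 3),
                 c("enhancer_like", "promoter_like", "ambiguous")),
    c("elncRNA", "plncRNA", "none"))
  expect_equal(assign_class("bidirectional", "enhancer_like"), "none")
  expect_error(assign_class("intergenic", NA_character_),
               "without TIR classification")
})

test_that("orientation implements the head/tail truth table", {
  lnc <- function(s) data.table::data.table(chrom = "c", start = 100,
                                            end = 200, strand = s)
  gene <- function(s) data.table::data.table(chrom = "c", start = 500,
                                             end = 600, strand = s)
  expect_equal(orientation(lnc("+"), gene("+")), "tail_to_head")
  expect_equal(orientation(lnc("-"), gene("+")), "head_to_head")
  expect_equal(orientation(lnc("+"), gene("-")), "tail_to_tail")
  expect_equal(orientation(lnc("-"), gene("-")), "head_to_tail")
  expect_error(orientation(lnc("+"),
                           data.table::data.table(chrom = "c", start = 150,
                                                  end = 250, strand = "+")),
               "overlapping")
})

test_that("orientation is invariant under locus reflection", {
  flip <- function(x, L = 1000) data.table::data.table(
    chrom = x$chrom, start = L - x$end, end = L - x$start,
    strand = ifelse(x$strand == "+", "-", "+"))
  set.seed(9)
  for (i in 1:20) {
    l <- data.table::data.table(chrom = "c", start = 100, end = 200,
                                strand = sample(c("+", "-"), 1))
    g <- data.table::data.table(chrom = "c", start = 500, end = 600,
                                strand = sample(c("+", "-"), 1))
    o <- orientation(l, g)
    o_ref <- orientation(flip(l), flip(g))
    expect_equal(o_ref, o)   # symmetric classes map to themselves
  }
})

test_that("te_density equals brute-force per-base counting", {
  iv <- gintervals("chr1", 100, 200)
  te <- gintervals(rep("chr1", 2), c(120, 150), c(150, 170))
  expect_equal(te_density(iv, te), 0.5)
  expect_equal(te_density(iv, te[0, ]), 0)
  # overlapping TEs counted once; full tiling capped at 1
  te2 <- gintervals(rep("chr1", 3), c(90, 120, 150), c(160, 180, 210))
  expect_equal(te_density(iv, te2), 1)

  set.seed(14)
  for (i in 1:20) {
    s <- sample.int(500, 1); e <- s + sample.int(100, 1)
    ts <- sample.int(600, 5); te_ends <- ts + sample.int(50, 5)
    got <- te_density(gintervals("c", s, e),
                      gintervals(rep("c", 5), ts, te_ends))
    expect_equal(got, brute_covered_fraction(s, e, ts, te_ends))
  }
})

test_that("cpg_overlap requires strictly more than one shared base", {
  tir <- gintervals("chr1", 100, 200)
  expect_true(cpg_overlap(tir, gintervals("chr1", 198, 300)))   # 2 bp
  expect_false(cpg_overlap(tir, gintervals("chr1", 199, 300)))  # 1 bp
  expect_false(cpg_overlap(tir, gintervals("chr1", 300, 400)))
})

test_that("catalog_summary computes per-class statistics", {
  rec <- data.table::data.table(
    lnc_class = c("elncRNA", "elncRNA", "plncRNA"),
    mature_length = c(100, 300, 500), n_exons = c(1L, 2L, 1L),
    tss_distance = c(1000, 3000, 2000))
  s <- catalog_summary(rec)
  expect_equal(s[lnc_class == "elncRNA", median_length], 200)
  expect_equal(s[lnc_class == "elncRNA", monoexonic_fraction], 0.5)
  expect_equal(sum(s$fraction), 1)
  expect_equal(nrow(catalog_summary(rec[0, ])), 0L)
})

test_that("categories partition the linked transcripts in a full run", {
  b <- simulate_bundle(simulation_config(seed = 12, n_coding = 12,
                                         n_lnc = 8))
  r <- run_pipeline(b, pipeline_params(n_perm = 20))
  cnt <- r$report$counts
  cats <- unlist(cnt$categories)
  expect_equal(sum(cats), cnt$linked_transcripts)
  expect_equal(cnt$intergenic_lncRNA,
               cnt$elncRNA + cnt$plncRNA + cnt$ambiguous)
})
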