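flat_track <- function(value = 1, len = 100000, lib = 1e6,
                       chrom = "chr1", mark = "H3K4me1") {
  chromatin_track(data.table::data.table(chrom = chrom, start = 0,
                                         end = len, value = value),
                  mark, lib)
}

test_that("quantify_mark normalises windowed coverage per million", {
  tr <- flat_track(value = 1, lib = 1e6)
  reg <- gintervals("chr1", 9000, 11000)            # midpoint 10000
  expect_equal(quantify_mark(tr, reg, window = 2000), 2000)

  # zero coverage
  tr0 <- chromatin_track(data.table::data.table(chrom = "chr1", start = 0,
                                                end = 10, value = 0),
                         "m", 1e6)
  expect_equal(quantify_mark(tr0, reg, window = 2000), 0)

  # window clipped at the chromosome start
  near0 <- gintervals("chr1", 50, 150)              # midpoint 100
  expect_equal(quantify_mark(tr, near0, window = 2000), 1100)

  expect_error(chromatin_track(tr$cov, "m", 0), "library_size")
})

test_that("classify_regions labels by the sign of the difference", {
  cls <- classify_regions(c(10, 2, 5), c(2, 10, 5))
  expect_equal(cls$label, c("enhancer_like", "promoter_like", "ambiguous"))
  expect_equal(cls$diff, c(8, -8, 0))
  expect_equal(cls$log2_ratio[3], 0)
  expect_error(classify_regions(-1, 2), "non-negative")

  # invariant to common rescaling of both score vectors
  cls2 <- classify_regions(c(10, 2, 5) * 7.3, c(2, 10, 5) * 7.3)
  expect_equal(cls2$label, cls$label)
  # label invariant to pseudocount choice
  for (p in c(0.1, 1, 10))
    expect_equal(classify_regions(c(10, 2), c(2, 10), pseudocount = p)$label,
                 cls$label[1:2])
})

test_that("planted two-class tracks are recovered (small version)", {
  set.seed(3)
  n <- 60
  loci <- data.table::data.table(
    chrom = "chr1", tss = seq(5000, by = 5000, length.out = n),
    class = rep(c("enhancer", "promoter"), n / 2))
  cfg <- simulation_config(seed = 3)
  trk <- simulate_mark_tracks(loci, cfg)
  reg <- gintervals(loci$chrom, loci$tss - 100, loci$tss + 100)
  cls <- classify_regions(quantify_mark(trk$me1, reg),
                          quantify_mark(trk$me3, reg))
  truth <- ifelse(loci$class == "enhancer", "enhancer_like",
                  "promoter_like")
  expect_gte(mean(cls$label == truth), 0.9)
})

test_that("signal_matrix bins, sorts, and matches quantify_mark", {
  tr <- flat_track(value = 2, lib = 2e6)
  reg <- gintervals("chr1", c(10000, 30000), c(10200, 30200))
  sm <- signal_matrix(tr, reg, window = 4000, bin = 50)
  expect_equal(dim(sm$matrix), c(2L, 80L))
  expect_true(all(abs(sm$matrix - 2 * 1e6 / 2e6) < 1e-12))

  expect_error(signal_matrix(tr, reg, window = 4000, bin = 33),
               "divisible")

  # spike at a region midpoint lands in the centre bin
  spike <- chromatin_track(
    data.table::data.table(chrom = "chr1", start = 10100, end = 10110,
                           value = 50), "m", 1e6)
  sms <- signal_matrix(spike, reg[1, ], window = 4000, bin = 50)
  expect_equal(unname(which.max(sms$matrix[1, ])), 41L)  # bin [0, 50)

  # reversing sort_by reverses row order
  a <- signal_matrix(tr, reg, window = 400, bin = 50, sort_by = c(1, 2))
  b <- signal_matrix(tr, reg, window = 400, bin = 50, sort_by = c(2, 1))
  expect_equal(rownames(a$matrix), rev(rownames(b$matrix)))

  # row sums x bin reproduce the window quantification
  q <- quantify_mark(tr, reg, window = 4000)
  expect_equal(unname(rowSums(sm$matrix) * sm$bin), q)
})

test_that("metaprofile averages in transcription orientation", {
  tr <- flat_track(value = 3)
  reg <- gintervals("chr1", c(10000, 20000), c(10200, 20200),
                    strand = c("+", "-"))
  mp <- metaprofile(tr, reg, window = 400, bin = 50)
  expect_equal(unname(mp), rep(3, 8))
  expect_equal(unname(metaprofile(tr, reg, 400, 50)),
               unname(colMeans(signal_matrix(tr, reg, 400, 50)$matrix)))

  # minus-strand spike 100 bp 3' of the midpoint appears downstream (+100)
  spike <- chromatin_track(
    data.table::data.table(chrom = "chr1", start = 19950, end = 20000,
                           value = 10), "m", 1e6)
  neg <- gintervals("chr1", 20050, 20150, strand = "-")  # midpoint 20100
  mp2 <- metaprofile(spike, neg, window = 400, bin = 50)
  expect_equal(names(mp2)[which.max(mp2)], "100")

  expect_error(metaprofile(tr, gintervals(character(), numeric(),
                                          numeric()), 400, 50), "empty")
})

test_that("stranded_tss_profile counts reads in transcription frame", {
  tss <- data.table::data.table(chrom = "chr1", pos = 1000, strand = "+")
  tags <- tag_set("chr1", 1010, "+")
  pr <- stranded_tss_profile(tags, tss, flank = 50)
  expect_equal(unname(pr$sense[pr$offsets == 10]), 1)
  expect_equal(sum(pr$antisense), 0)

  # mirror dataset: flip all strands -> sense/antisense swap
  tags_m <- tag_set("chr1", 1010, "-")
  tss_m <- data.table::data.table(chrom = "chr1", pos = 1000, strand = "-")
  pr_m <- stranded_tss_profile(tags_m, tss, flank = 50)
  expect_equal(unname(pr_m$antisense[pr_m$offsets == 10]), 1)
  # minus-strand TSS flips the offset sign
  pr2 <- stranded_tss_profile(tags_m, tss_m, flank = 50)
  expect_equal(unname(pr2$sense[pr2$offsets == -10]), 1)
})

test_that("tag_density_track slides a step-aligned window", {
  tg <- tag_set("chr1", 505, "+")
  dens <- tag_density_track(tg, window = 100, step = 10)
  expect_equal(nrow(dens), 10L)                      # window/step windows
  expect_true(all(dens$value == 1))
  expect_true(all(dens$start %% 10 == 0))
  expect_true(all(505 >= dens$start & 505 < dens$end))

  expect_equal(nrow(tag_density_track(tag_set(character(), integer(),
                                              character()))), 0L)

  # conservation: summed density = window/step x total tag count
  set.seed(2)
  tg2 <- tag_set(rep("chr1", 50), sample(1000:5000, 50), "+",
                 count = sample.int(3, 50, replace = TRUE))
  d2 <- tag_density_track(tg2, 100, 10)
  expect_equal(sum(d2$value), 10 * sum(tg2$count))
})
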