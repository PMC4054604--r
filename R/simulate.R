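#' Simulation configuration with planted ground truth parameters
#'
#' Defaults describe a small genome that emulates the pipeline's real
#' inputs: 5'-tag pileups with positional jitter around planted TSSs,
#' DHS peaks over true TIRs, H3K4me1/me3 coverage with class-dependent
#' ratios, a tissue panel and a 3-stage series with planted neighbor
#' coupling, and sequence pairs evolved at planted substitution rates with
#' nearby neutral ancestral repeats.
#'
#' @param seed integer seed; the whole bundle is a deterministic function
#'   of the config including this seed.
#' @param n_chrom,chrom_length genome shape.
#' @param n_coding,n_lnc locus counts (coding genes flank every lncRNA).
#' @param class_mix elncRNA/plncRNA mix; allocated deterministically
#'   (exact counts) unless `stochastic_mix`.
#' @param cage_mean,cage_disp negative-binomial tag count per TIR
#'   (mean / dispersion `size`).
#' @param jitter_sd positional jitter of tag 5' ends around the TSS (bp).
#' @param dhs_width DHS peak width centred on each true TSS (bp).
#' @param ratio_enh,ratio_prom me1:me3 ratio per class (enhancer-like 4:1,
#'   promoter-like 1:4).
#' @param chip_depth expected ChIP reads per region (me1 + me3 combined).
#' @param n_tissues tissue panel size.
#' @param conc_elnc,conc_plnc,conc_coding Dirichlet concentration of
#'   tissue shares per class (lower = more tissue-specific).
#' @param alpha_elnc,alpha_plnc planted stage-expression coupling between a
#'   lncRNA and its nearest gene.
#' @param d_ar neutral (ancestral repeat) substitution rate.
#' @param rate_factor_elnc,rate_factor_plnc element rate as a fraction of
#'   the neutral rate (1 = neutral, 0.8 = 20% constraint).
#' @param element_length,ar_length,ars_per_element alignment geometry.
#' @param stochastic_mix draw classes from `class_mix` instead of exact
#'   allocation.
#' @return a list of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1,
                              n_chrom = 2, chrom_length = 1e6,
                              n_coding = 30, n_lnc = 20,
                              class_mix = c(elncRNA = 0.5, plncRNA = 0.5),
                              cage_mean = 50, cage_disp = 2,
                              jitter_sd = 5, dhs_width = 300,
                              ratio_enh = c(4, 1), ratio_prom = c(1, 4),
                              chip_depth = 100,
                              n_tissues = 10,
                              conc_elnc = 0.2, conc_plnc = 2,
                              conc_coding = 5,
                              alpha_elnc = 1, alpha_plnc = 0,
                              d_ar = 0.165,
                              rate_factor_elnc = 1, rate_factor_plnc = 0.8,
                              element_length = 1000, ar_length = 1000,
                              ars_per_element = 2,
                              stochastic_mix = FALSE) {
  stopifnot(abs(sum(class_mix) - 1) < 1e-9, d_ar >= 0,
            n_coding >= n_lnc + n_chrom)
  cfg <- as.list(environment())
  structure(cfg, class = "simulation_config")
}

rdirichlet1 <- function(n, conc) {
  g <- stats::rgamma(n, shape = conc)
  if (sum(g) == 0) g[sample.int(n, 1)] <- 1
  g / sum(g)
}

#' Random DNA sequence at a target G+C content
#' @param len sequence length (bp).
#' @param gc expected G+C fraction.
#' @return a character string over ACGT.
#' @export
random_dna <- function(len, gc = 0.45) {
  paste(sample(DNA_BASES, len, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

#' Evolve a sequence into an aligned pair at a planted distance
#'
#' Per-site substitution under the model's transition probabilities at
#' branch length `d`; no indels, so the pair is gap-free and its expected
#' mismatch fraction follows the model's closed form (JC69:
#' `p = (3/4)(1 - exp(-4d/3))`).
#'
#' @param sequence reference sequence (ACGT string).
#' @param d planted substitution distance (subs/site).
#' @param model `"JC69"` or `"K80"`.
#' @param kappa transition/transversion rate ratio for K80.
#' @param seed optional seed.
#' @param id,kind,chrom,start,end passed to [aligned_pair()].
#' @return an [aligned_pair()].
#' @export
evolve_pair <- function(sequence, d, model = c("JC69", "K80"), kappa = 2,
                        seed = NULL, id = "element", kind = "locus",
                        chrom = NA_character_, start = NA_real_,
                        end = NA_real_) {
  model <- match.arg(model)
  stopifnot(d >= 0)
  with_seed(seed, {
    chars <- strsplit(toupper(sequence), "")[[1L]]
    P <- if (model == "JC69") {
      e <- exp(-4 * d / 3)
      matrix((1 - e) / 4, 4, 4, dimnames = list(DNA_BASES, DNA_BASES)) +
        diag(e, 4)
    } else {
      # K80 with rate matrix scaled to d subs/site; beta = 1/(kappa + 2)
      b <- d / (kappa + 2)
      e1 <- exp(-4 * b); e2 <- exp(-2 * b * (kappa + 1))
      same <- 0.25 + 0.25 * e1 + 0.5 * e2
      ts <- 0.25 + 0.25 * e1 - 0.5 * e2
      tv <- 0.25 - 0.25 * e1
      m <- matrix(tv, 4, 4, dimnames = list(DNA_BASES, DNA_BASES))
      diag(m) <- same
      m["A", "G"] <- m["G", "A"] <- m["C", "T"] <- m["T", "C"] <- ts
      m
    }
    out <- chars
    idx <- chars %in% DNA_BASES
    for (b in DNA_BASES) {
      at <- which(idx & chars == b)
      if (length(at))
        out[at] <- sample(DNA_BASES, length(at), replace = TRUE,
                          prob = P[b, ])
    }
    aligned_pair(id, sequence, paste(out, collapse = ""), kind = kind,
                 chrom = chrom, start = start, end = end)
  })
}

#' Sample 5'-tag positions around a TSS
#'
#' @param tss 0-based TSS position.
#' @param n_reads number of tags.
#' @param jitter_sd discretised normal jitter sd (bp); 0 puts every tag at
#'   the TSS.
#' @param chrom_length positions are clipped into `[0, chrom_length)`.
#' @return integer vector of tag positions (length `n_reads`).
#' @export
sample_cage_tags <- function(tss, n_reads, jitter_sd, chrom_length) {
  if (n_reads <= 0) return(integer())
  pos <- tss + round(stats::rnorm(n_reads, 0, jitter_sd))
  pmax(0, pmin(chrom_length - 1, pos))
}

#' Simulate H3K4me1/H3K4me3 coverage tracks over planted TIRs
#'
#' Each locus receives an expected `chip_depth` reads split between the
#' marks by its class ratio, spread over a smoothed triangular profile
#' across +-1 kb of the TSS in 50-bp bins, with Poisson noise per bin.
#'
#' @param loci `data.table` with chrom, tss, class (values `enhancer` /
#'   `promoter` select the ratio).
#' @param config a [simulation_config()].
#' @return list with `me1` and `me3` [chromatin_track()]s.
#' @export
simulate_mark_tracks <- function(loci, config) {
  bin <- 50; half <- 1000
  offs <- seq(-half, half - bin, by = bin)
  w <- 1 - abs(offs + bin / 2) / half
  w <- w / sum(w)
  rows1 <- vector("list", nrow(loci)); rows3 <- rows1
  for (i in seq_len(nrow(loci))) {
    r <- if (loci$class[i] == "enhancer") config$ratio_enh
         else config$ratio_prom
    share1 <- r[1] / sum(r)
    starts <- loci$tss[i] + offs
    ok <- starts >= 0
    v1 <- stats::rpois(sum(ok), config$chip_depth * share1 * w[ok])
    v3 <- stats::rpois(sum(ok), config$chip_depth * (1 - share1) * w[ok])
    rows1[[i]] <- data.table::data.table(chrom = loci$chrom[i],
                                         start = starts[ok],
                                         end = starts[ok] + bin, value = v1)
    rows3[[i]] <- data.table::data.table(chrom = loci$chrom[i],
                                         start = starts[ok],
                                         end = starts[ok] + bin, value = v3)
  }
  cov1 <- data.table::rbindlist(rows1)
  cov3 <- data.table::rbindlist(rows3)
  # collapse duplicated bins from nearby loci
  cov1 <- cov1[, list(value = sum(value)), by = c("chrom", "start", "end")]
  cov3 <- cov3[, list(value = sum(value)), by = c("chrom", "start", "end")]
  list(me1 = chromatin_track(cov1[value > 0], "H3K4me1",
                             max(1, sum(cov1$value))),
       me3 = chromatin_track(cov3[value > 0], "H3K4me3",
                             max(1, sum(cov3$value))))
}

#' Simulate tissue-panel and stage expression matrices
#'
#' Tissue panel: per-locus total abundance is log-normal; tissue shares are
#' Dirichlet with a class-dependent concentration (low concentration =
#' tissue-restricted, emulating the restricted expression of
#' enhancer-associated lncRNAs). Stage series (3 stages): each elncRNA's
#' nearest gene tracks the lncRNA's stage profile with planted coupling
#' `alpha_elnc`; plncRNA neighbours are uncoupled.
#'
#' @param truth truth table from [simulate_bundle()] (`$truth$loci` shape).
#' @param config a [simulation_config()].
#' @return list with `tissue` and `stage` matrices (loci x conditions).
#' @export
simulate_expression <- function(truth, config) {
  ids <- truth$id
  n <- length(ids)
  conc <- ifelse(truth$type == "coding", config$conc_coding,
                 ifelse(truth$class == "elncRNA", config$conc_elnc,
                        config$conc_plnc))
  tissue <- matrix(0, n, config$n_tissues,
                   dimnames = list(ids, paste0("tissue_", seq_len(config$n_tissues))))
  totals <- stats::rlnorm(n, meanlog = 3, sdlog = 1)
  for (i in seq_len(n))
    tissue[i, ] <- totals[i] * rdirichlet1(config$n_tissues, conc[i])

  stage <- matrix(0, n, 3, dimnames = list(ids, c("CFUE", "BFUE", "Ter119")))
  z <- matrix(stats::rnorm(n * 3), n, 3)   # per-locus stage deviations
  idx <- stats::setNames(seq_len(n), ids)
  coupled_genes <- character()
  is_lnc <- truth$type == "lnc"
  for (i in which(is_lnc)) {
    stage[i, ] <- exp(2 + z[i, ])
    g <- truth$neighbor_gene[i]
    if (is.na(g) || !g %in% ids) next
    a <- if (truth$class[i] == "elncRNA") config$alpha_elnc
         else config$alpha_plnc
    gi <- idx[[g]]
    if (a != 0 && !(g %in% coupled_genes)) {
      stage[gi, ] <- exp(3 + a * z[i, ] + stats::rnorm(3, 0, 0.3))
      coupled_genes <- c(coupled_genes, g)
    }
  }
  for (i in which(!is_lnc))
    if (!ids[i] %in% coupled_genes) stage[i, ] <- exp(3 + z[i, ])
  list(tissue = tissue, stage = stage)
}

#' Generate the complete synthetic input bundle
#'
#' Lays out coding genes and intergenic lncRNAs (classes allocated
#' deterministically by default), then generates every pipeline input:
#' 5'-tag positions, DHS peaks, mark bedGraphs, transcript models, TE /
#' CpG-island / pseudogene annotations, tissue and stage expression, and
#' pairwise alignments of TIR elements and neighbouring ancestral repeats
#' evolved at the planted rates. All randomness derives from
#' `config$seed`.
#'
#' @param config a [simulation_config()].
#' @param dir optional directory; when given all inputs are also written as
#'   plain-text files (BED/bedGraph/GTF/TSV/FASTA/JSON) via
#'   [write_bundle()].
#' @return a list of class `sim_bundle` with elements genome, tags, dhs,
#'   tracks, transcripts, coding_genes, te, cpg, pseudogenes,
#'   coding_potential, expression, alignments, and `truth` (the planted
#'   ground-truth table plus the config echo).
#' @export
simulate_bundle <- function(config = simulation_config(), dir = NULL) {
  with_seed(config$seed, {
    genome <- genome_model(paste0("chr", seq_len(config$n_chrom)),
                           rep(config$chrom_length, config$n_chrom))

    # --- layout: alternate coding / lnc slots, coding at both ends -------
    per_chrom_lnc <- diff(round(seq(0, config$n_lnc,
                                    length.out = config$n_chrom + 1)))
    per_chrom_cod <- diff(round(seq(0, config$n_coding,
                                    length.out = config$n_chrom + 1)))
    classes <- rep(c("elncRNA", "plncRNA"),
                   length.out = config$n_lnc)
    if (config$stochastic_mix) {
      classes <- sample(names(config$class_mix), config$n_lnc,
                        replace = TRUE, prob = config$class_mix)
    } else {
      counts <- round(config$class_mix * config$n_lnc)
      counts[1] <- config$n_lnc - sum(counts[-1])
      classes <- rep(names(config$class_mix), counts)
    }
    classes <- sample(classes)   # shuffle genomic placement of classes
    loci <- list(); li <- 0L; ci <- 0L
    for (ch in seq_len(config$n_chrom)) {
      nl <- per_chrom_lnc[ch]; nc <- per_chrom_cod[ch]
      kinds <- character(nl + nc)
      # every lncRNA sits between two coding genes (requires nc >= nl + 1)
      pos_l <- if (nl > 0) seq(2L, by = 2L, length.out = nl) else integer()
      kinds[] <- "coding"; kinds[pos_l] <- "lnc"
      spacing <- config$chrom_length / (nl + nc + 1)
      for (s in seq_along(kinds)) {
        center <- round(spacing * s)
        strand <- sample(c("+", "-"), 1L)
        if (kinds[s] == "coding") {
          ci <- ci + 1L
          span <- 4000
          loci[[length(loci) + 1L]] <- data.table::data.table(
            id = sprintf("gene_%03d", ci), type = "coding",
            class = NA_character_, chrom = genome$chrom_names[ch],
            start = center - span / 2, end = center + span / 2,
            strand = strand)
        } else {
          li <- li + 1L
          span <- 800
          loci[[length(loci) + 1L]] <- data.table::data.table(
            id = sprintf("lnc_%03d", li), type = "lnc",
            class = classes[li], chrom = genome$chrom_names[ch],
            start = center - span / 2, end = center + span / 2,
            strand = strand)
        }
      }
    }
    loci <- data.table::rbindlist(loci)
    loci[, tss := tss_position(start, end, strand)]
    loci[, mono := FALSE]
    loci[type == "lnc", mono := seq_len(.N) %% 2L == 1L]

    # --- exon structure / transcripts -----------------------------------
    ex <- loci[, {
      if (type == "coding") {
        rel_s <- c(0, 1500, 3300); rel_e <- c(400, 1900, 4000)
      } else if (mono) {
        rel_s <- 0; rel_e <- end - start            # mono-exonic
      } else {
        rel_s <- c(0, 500); rel_e <- c(300, 800)    # bi-exonic
      }
      list(transcript_id = paste0(id, ".t1"), gene_id = id,
           chrom = chrom, start = start + rel_s, end = start + rel_e,
           strand = strand)
    }, by = "id"][, -"id"]
    transcripts <- transcript_set(ex)
    coding_potential <- stats::setNames(
      ifelse(loci$type == "coding", "coding", "noncoding"),
      paste0(loci$id, ".t1"))

    # --- tags and DHS ----------------------------------------------------
    loci[, n_reads := stats::rnbinom(.N, mu = config$cage_mean,
                                     size = config$cage_disp)]
    tag_rows <- loci[, {
      p <- sample_cage_tags(tss, n_reads, config$jitter_sd,
                            config$chrom_length)
      if (length(p)) list(chrom = chrom, pos = p, strand = strand)
      else list(chrom = character(), pos = integer(), strand = character())
    }, by = "id"][, -"id"]
    tags <- tag_set(tag_rows$chrom, tag_rows$pos, tag_rows$strand,
                    genome = genome)
    dhs <- gintervals(loci$chrom,
                      pmax(0, loci$tss - config$dhs_width / 2),
                      loci$tss + config$dhs_width / 2,
                      name = paste0("dhs_", loci$id))

    # --- chromatin tracks ------------------------------------------------
    mark_loci <- loci[, list(chrom, tss,
                             class = ifelse(type == "coding", "promoter",
                                            ifelse(class == "elncRNA",
                                                   "enhancer", "promoter")))]
    tracks <- simulate_mark_tracks(mark_loci, config)

    # --- annotations: TE / CpG / pseudogenes -----------------------------
    # TEs cover ~40% of each elncRNA TIR region plus random background
    te <- list(); cpg <- list()
    for (i in seq_len(nrow(loci))) {
      if (identical(loci$class[i], "elncRNA")) {
        te[[length(te) + 1L]] <- data.table::data.table(
          chrom = loci$chrom[i], start = loci$tss[i] - 60,
          end = loci$tss[i] + 60)
      }
      promoter_like <- loci$type[i] == "coding" ||
        identical(loci$class[i], "plncRNA")
      if (promoter_like && stats::runif(1) < 0.66) {
        cpg[[length(cpg) + 1L]] <- data.table::data.table(
          chrom = loci$chrom[i], start = pmax(0, loci$tss[i] - 150),
          end = loci$tss[i] + 150)
      }
    }
    n_bg <- 50
    te[[length(te) + 1L]] <- data.table::data.table(
      chrom = sample(genome$chrom_names, n_bg, replace = TRUE),
      start = bg <- floor(stats::runif(n_bg, 0, config$chrom_length - 200)),
      end = bg + sample(50:200, n_bg, replace = TRUE))
    te <- data.table::rbindlist(te)
    te <- gintervals(te$chrom, te$start, te$end)
    cpg <- if (length(cpg)) {
      cpg <- data.table::rbindlist(cpg)
      gintervals(cpg$chrom, cpg$start, cpg$end)
    } else gintervals(character(), numeric(), numeric())
    pseudogenes <- gintervals(character(), numeric(), numeric())

    # --- neighbours ------------------------------------------------------
    cg <- loci[type == "coding",
               list(chrom, start, end, name = id, score = 0, strand)]
    pairs <- pair_loci(loci[type == "lnc",
                            list(chrom, start, end, name = id)], cg)
    loci[, neighbor_gene := NA_character_]
    loci[type == "lnc",
         neighbor_gene := pairs$nearest_gene[match(id, pairs$locus)]]
    loci[, coupling_alpha := ifelse(type != "lnc", NA_real_,
                                    ifelse(class == "elncRNA",
                                           config$alpha_elnc,
                                           config$alpha_plnc))]

    # --- expression ------------------------------------------------------
    expression <- simulate_expression(loci, config)

    # --- alignments ------------------------------------------------------
    loci[, rate_factor := ifelse(type != "lnc", NA_real_,
                                 ifelse(class == "elncRNA",
                                        config$rate_factor_elnc,
                                        config$rate_factor_plnc))]
    elements <- list(); ars <- list()
    for (i in which(loci$type == "lnc")) {
      gc <- stats::runif(1, 0.40, 0.50)
      es <- loci$tss[i] - config$element_length / 2
      el <- evolve_pair(random_dna(config$element_length, gc),
                        d = config$d_ar * loci$rate_factor[i],
                        id = paste0(loci$id[i], "_tir"), kind = "TIR",
                        chrom = loci$chrom[i], start = es,
                        end = es + config$element_length)
      elements[[length(elements) + 1L]] <- el
      for (k in seq_len(config$ars_per_element)) {
        as_ <- loci$tss[i] + 5000 * k
        ars[[length(ars) + 1L]] <- evolve_pair(
          random_dna(config$ar_length, gc + stats::runif(1, -0.01, 0.01)),
          d = config$d_ar, id = paste0(loci$id[i], "_ar", k), kind = "AR",
          chrom = loci$chrom[i], start = as_,
          end = as_ + config$ar_length)
      }
    }

    truth <- list(loci = loci[], config = unclass(config))
    bundle <- structure(
      list(genome = genome, tags = tags, dhs = dhs, tracks = tracks,
           transcripts = transcripts, coding_genes = cg, te = te, cpg = cpg,
           pseudogenes = pseudogenes, coding_potential = coding_potential,
           expression = expression,
           alignments = list(elements = elements, ars = ars),
           truth = truth),
      class = "sim_bundle")
    if (!is.null(dir)) write_bundle(bundle, dir)
    bundle
  })
}

#' @export
print.sim_bundle <- function(x, ...) {
  cat("sim_bundle:", nrow(x$truth$loci), "planted loci (",
      sum(x$truth$loci$type == "coding"), "coding,",
      sum(x$truth$loci$type == "lnc"), "lncRNA ),",
      sum(x$tags$count), "tags\n")
  invisible(x)
}

#' Write a synthetic bundle as plain-text files
#'
#' Writes chrom.sizes, tags.bed, dhs.bed, me1/me3 bedGraphs,
#' transcripts.gtf, te.bed, cpg.bed, pseudogenes.bed, coding_genes.bed,
#' coding_potential.tsv, tissue_expression.tsv, stage_expression.tsv,
#' alignments/*.fa and truth.json under `dir`.
#'
#' @param bundle a `sim_bundle`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(dir, ...)
  write_chrom_sizes(bundle$genome, p("chrom.sizes"))
  tg <- data.table::as.data.table(bundle$tags)
  write_bed(gintervals(tg$chrom, tg$pos, tg$pos + 1, score = tg$count,
                       strand = tg$strand), p("tags.bed"))
  write_bed(bundle$dhs, p("dhs.bed"))
  write_bedgraph(bundle$tracks$me1$cov, p("me1.bedgraph"))
  write_bedgraph(bundle$tracks$me3$cov, p("me3.bedgraph"))
  write_gtf(bundle$transcripts, p("transcripts.gtf"))
  write_bed(bundle$te, p("te.bed"))
  write_bed(bundle$cpg, p("cpg.bed"))
  write_bed(bundle$pseudogenes, p("pseudogenes.bed"))
  write_bed(gintervals(bundle$coding_genes$chrom, bundle$coding_genes$start,
                       bundle$coding_genes$end,
                       name = bundle$coding_genes$name,
                       strand = bundle$coding_genes$strand),
            p("coding_genes.bed"))
  data.table::fwrite(
    data.table::data.table(transcript_id = names(bundle$coding_potential),
                           potential = bundle$coding_potential),
    p("coding_potential.tsv"), sep = "\t")
  write_matrix_tsv(bundle$expression$tissue, p("tissue_expression.tsv"))
  write_matrix_tsv(bundle$expression$stage, p("stage_expression.tsv"))
  dir.create(p("alignments"), showWarnings = FALSE)
  all_pairs <- c(bundle$alignments$elements, bundle$alignments$ars)
  for (el in all_pairs)
    write_aligned_pair(el, p("alignments", paste0(el$id, ".fa")))
  data.table::fwrite(data.table::data.table(
    id = vapply(all_pairs, `[[`, character(1), "id"),
    kind = vapply(all_pairs, `[[`, character(1), "kind"),
    chrom = vapply(all_pairs, `[[`, character(1), "chrom"),
    start = vapply(all_pairs, `[[`, numeric(1), "start"),
    end = vapply(all_pairs, `[[`, numeric(1), "end"),
    file = file.path("alignments",
                     paste0(vapply(all_pairs, `[[`, character(1), "id"),
                            ".fa"))),
    p("alignments.tsv"), sep = "\t")
  truth <- bundle$truth
  jsonlite::write_json(
    list(loci = truth$loci,
         config = truth$config[!vapply(truth$config, is.function,
                                       logical(1))],
         library_sizes = list(me1 = bundle$tracks$me1$library_size,
                              me3 = bundle$tracks$me3$library_size)),
    p("truth.json"), auto_unbox = TRUE, digits = NA, na = "null")
  invisible(dir)
}
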