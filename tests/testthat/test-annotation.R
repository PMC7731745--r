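test_that("island statistics match hand counts", {
  st <- cgi_stats("CGCGCGCG")
  expect_equal(st[["gc"]], 1)
  expect_equal(st[["obs_exp"]], 2)  # 4 * 8 / (4 * 4)
  expect_equal(st[["length"]], 8)
})

test_that("CGI detection confines islands to the CG-rich run and re-verifies criteria", {
  set.seed(21)
  at <- function(n) rand_dna(n, c("A", "T"))
  s <- paste0(at(500), island_dna(400), at(500))
  cg <- find_cgis(s)
  expect_equal(nrow(cg), 1L)
  expect_gte(cg$start, 450)
  expect_lte(cg$end, 950)
  expect_lte(cg$start, 500)
  expect_gte(cg$end, 900)
  sub <- substr(s, cg$start + 1, cg$end)
  st <- cgi_stats(sub)
  expect_gt(st[["length"]], 200)
  expect_gte(st[["gc"]], 0.5)
  expect_gte(st[["obs_exp"]], 0.6)

  expect_equal(nrow(find_cgis(at(1000))), 0L)
  expect_equal(nrow(find_cgis(strrep("N", 500))), 0L)
})

test_that("every emitted CGI on fuzzed sequences passes direct re-verification", {
  set.seed(33)
  for (k in 1:15) {
    # random composition with an embedded CpG-rich block half the time
    s <- rand_dna(1500)
    if (k %% 2 == 0) {
      block <- paste(sample(c("CG", "C", "G", "A", "T"), 150, replace = TRUE,
                            prob = c(0.3, 0.2, 0.2, 0.15, 0.15)), collapse = "")
      at <- sample(1000, 1)
      s <- paste0(substr(s, 1, at), block, substr(s, at + 1, 1500))
    }
    cg <- find_cgis(s)
    for (i in seq_len(nrow(cg))) {
      st <- cgi_stats(substr(s, cg$start[i] + 1, cg$end[i]))
      expect_gt(st[["length"]], 200)
      expect_gte(st[["gc"]], 0.5)
      expect_gte(st[["obs_exp"]], 0.6)
      expect_equal(unname(st[["gc"]]), cg$gc_fraction[i])
      expect_equal(unname(st[["obs_exp"]]), cg$obs_exp_cpg[i])
    }
  }
})

test_that("CGI detection agrees with the exhaustive maximal-subinterval oracle on short sequences", {
  set.seed(44)
  mk <- function(core, flank) {
    paste0(rand_dna(flank, c("A", "T")), island_dna(core),
           rand_dna(flank, c("A", "T")))
  }
  for (k in 1:8) {
    s <- mk(core = sample(150:400, 1), flank = sample(150:400, 1))
    got <- find_cgis(s)
    want <- cgi_exhaustive(s)
    if (is.null(want)) {
      expect_equal(nrow(got), 0L)
    } else {
      expect_gt(nrow(got), 0L)
      top <- got[which.max(got$length), ]
      expect_equal(c(top$start, top$end), unname(want))
    }
  }
})

test_that("shores flank islands, clip to bounds, and never double count", {
  sh <- define_shores(data.frame(chrom = "chr1", start = 5000, end = 6000),
                      chrom_lengths = c(chr1 = 20000))
  expect_equal(sh$start, c(3000, 6000))
  expect_equal(sh$end, c(5000, 8000))

  sh2 <- define_shores(data.frame(chrom = "chr1", start = 500, end = 900),
                       chrom_lengths = c(chr1 = 20000))
  expect_equal(sh2$start[1], 0)
  expect_equal(sh2$end[1], 500)

  # two CGIs 1 kb apart: the inter-CGI shore is the single 1 kb gap
  cgis <- data.frame(chrom = "chr1", start = c(5000, 7000), end = c(6000, 8000))
  sh3 <- define_shores(cgis, chrom_lengths = c(chr1 = 30000))
  ir <- IRanges::IRanges(sh3$start + 1, sh3$end)
  expect_equal(sum(IRanges::width(IRanges::reduce(ir))), sum(IRanges::width(ir)))
  gap <- sh3[sh3$start == 6000, ]
  expect_equal(gap$end, 7000)
  expect_equal(sum(sh3$end - sh3$start), 2000 + 1000 + 2000)
})

test_that("feature model places promoter bins and transcription-order features strand-awarely", {
  gm <- structure(list(
    genes = data.frame(gene_id = c("plus", "minus", "mono"),
                       chrom = "chr1",
                       start = c(10000, 8000, 40000),
                       end = c(16000, 10000, 41000),
                       strand = c("+", "-", "+")),
    exons = data.frame(gene_id = c("plus", "plus", "minus", "minus", "mono"),
                       chrom = "chr1",
                       start = c(10000, 14000, 8000, 9500, 40000),
                       end = c(10500, 16000, 8600, 10000, 41000),
                       strand = c("+", "+", "-", "-", "+"),
                       exon_rank = c(1, 2, 2, 1, 1)),
    utr5 = data.frame(gene_id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0)),
    utr3 = data.frame(gene_id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0))), class = "gene_models")
  fm <- build_feature_model(gm)

  p1 <- fm$features$promoter_P1
  plus_p1 <- p1[1]
  expect_equal(GenomicRanges::start(plus_p1) - 1, 9800)
  expect_equal(GenomicRanges::end(plus_p1), 10000)
  # minus-strand gene ending at 10000: promoter at greater coordinates
  minus_p3 <- fm$features$promoter_P3[2]
  expect_equal(GenomicRanges::start(minus_p3) - 1, 11500)
  expect_equal(GenomicRanges::end(minus_p3), 12000)

  # transcription-order first exon of the minus gene is the rightmost one
  fe <- as.data.frame(fm$features$first_exon)
  expect_true(any(fe$start - 1 == 9500 & fe$end == 10000))
  # single-exon gene contributes no introns
  intr <- as.data.frame(fm$features$first_intron)
  expect_equal(nrow(intr), 2L)  # one per multi-exon gene only
})

test_that("DMR category assignment is total and follows the precedence order", {
  gm <- generate_gene_models(small_cfg(seed = 13),
                             generate_genome(small_cfg(seed = 13)))
  fm <- build_feature_model(gm)
  g1 <- gm$genes[1, ]
  tss <- if (g1$strand == "+") g1$start else g1$end - 1

  # a DMR centered 100 bp upstream of the TSS lands in promoter P1
  mid <- if (g1$strand == "+") g1$start - 100 else g1$end + 100
  d <- data.frame(chrom = g1$chrom, start = mid - 50, end = mid + 50)
  expect_equal(as.character(annotate_dmr(d, fm)), "promoter_P1")

  # far away from everything: distal intergenic; unknown chrom warns
  d2 <- data.frame(chrom = "chr99", start = 10, end = 110)
  expect_warning(cat2 <- annotate_dmr(d2, fm), "absent")
  expect_equal(as.character(cat2), "distal_intergenic")

  # promoter wins over intron when both genes overlap the midpoint
  gm2 <- structure(list(
    genes = data.frame(gene_id = c("A", "B"), chrom = "chr1",
                       start = c(10000, 2000), end = c(13000, 30000),
                       strand = "+"),
    exons = data.frame(gene_id = c("A", "A", "B", "B"), chrom = "chr1",
                       start = c(10000, 12000, 2000, 25000),
                       end = c(10300, 13000, 2300, 30000),
                       strand = "+", exon_rank = c(1, 2, 1, 2)),
    utr5 = data.frame(gene_id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0)),
    utr3 = data.frame(gene_id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0))), class = "gene_models")
  fm2 <- build_feature_model(gm2)
  d3 <- data.frame(chrom = "chr1", start = 9850, end = 9950)  # P1 of A, intron of B
  expect_equal(as.character(annotate_dmr(d3, fm2)), "promoter_P1")

  dist <- feature_distribution(annotate_dmr(rbind(d, d3), fm2))
  expect_equal(sum(dist$count), 2L)
  expect_equal(sum(dist$percent), 100)
})

test_that("closest-gene linkage matches the all-pairs oracle on fuzz cases", {
  genes <- data.frame(gene_id = c("gA", "gB"), chrom = "chr1",
                      start = c(1000, 6300), end = c(2000, 9000),
                      strand = c("+", "-"))
  d <- data.frame(chrom = "chr1", start = c(1500, 2300, 100000),
                  end = c(1600, 2400, 100100))
  got <- closest_gene(d, genes)
  expect_equal(got$gene_id, c("gA", "gA", "gB"))
  expect_equal(got$distance, c(0, 300, 91000))

  set.seed(55)
  fuzz_genes <- data.frame(
    gene_id = sprintf("g%02d", 1:20),
    chrom = sample(c("chr1", "chr2"), 20, replace = TRUE),
    start = sample.int(5e4, 20), strand = sample(c("+", "-"), 20, TRUE))
  fuzz_genes$end <- fuzz_genes$start + sample(500:5000, 20, TRUE)
  fuzz_dmrs <- data.frame(
    chrom = sample(c("chr1", "chr2", "chr3"), 200, replace = TRUE),
    start = sample.int(6e4, 200))
  fuzz_dmrs$end <- fuzz_dmrs$start + 100
  got <- closest_gene(fuzz_dmrs, fuzz_genes)
  want <- closest_brute(fuzz_dmrs, fuzz_genes)
  expect_equal(got, want)
  expect_true(all(is.na(got$gene_id[fuzz_dmrs$chrom == "chr3"])))
})

test_that("DMR FASTA export matches the genome slices and round-trips", {
  sim <- cached_sim()
  d <- data.frame(chrom = "chr1", start = c(100, 250), end = c(200, 400),
                  dmr_id = c("d1", "d2"), direction = c("hyper", "hypo"))
  f <- withr::local_tempfile(fileext = ".fa")
  export_dmr_fasta(d, sim$genome, f)
  back <- Biostrings::readDNAStringSet(f)
  expect_equal(length(back), 2L)
  expect_equal(unname(Biostrings::width(back)), c(100L, 150L))
  expect_equal(as.character(back[[1]]),
               as.character(Biostrings::subseq(sim$genome[["chr1"]], 101, 200)))
  expect_match(names(back)[1], "d1\\|chr1:100-200\\|hyper")

  export_dmr_fasta(d[0, ], sim$genome, f)
  expect_equal(length(Biostrings::readDNAStringSet(f)), 0L)
  d_bad <- data.frame(chrom = "chr1", start = -5, end = 50)
  expect_error(export_dmr_fasta(d_bad, sim$genome, f), "bounds")
})

test_that("planted islands are recovered with high interval Jaccard across seeds", {
  jacs <- c()
  for (sd in 1:10) {
    cfg <- sim_config(seed = sd, n_chrom = 1, chrom_length = 1e5,
                      n_genes = 5, n_cgi = 3, n_rrbs_targets = 20, n_dmr = 5)
    g <- generate_genome(cfg)
    cg <- find_cgis(g$genome)
    for (i in seq_len(nrow(g$cgis))) {
      t <- g$cgis[i, ]
      cand <- cg[cg$chrom == t$chrom, ]
      inter <- pmax(0, pmin(cand$end, t$end) - pmax(cand$start, t$start))
      un <- (cand$end - cand$start) + (t$end - t$start) - inter
      jacs <- c(jacs, if (nrow(cand)) max(inter / un) else 0)
    }
  }
  expect_gte(mean(jacs), 0.9)
})
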