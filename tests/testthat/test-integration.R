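test_that("DEG thresholds are strict on both fold change and FDR", {
  tab <- data.frame(gene_id = c("a", "b", "c", "d", "e"),
                    fc = c(2.5, 2.0, 0.4, 3.0, 0.45),
                    fdr = c(0.01, 0.001, 0.04, 0.2, NA))
  expect_message(d <- call_degs(tab), "missing FDR")
  expect_equal(d$direction[d$gene_id == "a"], "up")
  expect_equal(d$direction[d$gene_id == "b"], "ns")   # fc == 2 exactly
  expect_equal(d$direction[d$gene_id == "c"], "down")
  expect_equal(d$direction[d$gene_id == "d"], "ns")   # fdr fails
  expect_false("e" %in% d$gene_id)
  expect_error(call_degs(tab, fc_up = 0.9), "fc_down")
})

test_that("DEG calling from replicates recovers planted truth", {
  sim <- cached_sim()
  d <- call_degs(sim$expression)
  called <- d$gene_id[d$direction != "ns"]
  truth <- sim$truth$degs$gene_id
  sens <- mean(truth %in% called)
  fdr <- if (length(called)) mean(!called %in% truth) else 0
  expect_gte(sens, 0.8)
  expect_lte(fdr, 0.1)
  # planted direction matches the call
  up_truth <- sim$truth$degs$gene_id[sim$truth$degs$log2fc > 0]
  expect_true(all(d$direction[d$gene_id %in% up_truth] %in% c("up", "ns")))
})

test_that("co-different genes are the exact DEG/DMR-linked intersection with consistent quadrants", {
  degs <- data.frame(gene_id = c("g1", "g2", "g3", "g4", "g5", "g6"),
                     fc = c(4, 0.2, 3, 0.3, 1, 5),
                     log2_fc = log2(c(4, 0.2, 3, 0.3, 1, 5)),
                     fdr = c(0.01, 0.01, 0.01, 0.01, 0.5, 0.01),
                     direction = c("up", "down", "up", "down", "ns", "up"))
  links <- data.frame(
    dmr_id = paste0("d", 1:8),
    gene_id = c("g1", "g1", "g2", "g3", "g5", "g7", "g4", "g4"),
    direction = c("hyper", "hypo", "hypo", "hyper", "hyper", "hypo",
                  "hyper", "hyper"),
    delta = c(0.4, -0.1, -0.3, 0.2, 0.5, -0.2, 0.25, 0.35))
  out <- co_different(degs, links)
  # g6 is a DEG without DMR; g5 not a DEG; g7 linked but not detected DEG
  expect_setequal(out$genes$gene_id, c("g1", "g2", "g3", "g4"))
  # g1 takes the direction of the larger |delta| DMR (hyper)
  expect_equal(out$genes$quadrant[out$genes$gene_id == "g1"], "hyper-up")
  expect_equal(out$genes$quadrant[out$genes$gene_id == "g2"], "hypo-down")
  expect_equal(unname(out$quadrant_genes[["hyper-down"]]), 1L)  # g4
  # DMR-level tally keeps every DMR-DEG link
  expect_equal(sum(out$quadrant_dmrs), 6L)
  expect_equal(unname(out$quadrant_dmrs[["hyper-down"]]), 2L)   # both g4 DMRs
})

test_that("fold-change comparison by category uses the exact rank-sum test", {
  links <- data.frame(
    dmr_id = paste0("d", 1:6),
    gene_id = paste0("g", 1:6),
    direction = rep(c("hyper", "hypo"), each = 3),
    delta = c(0.3, 0.3, 0.3, -0.3, -0.3, -0.3),
    category = "first_intron")
  fcs <- data.frame(gene_id = paste0("g", 1:6),
                    log2_fc = c(-2, -1, -1.5, 2, 1, 1.5))
  out <- fold_change_by_category(links, fcs)
  expect_equal(out$p_value, 0.1)  # complete separation, exact two-sided 3v3
  expect_gt(out$median_log2fc_hypo, out$median_log2fc_hyper)
  expect_false(out$significant)

  # identical arms: no difference
  fcs2 <- fcs; fcs2$log2_fc <- rep(c(1, 2, 3), 2)
  out2 <- suppressWarnings(fold_change_by_category(links, fcs2))
  expect_equal(out2$median_log2fc_hyper, out2$median_log2fc_hypo)
  expect_equal(out2$p_value, 1)

  # an arm below min_genes is flagged not testable
  out3 <- fold_change_by_category(links[-(1:2), ], fcs)
  expect_false(out3$testable)
  expect_true(is.na(out3$p_value))
})

test_that("TF subsetting intersects detected genes and DEGs", {
  degs <- data.frame(gene_id = c("tf1", "g2"), fc = c(3, 4),
                     log2_fc = log2(c(3, 4)), fdr = c(0.01, 0.01),
                     direction = c("up", "up"))
  detected <- c("tf1", "tf2", "g2", "g3")
  out <- tf_subset(detected, c("tf1", "tf2", "tf9"), degs)
  expect_setequal(out$expressed, c("tf1", "tf2"))
  expect_equal(out$de$gene_id, "tf1")
  expect_warning(out0 <- tf_subset(detected, character(0), degs), "empty")
  expect_equal(length(out0$expressed), 0L)
  out_all <- tf_subset(detected, detected, degs)
  expect_setequal(out_all$expressed, detected)
})

test_that("hypergeometric enrichment matches exact enumeration", {
  uni <- sprintf("u%02d", 1:20)
  query <- uni[1:5]
  paths <- list(setA = uni[c(1, 2, 3, 10)],   # overlap 3 of size 4
                setB = uni[11:14],            # overlap 0
                setC = c("x1", "x2"))         # outside the universe
  out <- ora_enrichment(query, paths, uni)
  expect_false("setC" %in% out$pathway)       # skipped
  expect_equal(out$p_value[out$pathway == "setA"],
               hyper_brute(20, 5, 4, 3), tolerance = 1e-12)
  expect_equal(out$p_value[out$pathway == "setA"], 0.03199174, tolerance = 1e-6)
  expect_equal(out$p_value[out$pathway == "setB"], 1)
  expect_error(ora_enrichment(c(query, "zz"), paths, uni), "zz")

  # exhaustive agreement over small universes
  set.seed(17)
  for (k in 1:25) {
    N <- sample(5:25, 1)
    u <- sprintf("m%02d", seq_len(N))
    q <- sample(u, sample(1:N, 1))
    s <- sample(u, sample(1:N, 1))
    got <- ora_enrichment(q, list(s = s), u)
    expect_equal(got$p_value,
                 hyper_brute(N, length(q), length(s), got$overlap),
                 tolerance = 1e-12)
  }
})

test_that("GMT import feeds enrichment directly", {
  f <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("pathA\tdesc\tg1\tg2\tg3", "pathB\tdesc\tg4\tg5"), f)
  gs <- read_gmt(f)
  expect_equal(sort(names(gs)), c("pathA", "pathB"))
  expect_equal(gs$pathA, c("g1", "g2", "g3"))
  out <- ora_enrichment(c("g1", "g2"), gs, sprintf("g%d", 1:10))
  expect_equal(out$overlap[out$pathway == "pathA"], 2L)
})

test_that("relative qPCR expression follows the ddCt closed form", {
  expect_equal(ddct(25, 20, 24, 20), 0.5)
  expect_equal(ddct(20, 18, 25, 23), 1)
  expect_equal(ddct(20, 19, 25, 23), 2)
  set.seed(2)
  x <- runif(10, 15, 35); y <- runif(10, 15, 35)
  expect_equal(ddct(x, x, y, y), rep(1, 10))
})
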