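test_that("window tiling pools counts per window and applies the CpG minimum", {
  total <- matrix(20, 3, 6)
  meth <- matrix(c(rep(5, 6), rep(10, 6), rep(20, 6)), 3, 6, byrow = TRUE)
  x <- toy_counts(pos = c(10, 50, 120), meth = meth, total = total)

  w1 <- tile_windows(x, width = 100, min_cpgs = 1)
  expect_equal(w1$windows$start, c(0L, 100L))
  expect_equal(w1$windows$n_cpgs, c(2L, 1L))
  # pooled level of the first window: (5 + 10) / 40
  expect_equal(unname(w1$level[1, 1]), 15 / 40)
  # a single-site window reports that site's level
  expect_equal(unname(w1$level[2, 1]), 1)

  w3 <- tile_windows(x, width = 100, min_cpgs = 3)
  expect_equal(nrow(w3$windows), 0L)

  expect_error(tile_windows(x, width = 100, step = 200), "step")
})

test_that("paired t-test matches the closed form and the degenerate-case conventions", {
  r0 <- paired_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r0$t, 0)
  expect_equal(r0$p, 1)

  r <- paired_t_test(c(2, 3, 4), c(1, 1, 1))  # differences 1, 2, 3
  expect_equal(r$t, 2 / (1 / sqrt(3)), tolerance = 1e-10)
  expect_equal(r$df, 2L)
  expect_equal(r$p, 0.0741799, tolerance = 1e-5)

  rz <- paired_t_test(c(2, 2, 2), c(1, 1, 1))  # zero variance, nonzero mean
  expect_equal(rz$p, 0)
  expect_true(is.infinite(rz$t) && rz$t > 0)

  set.seed(12)
  for (k in 1:25) {
    n <- sample(3:8, 1)
    x <- rnorm(n); y <- rnorm(n)
    got <- paired_t_test(x, y)
    ref <- t.test(x, y, paired = TRUE)
    expect_equal(got$t, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(got$p, ref$p.value, tolerance = 1e-10)
  }
})

test_that("BH adjustment matches the step-up definition and validates input", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(0.07, 5)), rep(0.07, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")

  set.seed(3)
  for (k in 1:50) {
    p <- runif(sample(1:60, 1))
    q <- bh_adjust(p)
    expect_equal(q, bh_brute(p))
    expect_true(all(q >= p & q <= 1))
  }
  # order-preserving under permutation
  p <- runif(30)
  perm <- sample(30)
  expect_equal(bh_adjust(p)[perm], bh_adjust(p[perm]))
})

test_that("DMR calling applies both thresholds and orients directions", {
  tab <- data.frame(chrom = "chr1", start = c(0, 100, 200), end = c(100, 200, 300),
                    n_cpgs = 4,
                    delta = c(0.031, 0.02, -0.50),
                    t_stat = c(5, 8, -2),
                    p_value = c(0.001, 0.0001, 0.02),
                    q_value = c(0.04, 0.001, 0.06))
  fit <- structure(list(table = tab, level = matrix(0.5, 3, 6),
                        samples = cached_sim()$counts$samples,
                        groups = c("adipogenic", "myogenic"),
                        mode = "level", n_animals = 3),
                   class = "dmr_fit")
  d <- call_dmrs(fit)
  expect_equal(nrow(d$dmrs), 1L)           # only |delta|>=0.03 AND q<0.05
  expect_equal(d$dmrs$direction, "hyper")
  expect_equal(d$summary$n_hyper + d$summary$n_hypo, d$summary$n_called)
  expect_equal(unname(sum(d$summary$pct)), 100)
})

test_that("the level-mode test recovers planted DMRs and counts mode ranks them first", {
  sim <- cached_sim()
  f <- filter_sites(sim$counts)
  w <- tile_windows(f)

  fit <- dmr_test(w, groups = sim$cfg$groups)
  d <- call_dmrs(fit)
  rec <- dmr_recovery(d, sim$truth$dmrs)
  expect_gte(rec$sensitivity, 0.8)
  expect_lte(rec$fdr, 0.1)

  # normalized-count mode carries the extra depth noise, so it is checked on
  # separation: planted windows sit far below the null p-value distribution
  fitc <- dmr_test(w, mode = "counts", groups = sim$cfg$groups)
  tab <- fitc$table
  is_true <- paste(tab$chrom, tab$start) %in%
    paste(sim$truth$dmrs$chrom, sim$truth$dmrs$start)
  expect_lt(median(tab$p_value[is_true]), median(tab$p_value[!is_true]) / 5)
  expect_gte(mean(tab$p_value[is_true] < 0.1), 0.8)
})

test_that("sample clustering matches exhaustive agglomeration and separates the cell types", {
  # two identical samples merge at height zero
  m <- cbind(a = c(0.1, 0.2), b = c(0.1, 0.2), c = c(0.9, 0.9))
  h <- cluster_samples(m)
  expect_equal(h$height[1], 0)

  # three points with hand-computed average-linkage heights
  m3 <- cbind(x = 0, y = 3, z = 10)
  h3 <- cluster_samples(m3)
  expect_equal(h3$height, c(3, 8.5))  # d(x,y)=3; avg(d(x,z), d(y,z)) = 8.5

  expect_error(cluster_samples(matrix(1, 2, 1)), "2 samples")

  sim <- cached_sim()
  f <- filter_sites(sim$counts)
  w <- tile_windows(f)
  d <- call_dmrs(dmr_test(w, groups = sim$cfg$groups))
  cl <- cutree(cluster_samples(d), k = 2)
  expect_equal(length(unique(cl[d$samples$group == "myogenic"])), 1L)
  expect_equal(length(unique(cl[d$samples$group == "adipogenic"])), 1L)
  expect_false(cl[1] == cl[4])
})

test_that("profile curves are flat on uniform methylation and dip where planted", {
  pos <- seq(0, 19980, by = 60)
  n <- length(pos)
  x <- toy_counts(pos = pos, meth = matrix(10, n, 6), total = matrix(20, n, 6))
  gm <- list(genes = data.frame(gene_id = "g1", chrom = "chr1", start = 6000,
                                end = 12000, strand = "+"))
  mp <- metagene_profile(x, gm)
  expect_true(all(abs(as.matrix(mp[, -(1:3)]) - 0.5) < 1e-12, na.rm = TRUE))

  cp <- cgi_profile(x, data.frame(chrom = "chr1", start = 8000, end = 9000))
  expect_true(all(abs(as.matrix(cp[, -(1:3)]) - 0.5) < 1e-12, na.rm = TRUE))

  # no covered intervals: empty profile with a warning
  gm2 <- list(genes = data.frame(gene_id = "g2", chrom = "chr9", start = 0,
                                 end = 5000, strand = "+"))
  expect_warning(mp2 <- metagene_profile(x, gm2), "empty")
  expect_equal(nrow(mp2), 0L)

  # synthetic study: the TSS-adjacent body bin sits below the mid-body bins
  sim <- cached_sim()
  f <- filter_sites(sim$counts)
  prof <- metagene_profile(f, sim$gene_models)
  body <- prof[prof$zone == "body", -(1:3)]
  first_body <- colMeans(body[1:4, ], na.rm = TRUE)
  mid_body <- colMeans(body[15:26, ], na.rm = TRUE)
  expect_true(all(first_body < mid_body))

  cgi <- cgi_profile(f, sim$truth$cgis)
  inner <- mean(as.matrix(cgi[cgi$zone == "body", -(1:3)]), na.rm = TRUE)
  outer <- mean(as.matrix(cgi[cgi$zone != "body", -(1:3)]), na.rm = TRUE)
  expect_lt(inner, outer)
})
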