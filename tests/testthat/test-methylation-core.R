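test_that("cytosine-report import collapses strands into dyads and validates rows", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chr1\t11\t+\t3\t7\tCpG",
               "chr1\t12\t-\t2\t8\tCpG",
               "chr1\t40\t+\t0\t12\tCHH"), f)
  x <- read_cpg_report(f, sample = "s1")
  expect_equal(nrow(x$sites), 1L)
  expect_equal(x$sites$pos, 10L)     # 0-based dyad position
  expect_equal(as.vector(x$meth), 5)
  expect_equal(as.vector(x$total), 20)
  ctl <- attr(x, "controls")
  expect_equal(ctl$sites$pos, 39L)
  expect_equal(as.vector(ctl$total), 12)

  # without collapsing, the two strand records stay separate
  x2 <- read_cpg_report(f, sample = "s1", collapse = FALSE)
  expect_equal(nrow(x2$sites), 2L)
  expect_equal(sum(x2$total), 20)

  writeLines(character(0), f)
  expect_equal(nrow(read_cpg_report(f)$sites), 0L)

  writeLines("chr1\t11\t*\t3\t7\tCpG", f)
  expect_error(read_cpg_report(f), "strand.*line 1")
  writeLines(c("chr1\t11\t+\t3\t7\tCpG", "chr1\t12\t+\t-1\t7\tCpG"), f)
  expect_error(read_cpg_report(f), "line 2")
})

test_that("cytosine reports round-trip through write and combine", {
  sim <- cached_sim()
  dir <- withr::local_tempdir()
  paths <- write_cpg_report(sim$counts, dir)
  smp <- sim$counts$samples
  xs <- lapply(seq_len(nrow(smp)), function(i)
    read_cpg_report(paths[[smp$sample[i]]], sample = smp$sample[i],
                    animal = smp$animal[i], group = smp$group[i]))
  back <- combine_cpg_counts(xs)
  expect_equal(back$sites, sim$counts$sites)
  expect_equal(unname(back$meth), unname(sim$counts$meth))
  expect_equal(unname(back$total), unname(sim$counts$total))
  ctl0 <- attr(sim$counts, "controls"); ctl1 <- attr(back, "controls")
  expect_equal(sum(ctl1$meth), sum(ctl0$meth))
  expect_equal(sum(ctl1$total), sum(ctl0$total))
})

test_that("site filter enforces strict depth in every sample and the autosome set", {
  total <- rbind(rep(11, 6), c(11, 11, 10, 11, 11, 11), rep(50, 6), rep(12, 6))
  meth <- matrix(0, 4, 6)
  x <- toy_counts(pos = c(10, 20, 30, 40), meth, total)
  x$sites$chrom <- c("chr1", "chr1", "chrX", "chr2")
  expect_warning(out <- filter_sites(x), "chrX")
  expect_equal(out$sites$pos, c(10, 40))   # >10 in all samples, autosomal
  # idempotent
  out2 <- suppressWarnings(filter_sites(out))
  expect_equal(out2$sites, out$sites)
  # empty in, empty out
  e <- toy_counts(integer(0), matrix(0, 0, 6), matrix(0, 0, 6))
  expect_equal(nrow(filter_sites(e)$sites), 0L)
})

test_that("median-of-ratios size factors match closed forms and are scale-equivariant", {
  m <- matrix(rep(c(10, 20, 40), each = 4), ncol = 3)
  expect_equal(unname(size_factors(cbind(m[, 1], m[, 1], m[, 1]))), rep(1, 3))

  two <- cbind(A = c(10, 30, 7), B = c(20, 60, 14))
  sf <- size_factors(two)
  expect_equal(unname(sf[2] / sf[1]), 2)
  expect_equal(unname(sf), c(1 / sqrt(2), sqrt(2)))

  single <- matrix(c(9, 16), nrow = 1)
  g <- sqrt(9 * 16)
  expect_equal(unname(size_factors(single)), c(9 / g, 16 / g))

  # rescaling one sample by c multiplies its factor by c relative to the
  # others (the estimator is defined up to the per-site geometric mean)
  set.seed(77)
  r <- matrix(rpois(60, 40) + 1, ncol = 4)
  base <- size_factors(r)
  r2 <- r; r2[, 3] <- r2[, 3] * 5
  sf2 <- size_factors(r2)
  expect_equal(unname((sf2[3] / sf2[1]) / (base[3] / base[1])), 5)
  expect_equal(unname(sf2[1] / sf2[2]), unname(base[1] / base[2]))
  expect_error(size_factors(matrix(c(0, 1, 1, 0), 2)), "positive")
})

test_that("size factors agree with the DESeq reference estimator", {
  skip_if_not_installed("DESeq2")
  set.seed(5)
  m <- matrix(rpois(300, 60) + 1, ncol = 6)
  expect_equal(unname(size_factors(m)),
               unname(DESeq2::estimateSizeFactorsForMatrix(m)))
})

test_that("conversion-rate estimation is the converted fraction of non-CpG reads", {
  est <- estimate_conversion_rate(list(meth = 5, total = 1000))
  expect_equal(est$pooled, 0.995)
  expect_equal(estimate_conversion_rate(list(meth = 0, total = 500))$pooled, 1)
  expect_true(is.na(estimate_conversion_rate(list(meth = 0, total = 0))$pooled))

  # simulated controls at 99.5% conversion recover the rate tightly
  ctl <- attr(cached_sim()$counts, "controls")
  est <- estimate_conversion_rate(ctl)
  expect_gt(sum(ctl$total), 1e5)
  expect_lt(abs(est$pooled - 0.995), 0.002)
  expect_equal(length(est$per_sample), 6L)
})

test_that("methylation level is the count ratio with missing totals propagated", {
  expect_equal(methylation_level(5, 20), 0.25)
  expect_equal(methylation_level(0, 15), 0)
  expect_equal(methylation_level(15, 15), 1)
  expect_true(is.na(methylation_level(0, 0)))
  expect_error(methylation_level(5, 3), "meth")
})
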