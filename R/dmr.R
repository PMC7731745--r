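#' Tile filtered CpGs into fixed-width windows
#'
#' Windows are tiled per chromosome from position 0 (0-based half-open);
#' windows covering fewer than `min_cpgs` filtered CpGs are discarded. The
#' per-sample window level is the pooled count ratio (sum of methylated
#' over sum of total counts across the window's CpGs).
#'
#' @param x a filtered [cpg_counts] object.
#' @param width window width in bp (default 100).
#' @param step step between window starts; defaults to `width`
#'   (non-overlapping tiles), must satisfy `1 <= step <= width`.
#' @param min_cpgs minimum covered CpGs per window (default 3).
#' @return an object of class `meth_windows`: list with `windows`
#'   (chrom/start/end/n_cpgs), pooled `meth`/`total` matrices, the `level`
#'   matrix, and the `samples` table.
#' @export
tile_windows <- function(x, width = 100L, step = width, min_cpgs = 3L) {
  width <- as.integer(width); step <- as.integer(step)
  if (width < 1L || step < 1L || step > width || min_cpgs < 1L)
    stopf("tile_windows: need width >= 1, 1 <= step <= width, min_cpgs >= 1")
  n <- nrow(x$sites)
  if (n == 0L) {
    win <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), n_cpgs = integer(0))
    emp <- matrix(numeric(0), 0, nrow(x$samples),
                  dimnames = list(NULL, x$samples$sample))
    return(structure(list(windows = win, meth = emp, total = emp,
                          level = emp, samples = x$samples),
                     class = "meth_windows"))
  }
  # window k covers [k*step, k*step + width); a site at p belongs to all k
  # with ceil((p - width + 1)/step) <= k <= floor(p/step)
  p <- x$sites$pos
  kmax <- p %/% step
  kmin <- pmax(0L, as.integer(ceiling((p - width + 1L) / step)))
  reps <- kmax - kmin + 1L
  site_idx <- rep(seq_len(n), reps)
  k <- unlist(lapply(seq_len(n), function(i) seq(kmin[i], kmax[i])))
  key <- paste(x$sites$chrom[site_idx], k)

  meth <- rowsum(x$meth[site_idx, , drop = FALSE], key)
  total <- rowsum(x$total[site_idx, , drop = FALSE], key)
  ncpg <- as.vector(table(key)[rownames(meth)])
  parts <- strsplit(rownames(meth), " ", fixed = TRUE)
  chrom <- vapply(parts, `[`, "", 1L)
  kk <- as.integer(vapply(parts, `[`, "", 2L))
  keep <- ncpg >= min_cpgs
  o <- order(chrom[keep], kk[keep])
  idx <- which(keep)[o]

  win <- data.frame(chrom = chrom[idx], start = kk[idx] * step,
                    end = kk[idx] * step + width, n_cpgs = ncpg[idx])
  rownames(win) <- NULL
  meth <- meth[idx, , drop = FALSE]; total <- total[idx, , drop = FALSE]
  rownames(meth) <- rownames(total) <- NULL
  level <- meth / ifelse(total > 0, total, NA_real_)
  structure(list(windows = win, meth = meth, total = total, level = level,
                 samples = x$samples),
            class = "meth_windows")
}

#' @export
print.meth_windows <- function(x, ...) {
  cat(sprintf("meth_windows: %d windows x %d samples\n",
              nrow(x$windows), nrow(x$samples)))
  invisible(x)
}

#' Paired t-test on per-animal differences
#'
#' Two-sided paired t with `df = n - 1` on the differences `x - y`. The
#' degenerate cases unavoidable at small n are resolved by the t limit:
#' zero variance with a non-zero mean difference gives p = 0 (t signed
#' infinite); zero variance with zero mean gives t = 0, p = 1.
#'
#' @param x,y paired observations (same animal order), length >= 2.
#' @return list with `t`, `df`, `p`.
#' @examples
#' paired_t_test(c(2, 3, 4), c(1, 1, 1))  # differences 1, 2, 3
#' @export
paired_t_test <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2L)
    stopf("paired_t_test: need two equal-length vectors, n >= 2")
  r <- .paired_t_mat(matrix(x - y, nrow = 1L))
  list(t = r$t, df = length(x) - 1L, p = r$p)
}

# vectorized paired t over rows of a difference matrix
.paired_t_mat <- function(d) {
  n <- ncol(d)
  md <- rowMeans(d)
  sdd <- apply(d, 1L, stats::sd)
  t <- ifelse(sdd > 0, md / (sdd / sqrt(n)),
              ifelse(md == 0, 0, sign(md) * Inf))
  p <- ifelse(sdd > 0, 2 * stats::pt(-abs(t), df = n - 1L),
              ifelse(md == 0, 1, 0))
  list(t = t, p = p)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up BH with monotonicity enforcement over one genome-wide family of
#' tested windows (thin validated wrapper over [stats::p.adjust()]).
#'
#' @param p p-values in `[0, 1]`.
#' @return q-values, same order as `p`.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (anyNA(p) || any(p < 0 | p > 1))
    stopf("bh_adjust: p-values must be in [0, 1] with no NA")
  stats::p.adjust(p, method = "BH")
}

#' Windowed paired differential-methylation test
#'
#' Fits the per-window paired t-test between the two groups, pairing the
#' cell types from the same animal, and BH-adjusts the p-values in one
#' genome-wide family. The group difference `delta` (in methylation
#' fraction, second group minus first — myogenic minus adipogenic under the
#' default labels) is always computed from pooled levels, since the
#' "at least 3%" call threshold is a level difference. The test statistic
#' itself can be taken on the pooled levels (default) or on size-factor
#' normalized methylated counts.
#'
#' @param x a `meth_windows` object from [tile_windows()].
#' @param mode `"level"` (default) tests pooled methylation levels;
#'   `"counts"` tests size-factor-normalized methylated counts.
#' @param sf size factors (named per sample) for `mode = "counts"`;
#'   computed from the window totals when omitted.
#' @param groups length-2 character: reference group then the group whose
#'   excess methylation counts as hyper. Defaults to the order of first
#'   appearance in the sample table.
#' @return an object of class `dmr_fit`: the window table with columns
#'   `delta`, `t_stat`, `p_value`, `q_value`, plus the per-sample level
#'   matrix and design metadata.
#' @seealso [call_dmrs()] to threshold the fit into a DMR set.
#' @export
dmr_test <- function(x, mode = c("level", "counts"), sf = NULL, groups = NULL) {
  mode <- match.arg(mode)
  smp <- x$samples
  groups <- groups %||% unique(smp$group)
  if (length(groups) != 2L || !all(smp$group %in% groups))
    stopf("dmr_test: need exactly two groups")
  animals <- unique(smp$animal)
  if (length(animals) < 2L) stopf("dmr_test: need >= 2 animals")
  i1 <- match(paste(groups[1], animals), paste(smp$group, smp$animal))
  i2 <- match(paste(groups[2], animals), paste(smp$group, smp$animal))
  if (anyNA(i1) || anyNA(i2))
    stopf("dmr_test: every animal needs one sample in each group")

  vals <- switch(mode,
    level = x$level,
    counts = {
      sf <- sf %||% size_factors(x$total)
      if (!is.null(names(sf))) sf <- sf[colnames(x$meth)]
      sweep(x$meth, 2L, sf, "/")
    })
  d <- vals[, i2, drop = FALSE] - vals[, i1, drop = FALSE]
  complete <- !apply(is.na(d), 1L, any)
  excluded <- x$windows[!complete, , drop = FALSE]
  if (nrow(excluded))
    message(sprintf("dmr_test: excluding %d window(s) with a missing pair member",
                    nrow(excluded)))

  win <- x$windows[complete, , drop = FALSE]
  level <- x$level[complete, , drop = FALSE]
  delta <- rowMeans(level[, i2, drop = FALSE]) -
           rowMeans(level[, i1, drop = FALSE])
  tt <- .paired_t_mat(d[complete, , drop = FALSE])
  res <- cbind(win, delta = delta, t_stat = tt$t, p_value = tt$p,
               q_value = bh_adjust(tt$p))
  rownames(res) <- NULL
  structure(list(table = res, level = level, samples = smp,
                 groups = groups, mode = mode, n_animals = length(animals),
                 excluded = excluded),
            class = "dmr_fit")
}

#' @export
print.dmr_fit <- function(x, ...) {
  cat(sprintf("Paired windowed methylation test (%s mode)\n", x$mode))
  cat(sprintf("  %d windows tested; %d animals; delta = %s - %s\n",
              nrow(x$table), x$n_animals, x$groups[2], x$groups[1]))
  cat(sprintf("  q < 0.05: %d windows; |delta| >= 0.03 and q < 0.05: %d\n",
              sum(x$table$q_value < 0.05),
              sum(x$table$q_value < 0.05 & abs(x$table$delta) >= 0.03)))
  invisible(x)
}

#' @method summary dmr_fit
#' @export
summary.dmr_fit <- function(object, delta_min = 0.03, q_max = 0.05, ...) {
  tab <- object$table
  called <- abs(tab$delta) >= delta_min & tab$q_value < q_max
  out <- list(n_tested = nrow(tab), n_called = sum(called),
              n_hyper = sum(called & tab$delta > 0),
              n_hypo = sum(called & tab$delta <= 0),
              delta_min = delta_min, q_max = q_max,
              groups = object$groups)
  class(out) <- "summary.dmr_fit"
  out
}

#' @export
print.summary.dmr_fit <- function(x, ...) {
  cat(sprintf("%d windows tested; %d DMRs at |delta| >= %.2f, q < %.2f\n",
              x$n_tested, x$n_called, x$delta_min, x$q_max))
  if (x$n_called > 0) {
    pct <- direction_percentages(x$n_hyper, x$n_hypo)
    cat(sprintf("  hyper in %s: %d (%.1f%%); hypo: %d (%.1f%%)\n",
                x$groups[2], x$n_hyper, pct["hyper"], x$n_hypo, pct["hypo"]))
  }
  invisible(x)
}

#' @method as.data.frame dmr_fit
#' @export
as.data.frame.dmr_fit <- function(x, ...) x$table

#' @method plot dmr_fit
#' @export
plot.dmr_fit <- function(x, delta_min = 0.03, q_max = 0.05, ...) {
  tab <- x$table
  called <- abs(tab$delta) >= delta_min & tab$q_value < q_max
  graphics::plot(tab$delta, -log10(pmax(tab$q_value, 1e-300)),
                 col = ifelse(called, "red3", "grey50"), pch = 20,
                 xlab = sprintf("methylation difference (%s - %s)",
                                x$groups[2], x$groups[1]),
                 ylab = expression(-log[10] ~ q), ...)
  graphics::abline(v = c(-delta_min, delta_min), h = -log10(q_max),
                   lty = 2, col = "grey30")
  invisible(x)
}

#' Hyper/hypo partition percentages
#'
#' @param n_hyper,n_hypo DMR counts in each direction.
#' @return named vector `c(hyper = , hypo = )` of percentages of the total
#'   (they sum to 100).
#' @examples
#' direction_percentages(5372, 5989)  # 47.3 / 52.7 to one decimal
#' @export
direction_percentages <- function(n_hyper, n_hypo) {
  tot <- n_hyper + n_hypo
  if (tot == 0) return(c(hyper = NA_real_, hypo = NA_real_))
  c(hyper = 100 * n_hyper / tot, hypo = 100 * n_hypo / tot)
}

#' Call DMRs from a windowed paired test
#'
#' A window is a DMR iff `|delta| >= delta_min` (3 percentage points by
#' default, absolute) and `q < q_max`. Direction is hyper when the second
#' group's mean level is higher (positive delta).
#'
#' @param fit a `dmr_fit` from [dmr_test()].
#' @param delta_min minimum absolute group difference in methylation
#'   fraction.
#' @param q_max strict upper bound on the BH-adjusted p-value.
#' @return an object of class `dmr_set`: the called window table with a
#'   `direction` column and `dmr_id`, the per-sample level matrix at the
#'   called windows, and a `summary` list (counts and percentages).
#' @export
call_dmrs <- function(fit, delta_min = 0.03, q_max = 0.05) {
  tab <- fit$table
  called <- abs(tab$delta) >= delta_min & tab$q_value < q_max
  out <- tab[called, , drop = FALSE]
  out$direction <- ifelse(out$delta > 0, "hyper", "hypo")
  out <- cbind(dmr_id = sprintf("DMR_%s_%d_%d", out$chrom, out$start, out$end),
               out)
  rownames(out) <- NULL
  n_hyper <- sum(out$direction == "hyper")
  n_hypo <- sum(out$direction == "hypo")
  structure(list(dmrs = out,
                 level = fit$level[called, , drop = FALSE],
                 samples = fit$samples, groups = fit$groups,
                 thresholds = c(delta_min = delta_min, q_max = q_max),
                 summary = list(n_tested = nrow(tab), n_called = nrow(out),
                                n_hyper = n_hyper, n_hypo = n_hypo,
                                pct = direction_percentages(n_hyper, n_hypo))),
            class = "dmr_set")
}

#' @export
print.dmr_set <- function(x, ...) {
  s <- x$summary
  cat(sprintf("dmr_set: %d DMRs from %d tested windows (|delta| >= %.2f, q < %.2f)\n",
              s$n_called, s$n_tested, x$thresholds["delta_min"],
              x$thresholds["q_max"]))
  if (s$n_called > 0)
    cat(sprintf("  hyper in %s: %d (%.1f%%); hypo: %d (%.1f%%)\n",
                x$groups[2], s$n_hyper, s$pct["hyper"], s$n_hypo, s$pct["hypo"]))
  invisible(x)
}

#' @method as.data.frame dmr_set
#' @export
as.data.frame.dmr_set <- function(x, ...) x$dmrs

#' Hierarchical clustering of samples on DMR methylation
#'
#' Agglomerative clustering of the samples using their methylation levels
#' at the called DMRs (Euclidean distance, average linkage by default).
#'
#' @param x a `dmr_set`, or a numeric matrix with one column per sample.
#' @param method linkage passed to [stats::hclust()].
#' @param metric distance passed to [stats::dist()].
#' @return an [stats::hclust] tree over the samples.
#' @export
cluster_samples <- function(x, method = "average", metric = "euclidean") {
  m <- if (inherits(x, "dmr_set")) x$level else as.matrix(x)
  if (ncol(m) < 2L) stopf("cluster_samples: need at least 2 samples")
  stats::hclust(stats::dist(t(m), method = metric), method = method)
}
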