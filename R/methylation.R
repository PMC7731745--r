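#' Per-CpG count container
#'
#' Holds strand-collapsed CpG dyad counts for one or more samples: a site
#' table (chromosome, 0-based forward-strand position of the dyad C), a
#' sample table with animal/group metadata for the paired design, and
#' methylated/total count matrices.
#'
#' @param sites data.frame with columns `chrom`, `pos` (0-based).
#' @param samples data.frame with columns `sample`, `animal`, `group`.
#' @param meth,total integer matrices, sites x samples.
#' @return an object of class `cpg_counts`.
#' @export
cpg_counts <- function(sites, samples, meth, total) {
  meth <- as.matrix(meth); total <- as.matrix(total)
  if (nrow(meth) != nrow(sites) || nrow(total) != nrow(sites) ||
      ncol(meth) != nrow(samples) || ncol(total) != nrow(samples))
    stopf("cpg_counts: dimension mismatch between sites, samples and counts")
  if (nrow(sites) > 0L && (any(meth < 0) || any(meth > total)))
    stopf("cpg_counts: need 0 <= meth <= total")
  colnames(meth) <- colnames(total) <- samples$sample
  structure(list(sites = sites, samples = samples, meth = meth, total = total),
            class = "cpg_counts")
}

#' @export
print.cpg_counts <- function(x, ...) {
  cat(sprintf("cpg_counts: %d CpG dyads x %d samples (%s)\n",
              nrow(x$sites), nrow(x$samples),
              paste(unique(x$samples$group), collapse = " vs ")))
  invisible(x)
}

# row subset preserving the controls attribute
.subset_counts <- function(x, keep) {
  out <- cpg_counts(x$sites[keep, , drop = FALSE], x$samples,
                    x$meth[keep, , drop = FALSE],
                    x$total[keep, , drop = FALSE])
  out$sites <- droplevels(out$sites)
  rownames(out$sites) <- NULL
  attr(out, "controls") <- attr(x, "controls")
  out
}

#' Read a cytosine report (Bismark-like TSV dialect)
#'
#' Expects a header-less TSV with columns chrom, position (1-based), strand,
#' methylated count, unmethylated count, context. CpG-context rows form the
#' count matrix: the minus-strand record of a dyad (position p+1) is merged
#' with the plus-strand record at p into one dyad with summed counts, and
#' positions are converted to 0-based. Rows in any other context are
#' returned as non-CpG conversion controls in the `"controls"` attribute.
#'
#' @param path file path.
#' @param sample sample label (defaults to the file base name).
#' @param animal,group optional design metadata for the sample.
#' @param collapse collapse the two strands of a dyad (default). Set FALSE
#'   for dialects that are already destranded (rows used as-is; plus-strand
#'   coordinate convention).
#' @return a one-sample [cpg_counts] object.
#' @export
read_cpg_report <- function(path, sample = NULL, animal = NA_character_,
                            group = NA_character_, collapse = TRUE) {
  sample <- sample %||% sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  samples <- data.frame(sample = sample, animal = animal, group = group)
  if (length(lines) == 0L)
    return(cpg_counts(data.frame(chrom = character(0), pos = integer(0)),
                      samples,
                      matrix(integer(0), 0, 1), matrix(integer(0), 0, 1)))
  f <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(f)
  if (any(nf < 6L))
    stopf("read_cpg_report: malformed row at line %d (expected 6 columns)",
          which(nf < 6L)[1])
  m <- matrix(unlist(lapply(f, `[`, 1:6)), ncol = 6L, byrow = TRUE)
  pos1 <- suppressWarnings(as.integer(m[, 2]))
  mc <- suppressWarnings(as.numeric(m[, 4]))
  uc <- suppressWarnings(as.numeric(m[, 5]))
  bad <- which(is.na(pos1) | is.na(mc) | is.na(uc) | pos1 < 1L)
  if (length(bad))
    stopf("read_cpg_report: malformed row at line %d", bad[1])
  bad <- which(mc < 0 | uc < 0)
  if (length(bad))
    stopf("read_cpg_report: negative count at line %d", bad[1])
  bad <- which(!m[, 3] %in% c("+", "-"))
  if (length(bad))
    stopf("read_cpg_report: unknown strand '%s' at line %d", m[bad[1], 3], bad[1])

  ctx <- toupper(m[, 6])
  is_cpg <- ctx %in% c("CPG", "CG")
  chrom <- m[, 1]; strand <- m[, 3]

  # dyad position: 0-based position of the forward-strand C
  dyad <- ifelse(strand == "+", pos1 - 1L, pos1 - 2L)
  cp <- data.frame(chrom = chrom[is_cpg], pos = dyad[is_cpg],
                   meth = mc[is_cpg], unmeth = uc[is_cpg])
  if (!collapse) cp$pos <- pos1[is_cpg] - 1L
  if (nrow(cp)) {
    agg <- stats::aggregate(cbind(meth, unmeth) ~ chrom + pos, data = cp, sum)
    agg <- agg[order(agg$chrom, agg$pos), , drop = FALSE]
  } else {
    agg <- data.frame(chrom = character(0), pos = integer(0),
                      meth = numeric(0), unmeth = numeric(0))
  }
  out <- cpg_counts(data.frame(chrom = agg$chrom, pos = as.integer(agg$pos)),
                    samples,
                    matrix(agg$meth, ncol = 1),
                    matrix(agg$meth + agg$unmeth, ncol = 1))
  if (any(!is_cpg)) {
    nc <- data.frame(chrom = chrom[!is_cpg], pos = pos1[!is_cpg] - 1L)
    attr(out, "controls") <- list(
      sites = nc,
      meth = matrix(mc[!is_cpg], ncol = 1, dimnames = list(NULL, sample)),
      total = matrix(mc[!is_cpg] + uc[!is_cpg], ncol = 1,
                     dimnames = list(NULL, sample)))
  }
  out
}

#' Write cytosine reports for each sample of a count object
#'
#' Emits one Bismark-like TSV per sample (destranded: one plus-strand row
#' per dyad, context `CpG`), appending the non-CpG control sites as `CHH`
#' rows when present. [read_cpg_report()] round-trips these files.
#'
#' @param x a [cpg_counts] object.
#' @param dir output directory.
#' @return invisibly, the written file paths (named by sample).
#' @export
write_cpg_report <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ctl <- attr(x, "controls")
  paths <- character(nrow(x$samples))
  for (j in seq_len(nrow(x$samples))) {
    sm <- x$samples$sample[j]
    df <- data.frame(chrom = x$sites$chrom, pos = x$sites$pos + 1L,
                     strand = "+", meth = x$meth[, j],
                     unmeth = x$total[, j] - x$meth[, j], context = "CpG")
    if (!is.null(ctl)) {
      df <- rbind(df, data.frame(
        chrom = ctl$sites$chrom, pos = ctl$sites$pos + 1L, strand = "+",
        meth = ctl$meth[, j], unmeth = ctl$total[, j] - ctl$meth[, j],
        context = "CHH"))
    }
    paths[j] <- file.path(dir, paste0(sm, ".cov.tsv"))
    utils::write.table(df, paths[j], sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  names(paths) <- x$samples$sample
  invisible(paths)
}

#' Merge single-sample count objects into one matrix
#'
#' Takes the union of sites; samples without a record at a site get 0/0
#' counts there (such sites are removed later by [filter_sites()]).
#'
#' @param xs list of [cpg_counts] objects (typically one sample each).
#' @return a combined [cpg_counts]; control counts are merged by position
#'   when every input carries them.
#' @export
combine_cpg_counts <- function(xs) {
  stopifnot(length(xs) >= 1L)
  key <- unique(do.call(rbind, lapply(xs, function(x) x$sites)))
  key <- key[order(key$chrom, key$pos), , drop = FALSE]
  rownames(key) <- NULL
  id <- paste(key$chrom, key$pos)
  k <- sum(vapply(xs, function(x) nrow(x$samples), integer(1)))
  meth <- total <- matrix(0, nrow(key), k)
  samples <- do.call(rbind, lapply(xs, function(x) x$samples))
  col <- 0L
  for (x in xs) {
    idx <- match(paste(x$sites$chrom, x$sites$pos), id)
    for (j in seq_len(nrow(x$samples))) {
      col <- col + 1L
      meth[idx, col] <- x$meth[, j]
      total[idx, col] <- x$total[, j]
    }
  }
  out <- cpg_counts(key, samples, meth, total)
  ctls <- lapply(xs, attr, "controls")
  if (!any(vapply(ctls, is.null, logical(1)))) {
    ck <- unique(do.call(rbind, lapply(ctls, `[[`, "sites")))
    ck <- ck[order(ck$chrom, ck$pos), , drop = FALSE]
    rownames(ck) <- NULL
    cid <- paste(ck$chrom, ck$pos)
    cm <- ct <- matrix(0, nrow(ck), k)
    col <- 0L
    for (i in seq_along(xs)) {
      idx <- match(paste(ctls[[i]]$sites$chrom, ctls[[i]]$sites$pos), cid)
      for (j in seq_len(ncol(ctls[[i]]$meth))) {
        col <- col + 1L
        cm[idx, col] <- ctls[[i]]$meth[, j]
        ct[idx, col] <- ctls[[i]]$total[, j]
      }
    }
    dimnames(cm) <- dimnames(ct) <- list(NULL, samples$sample)
    attr(out, "controls") <- list(sites = ck, meth = cm, total = ct)
  }
  out
}

#' Estimate the bisulfite conversion rate from non-CpG cytosines
#'
#' Non-CpG cytosines are essentially unmethylated, so reads still calling
#' them methylated measure conversion failure: the conversion rate is the
#' converted (unmethylated-called) fraction of non-CpG cytosine reads.
#'
#' @param controls either the `"controls"` attribute of a [cpg_counts]
#'   (list with `meth`/`total` matrices) or a data.frame/list with `meth`
#'   and `total` columns.
#' @return list with `per_sample` (named vector) and `pooled` (scalar);
#'   entries are `NA` where the total is zero.
#' @examples
#' estimate_conversion_rate(list(meth = 5, total = 1000))$pooled  # 0.995
#' @export
estimate_conversion_rate <- function(controls) {
  meth <- as.matrix(controls$meth); total <- as.matrix(controls$total)
  per_tot <- colSums(total); per_meth <- colSums(meth)
  per_sample <- ifelse(per_tot > 0, 1 - per_meth / per_tot, NA_real_)
  names(per_sample) <- colnames(total)
  pooled <- if (sum(per_tot) > 0) 1 - sum(per_meth) / sum(per_tot) else NA_real_
  list(per_sample = per_sample, pooled = pooled)
}

#' Filter CpG sites on depth and autosome membership
#'
#' Keeps sites whose total depth is strictly greater than `min_depth` in
#' every sample and whose chromosome is in the configured autosome set
#' (pig chr1-chr18 by default). Sites on chromosomes outside the set are
#' dropped with a warning listing the excluded chromosome names.
#'
#' @param x a [cpg_counts] object.
#' @param min_depth strict lower bound on per-sample depth (kept iff
#'   depth > min_depth).
#' @param autosomes character vector of allowed chromosome names.
#' @return the filtered [cpg_counts] (site order preserved).
#' @export
filter_sites <- function(x, min_depth = 10L, autosomes = paste0("chr", 1:18)) {
  if (nrow(x$sites) == 0L) return(x)
  on_auto <- x$sites$chrom %in% autosomes
  if (any(!on_auto))
    warning(sprintf("filter_sites: excluding chromosome(s) outside the autosome set: %s",
                    paste(unique(x$sites$chrom[!on_auto]), collapse = ", ")),
            call. = FALSE)
  deep <- rowSums(x$total > min_depth) == ncol(x$total)
  .subset_counts(x, on_auto & deep)
}

#' Median-of-ratios size factors
#'
#' The DESeq estimator applied to per-site total coverage: for each site
#' with all-positive totals, the ratio of each sample's count to the
#' geometric mean across samples; a sample's factor is the median of its
#' ratios.
#'
#' @param x a [cpg_counts] object or a plain count matrix (rows = sites).
#' @return named positive numeric vector, one factor per sample.
#' @export
size_factors <- function(x) {
  m <- if (inherits(x, "cpg_counts")) x$total else as.matrix(x)
  pos <- rowSums(m > 0) == ncol(m)
  if (!any(pos)) stopf("size_factors: no site has positive counts in all samples")
  lm <- log(m[pos, , drop = FALSE])
  lgeo <- rowMeans(lm)
  factors <- exp(apply(lm - lgeo, 2L, stats::median))
  names(factors) <- colnames(m)
  factors
}

#' Methylation level (beta value)
#'
#' @param meth,total methylated and total counts (vectorized).
#' @return `meth/total` in `[0, 1]`; `NA` where `total` is 0.
#' @export
methylation_level <- function(meth, total) {
  if (any(meth > total, na.rm = TRUE) || any(meth < 0, na.rm = TRUE))
    stopf("methylation_level: need 0 <= meth <= total")
  ifelse(total > 0, meth / total, NA_real_)
}
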