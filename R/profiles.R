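# Binned methylation profiles around genes and CpG islands (numeric tables;
# plotting is left to the user).

#' Metagene methylation profile
#'
#' Per sample, averages CpG methylation levels in fixed-bp bins across the
#' upstream flank, scaled gene-body bins, and the downstream flank, first
#' within each gene and then across genes. Minus-strand genes are reversed
#' so bins run in transcription order.
#'
#' @param x a (filtered) [cpg_counts] object.
#' @param gene_models a `gene_models` object (or a list with a `genes`
#'   data.frame chrom/start/end/strand).
#' @param flank flank size in bp on each side (default 2000).
#' @param body_bins,flank_bins number of bins for the scaled gene body and
#'   for each flank.
#' @return data.frame with `bin`, `zone` (upstream/body/downstream), `rel`
#'   (relative coordinate) and one mean-level column per sample; genes
#'   shorter than `body_bins` bp are skipped.
#' @export
metagene_profile <- function(x, gene_models, flank = 2000L, body_bins = 40L,
                             flank_bins = 20L) {
  g <- gene_models$genes
  short <- (g$end - g$start) < body_bins
  if (any(short))
    message(sprintf("metagene_profile: skipping %d gene(s) shorter than %d bp",
                    sum(short), body_bins))
  .binned_profile(x, g[!short, , drop = FALSE], flank, body_bins, flank_bins,
                  stranded = TRUE)
}

#' CpG-island methylation profile
#'
#' As [metagene_profile()], with the island body scaled to a fixed number of
#' bins and the 2 kb shores as flanks (islands are unstranded).
#'
#' @param x a (filtered) [cpg_counts] object.
#' @param cgis data.frame chrom/start/end (e.g. from [find_cgis()]).
#' @param flank,body_bins,flank_bins as in [metagene_profile()].
#' @return as [metagene_profile()].
#' @export
cgi_profile <- function(x, cgis, flank = 2000L, body_bins = 20L,
                        flank_bins = 20L) {
  .binned_profile(x, cgis, flank, body_bins, flank_bins, stranded = FALSE)
}

.binned_profile <- function(x, ivs, flank, body_bins, flank_bins, stranded) {
  nb <- 2L * flank_bins + body_bins
  zone <- rep(c("upstream", "body", "downstream"),
              c(flank_bins, body_bins, flank_bins))
  rel <- c(seq(-flank, 0, length.out = flank_bins + 1L)[-(flank_bins + 1L)],
           seq(0, 1, length.out = body_bins + 1L)[-(body_bins + 1L)],
           seq(1, 1 + flank / max(flank, 1), length.out = flank_bins + 1L)[-1])
  ns <- nrow(x$samples)
  lev <- methylation_level(x$meth, x$total)
  sums <- matrix(0, nb, ns)
  cnts <- matrix(0, nb, ns)
  used <- 0L

  by_chrom <- split(seq_len(nrow(x$sites)), x$sites$chrom)
  bw <- flank / flank_bins
  for (i in seq_len(nrow(ivs))) {
    ch <- ivs$chrom[i]
    idx <- by_chrom[[ch]]
    if (is.null(idx)) next
    p <- x$sites$pos[idx]
    s <- ivs$start[i]; e <- ivs$end[i]
    inr <- p >= s - flank & p < e + flank
    if (!any(inr)) next
    idx <- idx[inr]; p <- p[inr]
    bin <- integer(length(p))
    up <- p < s; dn <- p >= e; bd <- !up & !dn
    bin[up] <- pmin(flank_bins, floor((p[up] - (s - flank)) / bw) + 1L)
    bin[bd] <- flank_bins + pmin(body_bins,
                                 floor((p[bd] - s) / (e - s) * body_bins) + 1L)
    bin[dn] <- flank_bins + body_bins +
      pmin(flank_bins, floor((p[dn] - e) / bw) + 1L)
    if (stranded && !is.null(ivs$strand) && ivs$strand[i] == "-")
      bin <- nb + 1L - bin
    # per-interval bin means, then accumulate across intervals
    lv <- lev[idx, , drop = FALSE]
    for (j in seq_len(ns)) {
      ok <- !is.na(lv[, j])
      if (!any(ok)) next
      bm <- tapply(lv[ok, j], bin[ok], mean)
      bi <- as.integer(names(bm))
      sums[bi, j] <- sums[bi, j] + bm
      cnts[bi, j] <- cnts[bi, j] + 1
    }
    used <- used + 1L
  }
  if (used == 0L) {
    warning("no intervals covered by any CpG; empty profile", call. = FALSE)
    return(data.frame(bin = integer(0), zone = character(0), rel = numeric(0)))
  }
  prof <- sums / ifelse(cnts > 0, cnts, NA_real_)
  colnames(prof) <- x$samples$sample
  cbind(data.frame(bin = seq_len(nb), zone = zone, rel = rel),
        as.data.frame(prof))
}
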