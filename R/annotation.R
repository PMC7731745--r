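#' CpG-island statistics of a sequence
#'
#' Direct counts on one sequence: GC fraction and the observed/expected CpG
#' ratio `(N_CpG * L) / (N_C * N_G)`. N bases are excluded from all counts
#' and from `L`.
#'
#' @param seq character string (or DNAString).
#' @return named vector: `length` (non-N), `gc`, `obs_exp` (`NA` when the
#'   sequence has no C or no G).
#' @examples
#' cgi_stats("CGCGCGCG")  # obs/exp = 4*8/(4*4) = 2
#' @export
cgi_stats <- function(seq) {
  chars <- strsplit(toupper(as.character(seq)), "", fixed = TRUE)[[1]]
  ok <- chars %in% c("A", "C", "G", "T")
  nC <- sum(chars == "C"); nG <- sum(chars == "G")
  L <- sum(ok)
  ncpg <- sum(chars[-length(chars)] == "C" & chars[-1] == "G")
  c(length = L, gc = if (L > 0) (nC + nG) / L else NA_real_,
    obs_exp = if (nC > 0 && nG > 0) ncpg * L / (nC * nG) else NA_real_)
}

#' Detect CpG islands
#'
#' Two-phase scan in the Takai-Jones style of the classical criteria:
#' a 200-bp window slides by 1 bp and is flagged when GC >= 0.5 and
#' observed/expected CpG >= 0.6; overlapping or adjacent flagged windows are
#' merged, and each merged region is trimmed to its maximal sub-region that
#' still satisfies all three criteria (length strictly greater than 200 bp
#' included). Regions failing every trim are discarded. N bases never count.
#'
#' @param genome a named [Biostrings::DNAStringSet], a single sequence, or
#'   the path to a FASTA file.
#' @param min_gc,min_obs_exp,min_length the island criteria.
#' @return data.frame `chrom`, `start`, `end` (0-based half-open), `length`,
#'   `gc_fraction`, `obs_exp_cpg`; every emitted region satisfies all three
#'   criteria when re-verified by direct counting.
#' @export
find_cgis <- function(genome, min_gc = 0.5, min_obs_exp = 0.6,
                      min_length = 200L) {
  genome <- .as_genome(genome)
  out <- lapply(names(genome), function(ch) {
    r <- .find_cgis_chrom(as.character(genome[[ch]]), min_gc, min_obs_exp,
                          min_length)
    if (nrow(r)) cbind(chrom = ch, r) else NULL
  })
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out))
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), length = integer(0),
                      gc_fraction = numeric(0), obs_exp_cpg = numeric(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

.as_genome <- function(genome) {
  if (is.character(genome) && length(genome) == 1L && file.exists(genome))
    genome <- Biostrings::readDNAStringSet(genome)
  if (is.character(genome)) {
    nm <- names(genome) %||% paste0("seq", seq_along(genome))
    genome <- Biostrings::DNAStringSet(genome)
    names(genome) <- nm
  }
  if (methods::is(genome, "DNAString"))
    genome <- Biostrings::DNAStringSet(list(seq1 = genome))
  if (is.list(genome) && !is.null(genome$genome)) genome <- genome$genome
  if (is.null(names(genome)))
    names(genome) <- paste0("seq", seq_along(genome))
  genome
}

.find_cgis_chrom <- function(s, min_gc, min_obs_exp, min_length) {
  empty <- data.frame(start = integer(0), end = integer(0),
                      length = integer(0), gc_fraction = numeric(0),
                      obs_exp_cpg = numeric(0))
  chars <- strsplit(toupper(s), "", fixed = TRUE)[[1]]
  L <- length(chars)
  w <- 200L
  if (L < min_length + 1L) return(empty)
  isC <- chars == "C"; isG <- chars == "G"
  valid <- chars %in% c("A", "C", "G", "T")
  iscpg <- isC & c(isG[-1], FALSE)
  cs <- list(C = c(0, cumsum(isC)), G = c(0, cumsum(isG)),
             V = c(0, cumsum(valid)), P = c(0, cumsum(iscpg)))

  st <- seq_len(L - w + 1L)  # 1-based window starts
  nC <- cs$C[st + w] - cs$C[st]
  nG <- cs$G[st + w] - cs$G[st]
  nV <- cs$V[st + w] - cs$V[st]
  nP <- cs$P[st + w - 1L] - cs$P[st]  # CpG starts within the window
  flag <- nV > 0 & (nC + nG) >= min_gc * nV &
    nC > 0 & nG > 0 & nP * nV / (nC * nG) >= min_obs_exp
  if (!any(flag)) return(empty)

  # merge overlapping/adjacent flagged windows into candidate regions
  fs <- st[flag]
  brk <- c(TRUE, diff(fs) > w)
  grp <- cumsum(brk)
  lo <- tapply(fs, grp, min)
  hi <- tapply(fs, grp, max) + w - 1L  # 1-based inclusive region bounds

  res <- lapply(seq_along(lo), function(i) {
    # pad the candidate by its own span (capped) so the trim is equivalent
    # to the exhaustive maximal passing subinterval around the flagged core
    pad <- min(hi[i] - lo[i] + 1L, 2000L)
    tr <- .max_passing_subregion(cs, max(1L, lo[i] - pad),
                                 min(L, hi[i] + pad), min_gc, min_obs_exp,
                                 min_length)
    if (is.null(tr)) return(NULL)
    a <- tr[1]; b <- tr[2]  # 1-based inclusive
    stats <- .region_stats(cs, a, b)
    data.frame(start = a - 1L, end = b, length = b - a + 1L,
               gc_fraction = stats["gc"], obs_exp_cpg = stats["oe"])
  })
  res <- res[!vapply(res, is.null, logical(1))]
  if (!length(res)) return(empty)
  out <- unique(do.call(rbind, res))  # padded candidates can coincide
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

.region_stats <- function(cs, a, b) {
  nC <- cs$C[b + 1L] - cs$C[a]; nG <- cs$G[b + 1L] - cs$G[a]
  nV <- cs$V[b + 1L] - cs$V[a]; nP <- cs$P[b] - cs$P[a]
  c(gc = if (nV > 0) (nC + nG) / nV else NA_real_,
    oe = if (nC > 0 && nG > 0) nP * nV / (nC * nG) else NA_real_)
}

# maximal (leftmost on ties) subregion of [lo, hi] (1-based inclusive)
# passing all criteria; NULL when none exists
.max_passing_subregion <- function(cs, lo, hi, min_gc, min_obs_exp,
                                   min_length) {
  R <- hi - lo + 1L
  if (R < min_length + 1L) return(NULL)
  for (len in seq(R, min_length + 1L, by = -1L)) {
    a <- seq(lo, hi - len + 1L)
    b <- a + len - 1L
    nC <- cs$C[b + 1L] - cs$C[a]; nG <- cs$G[b + 1L] - cs$G[a]
    nV <- cs$V[b + 1L] - cs$V[a]; nP <- cs$P[b] - cs$P[a]
    ok <- nV > 0 & (nC + nG) >= min_gc * nV & nC > 0 & nG > 0 &
      nP * nV / (nC * nG) >= min_obs_exp
    if (any(ok)) {
      i <- which(ok)[1]
      return(c(a[i], b[i]))
    }
  }
  NULL
}

#' CpG-island shores
#'
#' The 2 kb flanks on each side of every island, clipped to chromosome
#' bounds, with island-overlapping portions removed and overlapping shores
#' merged (no double counting between nearby islands).
#'
#' @param cgis data.frame chrom/start/end (0-based half-open).
#' @param width shore width in bp (default 2000).
#' @param chrom_lengths named vector of chromosome lengths.
#' @return data.frame chrom/start/end of merged shore intervals.
#' @export
define_shores <- function(cgis, width = 2000L, chrom_lengths) {
  out <- lapply(unique(cgis$chrom), function(ch) {
    cg <- cgis[cgis$chrom == ch, , drop = FALSE]
    len <- chrom_lengths[[ch]]
    if (is.null(len) || is.na(len))
      stopf("define_shores: missing length for chromosome %s", ch)
    ir <- IRanges::reduce(IRanges::IRanges(cg$start + 1L, cg$end))
    fl <- c(IRanges::IRanges(pmax(1L, IRanges::start(ir) - width),
                             pmax(0L, IRanges::start(ir) - 1L)),
            IRanges::IRanges(pmin(len + 1L, IRanges::end(ir) + 1L),
                             pmin(len, IRanges::end(ir) + width)))
    fl <- fl[IRanges::width(fl) > 0L]
    sh <- IRanges::setdiff(IRanges::reduce(fl), ir)
    if (length(sh) == 0L) return(NULL)
    data.frame(chrom = ch, start = IRanges::start(sh) - 1L,
               end = IRanges::end(sh))
  })
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out))
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0)))
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Read gene models from GTF/GFF or BED12
#'
#' GTF/GFF (1-based inclusive) is read with rtracklayer and collapsed to one
#' model per gene, taking the longest transcript; exon ranks follow
#' transcription order and UTR records are kept when the file provides them.
#' BED12 gives exon blocks directly (no UTRs). Coordinates are converted to
#' the package's internal 0-based half-open convention.
#'
#' @param path annotation file path (`.gtf`, `.gff`, `.gff3`, or `.bed`).
#' @return a `gene_models` object (see [generate_gene_models()]).
#' @export
read_gene_annotation <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("gtf", "gff", "gff3")) .gene_models_from_gtf(path)
  else if (ext == "bed") .gene_models_from_bed12(path)
  else stopf("read_gene_annotation: unsupported extension '%s'", ext)
}

.gene_models_from_gtf <- function(path) {
  gr <- rtracklayer::import(path)
  typ <- tolower(as.character(gr$type))
  ex <- gr[typ == "exon"]
  if (length(ex) == 0L) stopf("read_gene_annotation: no exon records in %s", path)
  tx_id <- as.character(ex$transcript_id)
  gene_of_tx <- tapply(as.character(ex$gene_id), tx_id, `[`, 1L)
  tx_start <- tapply(GenomicRanges::start(ex), tx_id, min)
  tx_end <- tapply(GenomicRanges::end(ex), tx_id, max)
  tx_len <- tx_end - tx_start + 1L
  # longest transcript per gene; ties broken by transcript id
  ord <- order(gene_of_tx, -tx_len, names(tx_len))
  keep_tx <- names(tx_len)[ord][!duplicated(gene_of_tx[ord])]

  genes <- exons <- utr5 <- utr3 <- list()
  for (tx in keep_tx) {
    e <- ex[tx_id == tx]
    e <- e[order(GenomicRanges::start(e))]
    gid <- as.character(e$gene_id[1])
    ch <- as.character(GenomicRanges::seqnames(e)[1])
    strand <- as.character(GenomicRanges::strand(e)[1])
    if (!strand %in% c("+", "-")) strand <- "+"
    s0 <- min(GenomicRanges::start(e)) - 1L
    e0 <- max(GenomicRanges::end(e))
    if (e0 <= s0) {
      message(sprintf("read_gene_annotation: rejecting gene %s (end <= start)", gid))
      next
    }
    n <- length(e)
    rank <- if (strand == "+") seq_len(n) else rev(seq_len(n))
    genes[[length(genes) + 1L]] <-
      data.frame(gene_id = gid, chrom = ch, start = s0, end = e0,
                 strand = strand)
    exons[[length(exons) + 1L]] <-
      data.frame(gene_id = gid, chrom = ch,
                 start = GenomicRanges::start(e) - 1L,
                 end = GenomicRanges::end(e), strand = strand,
                 exon_rank = rank)
    for (lab in c("five_prime_utr", "three_prime_utr")) {
      u <- gr[typ %in% c(lab, sub("_prime_utr", "utr", lab)) &
                as.character(gr$transcript_id) == tx]
      if (length(u)) {
        df <- data.frame(gene_id = gid, chrom = ch,
                         start = GenomicRanges::start(u) - 1L,
                         end = GenomicRanges::end(u), strand = strand)
        if (lab == "five_prime_utr") utr5[[length(utr5) + 1L]] <- df
        else utr3[[length(utr3) + 1L]] <- df
      }
    }
  }
  .bind_gene_models(genes, exons, utr5, utr3)
}

.gene_models_from_bed12 <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  genes <- exons <- list()
  for (i in seq_along(gr)) {
    gid <- as.character(gr$name[i]) %||% sprintf("gene%04d", i)
    ch <- as.character(GenomicRanges::seqnames(gr)[i])
    strand <- as.character(GenomicRanges::strand(gr)[i])
    if (!strand %in% c("+", "-")) strand <- "+"
    blocks <- if (!is.null(gr$blocks)) gr$blocks[[i]] else
      IRanges::IRanges(1L, GenomicRanges::width(gr)[i])
    abs_s <- GenomicRanges::start(gr)[i] + IRanges::start(blocks) - 2L
    abs_e <- GenomicRanges::start(gr)[i] + IRanges::end(blocks) - 1L
    n <- length(blocks)
    rank <- if (strand == "+") seq_len(n) else rev(seq_len(n))
    genes[[i]] <- data.frame(gene_id = gid, chrom = ch,
                             start = GenomicRanges::start(gr)[i] - 1L,
                             end = GenomicRanges::end(gr)[i], strand = strand)
    exons[[i]] <- data.frame(gene_id = gid, chrom = ch, start = abs_s,
                             end = abs_e, strand = strand, exon_rank = rank)
  }
  .bind_gene_models(genes, exons, list(), list())
}

.bind_gene_models <- function(genes, exons, utr5, utr3) {
  emptyu <- data.frame(gene_id = character(0), chrom = character(0),
                       start = integer(0), end = integer(0),
                       strand = character(0))
  structure(list(genes = do.call(rbind, genes),
                 exons = do.call(rbind, exons),
                 utr5 = if (length(utr5)) do.call(rbind, utr5) else emptyu,
                 utr3 = if (length(utr3)) do.call(rbind, utr3) else emptyu),
            class = "gene_models")
}

#' Write gene models as GTF
#'
#' Emits gene, exon and UTR records (1-based inclusive) that
#' [read_gene_annotation()] round-trips.
#'
#' @param gm a `gene_models` object.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_gene_models_gtf <- function(gm, path) {
  row <- function(ch, type, s0, e0, strand, gid) {
    sprintf("%s\trrbsdmr\t%s\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; transcript_id \"%s.t1\";",
            ch, type, s0 + 1L, e0, strand, gid, gid)
  }
  lines <- character(0)
  g <- gm$genes
  for (i in seq_len(nrow(g))) {
    gid <- g$gene_id[i]
    lines <- c(lines, row(g$chrom[i], "gene", g$start[i], g$end[i],
                          g$strand[i], gid))
    e <- gm$exons[gm$exons$gene_id == gid, , drop = FALSE]
    for (j in seq_len(nrow(e)))
      lines <- c(lines, row(e$chrom[j], "exon", e$start[j], e$end[j],
                            e$strand[j], gid))
    for (part in list(c("utr5", "five_prime_utr"), c("utr3", "three_prime_utr"))) {
      u <- gm[[part[1]]][gm[[part[1]]]$gene_id == gid, , drop = FALSE]
      for (j in seq_len(nrow(u)))
        lines <- c(lines, row(u$chrom[j], part[2], u$start[j], u$end[j],
                              u$strand[j], gid))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

# ordered category labels for DMR feature assignment
.FEATURE_LEVELS <- c("promoter_P1", "promoter_P2", "promoter_P3",
                     "utr5", "utr3", "first_exon", "other_exon",
                     "first_intron", "other_intron", "distal_intergenic")

#' Build the genomic feature model
#'
#' Strand-aware feature intervals per gene: the 2 kb promoter split into
#' bins P1 (TSS to -200), P2 (-200 to -1500) and P3 (-1500 to -2000); 5' and
#' 3' UTRs; first and other exons and introns in transcription order (for
#' minus-strand genes the promoter lies at genomic coordinates greater than
#' the TSS and the first exon is the rightmost); and the gene span
#' (TSS to TTS) used for closest-gene linkage. Positions matching nothing
#' fall in the distal intergenic complement.
#'
#' @param gm a `gene_models` object.
#' @return an object of class `feature_model`.
#' @export
build_feature_model <- function(gm) {
  g <- gm$genes
  bad <- g$end <= g$start
  if (any(bad)) {
    message(sprintf("build_feature_model: rejecting %d gene(s) with end <= start",
                    sum(bad)))
    g <- g[!bad, , drop = FALSE]
  }
  plus <- g$strand == "+"
  p1 <- data.frame(chrom = g$chrom,
                   start = ifelse(plus, g$start - 200L, g$end),
                   end = ifelse(plus, g$start, g$end + 200L))
  p2 <- data.frame(chrom = g$chrom,
                   start = ifelse(plus, g$start - 1500L, g$end + 200L),
                   end = ifelse(plus, g$start - 200L, g$end + 1500L))
  p3 <- data.frame(chrom = g$chrom,
                   start = ifelse(plus, g$start - 2000L, g$end + 1500L),
                   end = ifelse(plus, g$start - 1500L, g$end + 2000L))
  clip <- function(df) {
    df$start <- pmax(df$start, 0L); df[df$end > df$start, , drop = FALSE]
  }
  ex <- gm$exons
  firsts <- ex$exon_rank == 1L
  n_ex <- stats::ave(ex$exon_rank, ex$gene_id, FUN = length)
  intr <- .introns(gm)

  feats <- list(
    promoter_P1 = clip(p1), promoter_P2 = clip(p2), promoter_P3 = clip(p3),
    utr5 = gm$utr5[, c("chrom", "start", "end")],
    utr3 = gm$utr3[, c("chrom", "start", "end")],
    first_exon = ex[firsts, c("chrom", "start", "end")],
    other_exon = ex[!firsts, c("chrom", "start", "end")],
    first_intron = intr[intr$intron_rank == 1L, c("chrom", "start", "end")],
    other_intron = intr[intr$intron_rank > 1L, c("chrom", "start", "end")])
  grl <- lapply(feats, function(df) {
    GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start + 1L, df$end))
  })
  genes_gr <- GenomicRanges::GRanges(
    g$chrom, IRanges::IRanges(g$start + 1L, g$end), gene_id = g$gene_id,
    strand_chr = g$strand)
  structure(list(features = grl, genes = g, genes_gr = genes_gr),
            class = "feature_model")
}

# introns in genomic coordinates with transcription-order ranks
.introns <- function(gm) {
  out <- lapply(split(gm$exons, gm$exons$gene_id), function(e) {
    e <- e[order(e$start), , drop = FALSE]
    n <- nrow(e)
    if (n < 2L) return(NULL)
    strand <- e$strand[1]
    s <- e$end[-n]; en <- e$start[-1]
    keep <- en > s
    if (!any(keep)) return(NULL)
    genomic_idx <- which(keep)
    rank <- if (strand == "+") genomic_idx else n - genomic_idx
    data.frame(gene_id = e$gene_id[1], chrom = e$chrom[1],
               start = s[keep], end = en[keep], strand = strand,
               intron_rank = rank)
  })
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out))
    return(data.frame(gene_id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), intron_rank = integer(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Assign DMRs to genomic feature categories
#'
#' Each DMR is located by its midpoint and receives exactly one category by
#' precedence: promoter P1 > P2 > P3 > 5'UTR > 3'UTR > first exon > other
#' exon > first intron > other intron > distal intergenic.
#'
#' @param dmrs a `dmr_set` or data.frame with chrom/start/end.
#' @param model a `feature_model` from [build_feature_model()].
#' @return factor of categories (levels in precedence order), one per DMR.
#' @export
annotate_dmr <- function(dmrs, model) {
  df <- if (inherits(dmrs, "dmr_set")) dmrs$dmrs else dmrs
  n <- nrow(df)
  cat <- rep("distal_intergenic", n)
  if (n == 0L) return(factor(cat[0], levels = .FEATURE_LEVELS))
  unknown <- !df$chrom %in% as.character(
    GenomicRanges::seqnames(model$genes_gr))
  if (any(unknown) && nrow(model$genes) > 0L)
    warning(sprintf("annotate_dmr: %d DMR(s) on chromosome(s) absent from the model",
                    sum(unknown)), call. = FALSE)
  mid <- (df$start + df$end) %/% 2L
  mid_gr <- GenomicRanges::GRanges(df$chrom,
                                   IRanges::IRanges(mid + 1L, mid + 1L))
  unassigned <- rep(TRUE, n)
  for (lab in names(model$features)) {
    if (!any(unassigned)) break
    # disjoint seqlevels (chromosome absent from the model) already warned above
    hit <- suppressWarnings(IRanges::overlapsAny(mid_gr, model$features[[lab]]))
    take <- unassigned & hit
    cat[take] <- lab
    unassigned[take] <- FALSE
  }
  factor(cat, levels = .FEATURE_LEVELS)
}

#' Link each DMR to its closest gene
#'
#' Distance is 0 when the DMR overlaps the gene span (TSS to TTS), else the
#' bp gap to the nearest span end. Ties are broken by the smaller distance
#' to the TSS, then by lexicographic gene id. Linking never crosses
#' chromosomes: DMRs on a chromosome without genes stay unlinked (`NA`).
#'
#' @param dmrs a `dmr_set` or data.frame with chrom/start/end.
#' @param model a `feature_model`, `gene_models`, or genes data.frame
#'   (gene_id/chrom/start/end/strand).
#' @return data.frame `gene_id`, `distance` (one row per DMR).
#' @export
closest_gene <- function(dmrs, model) {
  df <- if (inherits(dmrs, "dmr_set")) dmrs$dmrs else dmrs
  g <- if (inherits(model, "feature_model")) model$genes
       else if (inherits(model, "gene_models")) model$genes
       else model
  n <- nrow(df)
  out <- data.frame(gene_id = rep(NA_character_, n),
                    distance = rep(NA_real_, n))
  if (n == 0L || nrow(g) == 0L) return(out)
  lev <- union(unique(df$chrom), unique(g$chrom))
  q <- GenomicRanges::GRanges(factor(df$chrom, levels = lev),
                              IRanges::IRanges(df$start + 1L, df$end))
  s <- GenomicRanges::GRanges(factor(g$chrom, levels = lev),
                              IRanges::IRanges(g$start + 1L, g$end))
  tss <- ifelse(g$strand == "+", g$start, g$end - 1L)
  tss_gr <- GenomicRanges::GRanges(factor(g$chrom, levels = lev),
                                   IRanges::IRanges(tss + 1L, tss + 1L))
  hits <- GenomicRanges::distanceToNearest(q, s, select = "all")
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  dd <- S4Vectors::mcols(hits)$distance
  for (i in unique(qh)) {
    cand <- sh[qh == i]
    d <- dd[qh == i][1]
    if (length(cand) > 1L) {
      dtss <- GenomicRanges::distance(rep(q[i], length(cand)), tss_gr[cand])
      cand <- cand[order(dtss, g$gene_id[cand])]
    }
    out$gene_id[i] <- g$gene_id[cand[1]]
    out$distance[i] <- d
  }
  out
}

#' Feature-category distribution of a DMR set
#'
#' @param categories a factor from [annotate_dmr()] (or a `dmr_set` plus a
#'   `model` to annotate on the fly).
#' @param model optional `feature_model` when `categories` is a `dmr_set`.
#' @return data.frame `category`, `count`, `percent`; counts partition the
#'   DMR set and percentages sum to 100 (up to rounding).
#' @export
feature_distribution <- function(categories, model = NULL) {
  if (inherits(categories, "dmr_set"))
    categories <- annotate_dmr(categories, model)
  tab <- table(factor(categories, levels = .FEATURE_LEVELS))
  tot <- sum(tab)
  data.frame(category = names(tab), count = as.integer(tab),
             percent = if (tot > 0) 100 * as.integer(tab) / tot else
               rep(0, length(tab)))
}

#' Export DMR sequences as multi-FASTA
#'
#' One record per DMR; the header encodes coordinates and direction
#' (`dmr_id|chrom:start-end|direction`) and the sequence is the genome
#' slice, suitable as input to external motif-discovery tools.
#'
#' @param dmrs a `dmr_set` or data.frame with chrom/start/end (and
#'   optionally dmr_id/direction).
#' @param genome named [Biostrings::DNAStringSet].
#' @param path output FASTA path.
#' @return invisibly, the written [Biostrings::DNAStringSet].
#' @export
export_dmr_fasta <- function(dmrs, genome, path) {
  df <- if (inherits(dmrs, "dmr_set")) dmrs$dmrs else dmrs
  genome <- .as_genome(genome)
  if (nrow(df) == 0L) {
    writeLines(character(0), path)
    return(invisible(Biostrings::DNAStringSet()))
  }
  if (!all(df$chrom %in% names(genome)))
    stopf("export_dmr_fasta: DMR chromosome absent from genome")
  lens <- Biostrings::width(genome)[match(df$chrom, names(genome))]
  if (any(df$start < 0L | df$end > lens | df$end <= df$start))
    stopf("export_dmr_fasta: DMR coordinates out of genome bounds")
  seqs <- Biostrings::DNAStringSet(vapply(seq_len(nrow(df)), function(i) {
    as.character(Biostrings::subseq(genome[[df$chrom[i]]],
                                    df$start[i] + 1L, df$end[i]))
  }, character(1)))
  id <- df$dmr_id %||% sprintf("DMR_%s_%d_%d", df$chrom, df$start, df$end)
  dir <- df$direction %||% rep(".", nrow(df))
  names(seqs) <- sprintf("%s|%s:%d-%d|%s", id, df$chrom, df$start, df$end, dir)
  Biostrings::writeXStringSet(seqs, path)
  invisible(seqs)
}
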