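#' Generate a synthetic genome with planted CpG islands and MspI targets
#'
#' Builds a CpG-depleted genomic background (most CpGs removed by simulated
#' deamination, as in vertebrate genomes), then plants (i) CpG islands —
#' GC-rich, CpG-retaining segments that satisfy the island criteria used by
#' [find_cgis()] — and (ii) MspI target fragments: CCGG-delimited, CpG-dense
#' segments whose cut-to-cut length falls in the RRBS size-selection range,
#' so that the reduced representation observes a useful set of CpGs.
#' Coordinates are 0-based half-open throughout.
#'
#' @param cfg a [sim_config()] object.
#' @return a list with elements `genome` (a named [Biostrings::DNAStringSet]),
#'   `cgis` (data.frame chrom/start/end of planted islands), and `targets`
#'   (data.frame of planted MspI fragments, with `frag_start`/`frag_end`
#'   giving the cut-to-cut fragment the digest will produce).
#' @examples
#' g <- generate_genome(sim_config(seed = 1, n_chrom = 1, chrom_length = 1e5,
#'                                 n_rrbs_targets = 20, n_cgi = 3, n_genes = 5))
#' names(g$genome)
#' @export
generate_genome <- function(cfg) {
  validate_sim_config(cfg)
  set.seed(stage_seed(cfg$seed, "genome"))
  L <- cfg$chrom_length
  need <- cfg$n_cgi * mean(cfg$cgi_length_range) + cfg$n_rrbs_targets * 300
  if (need > 0.5 * cfg$n_chrom * L)
    stopf("generate_genome: chromosomes too short to host %d CGIs and %d targets",
          cfg$n_cgi, cfg$n_rrbs_targets)

  chroms <- paste0("chr", seq_len(cfg$n_chrom))
  # round-robin allocation of features to chromosomes
  cgi_chrom <- rep(chroms, length.out = cfg$n_cgi)
  tgt_chrom <- rep(chroms, length.out = cfg$n_rrbs_targets)

  seqs <- vector("list", cfg$n_chrom)
  names(seqs) <- chroms
  cgis <- list(); targets <- list()

  for (ci in seq_along(chroms)) {
    chars <- .background_chars(L, cfg$background_gc, cfg$cpg_depletion)
    occ_s <- integer(0); occ_e <- integer(0)

    reserve <- function(len, margin = 300L) {
      for (try in 1:2000) {
        s <- sample.int(L - len - 2L * margin, 1L) + margin
        if (!.overlaps_any(s - margin, s + len + margin, occ_s, occ_e)) {
          occ_s <<- c(occ_s, s); occ_e <<- c(occ_e, s + len)
          return(s)
        }
      }
      stopf("generate_genome: could not place a %d bp feature on %s", len,
            chroms[ci])
    }

    n_c <- sum(cgi_chrom == chroms[ci])
    ins <- 200L  # AT-rich insulator flank giving the island a crisp boundary
    for (k in seq_len(n_c)) {
      len <- sample(seq(cfg$cgi_length_range[1], cfg$cgi_length_range[2]), 1L)
      s <- reserve(len + 2L * ins)
      chars[(s + 1):(s + ins)] <- .insulator_chars(ins)
      chars[(s + ins + 1):(s + ins + len)] <- .cgi_chars(len)
      chars[(s + ins + len + 1):(s + 2L * ins + len)] <- .insulator_chars(ins)
      cgis[[length(cgis) + 1L]] <-
        data.frame(chrom = chroms[ci], start = s + ins, end = s + ins + len)
    }

    n_t <- sum(tgt_chrom == chroms[ci])
    for (k in seq_len(n_t)) {
      cut_len <- sample(230:285, 1L)      # cut-to-cut fragment length
      reg_len <- cut_len + 4L             # CCGG ... CCGG
      s <- reserve(reg_len)
      chars[(s + 1):(s + reg_len)] <- .target_chars(cut_len)
      targets[[length(targets) + 1L]] <-
        data.frame(chrom = chroms[ci], start = s, end = s + reg_len,
                   frag_start = s + 1L, frag_end = s + 1L + cut_len)
    }
    seqs[[ci]] <- paste(chars, collapse = "")
  }

  genome <- Biostrings::DNAStringSet(unlist(seqs))
  names(genome) <- chroms
  cgis <- if (length(cgis)) do.call(rbind, cgis) else
    data.frame(chrom = character(0), start = integer(0), end = integer(0))
  targets <- if (length(targets)) do.call(rbind, targets) else
    data.frame(chrom = character(0), start = integer(0), end = integer(0),
               frag_start = integer(0), frag_end = integer(0))
  o <- order(cgis$chrom, cgis$start); cgis <- cgis[o, , drop = FALSE]
  o <- order(targets$chrom, targets$start); targets <- targets[o, , drop = FALSE]
  rownames(cgis) <- rownames(targets) <- NULL
  list(genome = genome, cgis = cgis, targets = targets)
}

# background with target GC and thinned CpGs; removed CpGs deaminate (C->T)
.background_chars <- function(L, gc, retention) {
  p_cg <- (gc / 2)^2
  gc_adj <- min(0.95, gc + (1 - retention) * p_cg)  # compensate C->T loss
  chars <- sample(c("A", "C", "G", "T"), L, replace = TRUE,
                  prob = c((1 - gc_adj) / 2, gc_adj / 2, gc_adj / 2,
                           (1 - gc_adj) / 2))
  cg <- which(chars[-L] == "C" & chars[-1] == "G")
  if (length(cg)) {
    drop <- cg[stats::runif(length(cg)) > retention]
    chars[drop] <- "T"
  }
  chars
}

# CpG-free AT-rich spacer flanking planted islands; the near-zero GC makes
# flank inclusion maximally costly for the island criteria, so detected
# island boundaries stay close to the planted ones
.insulator_chars <- function(n, gc = 0.05) {
  chars <- sample(c("A", "C", "G", "T"), n, replace = TRUE,
                  prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
  cg <- which(chars[-n] == "C" & chars[-1] == "G")
  chars[cg] <- "T"
  chars
}

# CpG island built from shuffled 21-bp blocks of fixed composition
# (5 C, 6 G, 10 A/T: GC 11/21, just above the criterion). The uniform,
# slightly super-threshold GC keeps the island one contiguous flagged
# region while bounding how much flanking sequence a maximal-subinterval
# island call can absorb (a few percent of the island length), so detected
# boundaries stay close to the planted ones. Re-drawn until the whole
# island passes the three criteria.
.cgi_chars <- function(len) {
  block <- c(rep("C", 5), rep("G", 6), rep(c("A", "T"), length.out = 10))
  nb <- ceiling(len / 21L)
  for (try in 1:100) {
    chars <- unlist(lapply(seq_len(nb), function(i) sample(block)))[1:len]
    st <- cgi_stats(paste(chars, collapse = ""))
    if (len > 200 && st["gc"] >= 0.5 && st["gc"] <= 0.535 &&
        st["obs_exp"] >= 0.65)
      return(chars)
  }
  stopf("could not draw a CGI sequence passing the island criteria")
}

# CCGG + CpG-dense interior + CCGG; no internal CCGG so the digest yields
# exactly one cut-to-cut fragment of length cut_len. The interior is kept
# AT-rich (total GC ~0.40 after CpG planting) so targets stay CpG-dense
# without satisfying the GC >= 0.5 island criterion.
.target_chars <- function(cut_len, gc = 0.28, cpg_period = 12L) {
  ilen <- cut_len - 4L
  chars <- sample(c("A", "C", "G", "T"), ilen, replace = TRUE,
                  prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
  at <- seq(3L, ilen - 1L, by = cpg_period)
  chars[at] <- "C"; chars[at + 1L] <- "G"
  out <- c("C", "C", "G", "G", chars, "C", "C", "G", "G")
  # break accidental CCGG (mutating the first C keeps any planted CpG),
  # but never the two planted cut sites at the ends
  repeat {
    hits <- gregexpr("CCGG", paste(out, collapse = ""), fixed = TRUE)[[1]]
    hits <- as.integer(hits[hits > 0L])
    hits <- setdiff(hits, c(1L, length(out) - 3L))
    if (!length(hits)) break
    out[hits] <- "A"
  }
  out
}

#' In-silico MspI digestion
#'
#' Cuts a sequence at every CCGG occurrence between the first C and CGG
#' (C^CGG), scanning left to right; every occurrence cuts. N bases never
#' match. The returned fragments tile the input exactly.
#'
#' @param x a single sequence: character string, [Biostrings::DNAString], or
#'   a length-one [Biostrings::DNAStringSet].
#' @return data.frame with columns `start`, `end` (0-based half-open) and
#'   `width`; zero rows for an empty sequence.
#' @examples
#' digest_mspi("CCGGAACCGG")  # fragments C | CGGAAC | CGG
#' @export
digest_mspi <- function(x) {
  s <- .as_one_seq(x)
  L <- nchar(s)
  if (L == 0L)
    return(data.frame(start = integer(0), end = integer(0), width = integer(0)))
  hits <- gregexpr("CCGG", s, fixed = TRUE)[[1]]
  cuts <- if (hits[1] == -1L) integer(0) else as.integer(hits)  # cut after C
  bounds <- c(0L, cuts, L)
  data.frame(start = bounds[-length(bounds)], end = bounds[-1],
             width = diff(bounds))
}

.as_one_seq <- function(x) {
  if (methods::is(x, "DNAStringSet")) {
    if (length(x) != 1L) stopf("expected a single sequence")
    x <- x[[1]]
  }
  toupper(as.character(x))
}

#' RRBS size selection
#'
#' Keeps digest fragments whose length lies in the gel size-selection
#' window (225-290 bp by default); these define the observable CpGs.
#'
#' @param fragments data.frame from [digest_mspi()] (columns start/end/width).
#' @param low,high inclusive length bounds in bp.
#' @return the kept rows of `fragments`.
#' @export
size_select <- function(fragments, low = 225L, high = 290L) {
  if (low > high) stopf("size_select: 'low' must not exceed 'high'")
  w <- fragments$width %||% (fragments$end - fragments$start)
  out <- fragments[w >= low & w <= high, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Digest and size-select a whole genome
#'
#' @param genome named [Biostrings::DNAStringSet].
#' @param low,high size-selection bounds passed to [size_select()].
#' @return data.frame chrom/start/end/width of kept fragments.
#' @export
rrbs_fragments <- function(genome, low = 225L, high = 290L) {
  out <- lapply(names(genome), function(ch) {
    fr <- size_select(digest_mspi(genome[[ch]]), low, high)
    if (nrow(fr)) cbind(chrom = ch, fr) else NULL
  })
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out))
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), width = integer(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Generate gene models for the synthetic genome
#'
#' Places non-overlapping multi-exon gene models (random strand) with short
#' terminal UTRs, leaving room for 2 kb promoters. Exon ranks are in
#' transcription order: for minus-strand genes the first exon is the
#' rightmost one.
#'
#' @param cfg a [sim_config()] object.
#' @param genome output of [generate_genome()] (used for chromosome bounds).
#' @return an object of class `gene_models`: list of data.frames `genes`
#'   (gene_id/chrom/start/end/strand), `exons` (with `exon_rank`), `utr5`,
#'   `utr3`; 0-based half-open coordinates.
#' @export
generate_gene_models <- function(cfg, genome) {
  validate_sim_config(cfg)
  set.seed(stage_seed(cfg$seed, "genes"))
  chroms <- names(genome$genome)
  L <- cfg$chrom_length
  gene_chrom <- rep(chroms, length.out = cfg$n_genes)
  genes <- exons <- utr5 <- utr3 <- list()
  occ <- lapply(chroms, function(x) list(s = integer(0), e = integer(0)))
  names(occ) <- chroms

  for (i in seq_len(cfg$n_genes)) {
    ch <- gene_chrom[i]
    len <- sample(2000:8000, 1L)
    placed <- FALSE
    for (try in 1:2000) {
      s <- sample.int(L - len - 5000L, 1L) + 2500L
      if (!.overlaps_any(s - 2500L, s + len + 2500L, occ[[ch]]$s, occ[[ch]]$e)) {
        occ[[ch]]$s <- c(occ[[ch]]$s, s); occ[[ch]]$e <- c(occ[[ch]]$e, s + len)
        placed <- TRUE
        break
      }
    }
    if (!placed) stopf("generate_gene_models: no room left for gene %d on %s", i, ch)
    strand <- sample(c("+", "-"), 1L)
    gid <- sprintf("gene%04d", i)
    genes[[i]] <- data.frame(gene_id = gid, chrom = ch, start = s,
                             end = s + len, strand = strand)

    n_ex <- sample(2:5, 1L)
    ex_len <- sample(100:600, n_ex, replace = TRUE)
    in_len <- sample(200:1500, n_ex - 1L, replace = TRUE)
    tot <- sum(ex_len) + sum(in_len)
    scale <- len / tot
    ex_len <- pmax(50L, as.integer(ex_len * scale))
    in_len <- pmax(50L, as.integer(in_len * scale))
    pos <- s
    ex_s <- ex_e <- integer(n_ex)
    for (k in seq_len(n_ex)) {
      ex_s[k] <- pos; ex_e[k] <- pos + ex_len[k]
      pos <- ex_e[k] + if (k < n_ex) in_len[k] else 0L
    }
    ex_e[n_ex] <- s + len  # last exon ends at the gene end
    rank <- if (strand == "+") seq_len(n_ex) else rev(seq_len(n_ex))
    exons[[i]] <- data.frame(gene_id = gid, chrom = ch, start = ex_s,
                             end = ex_e, strand = strand, exon_rank = rank)
    # terminal UTRs in transcription order
    if (strand == "+") {
      u5l <- min(100L, ex_e[1] - ex_s[1])
      u3l <- min(150L, ex_e[n_ex] - ex_s[n_ex])
      utr5[[i]] <- data.frame(gene_id = gid, chrom = ch, start = ex_s[1],
                              end = ex_s[1] + u5l, strand = strand)
      utr3[[i]] <- data.frame(gene_id = gid, chrom = ch,
                              start = ex_e[n_ex] - u3l, end = ex_e[n_ex],
                              strand = strand)
    } else {
      u5l <- min(100L, ex_e[n_ex] - ex_s[n_ex])
      u3l <- min(150L, ex_e[1] - ex_s[1])
      utr5[[i]] <- data.frame(gene_id = gid, chrom = ch,
                              start = ex_e[n_ex] - u5l, end = ex_e[n_ex],
                              strand = strand)
      utr3[[i]] <- data.frame(gene_id = gid, chrom = ch, start = ex_s[1],
                              end = ex_s[1] + u3l, strand = strand)
    }
  }
  structure(list(genes = do.call(rbind, genes),
                 exons = do.call(rbind, exons),
                 utr5 = do.call(rbind, utr5),
                 utr3 = do.call(rbind, utr3)),
            class = "gene_models")
}

#' @export
print.gene_models <- function(x, ...) {
  cat(sprintf("gene_models: %d genes, %d exons on %d chromosome(s)\n",
              nrow(x$genes), nrow(x$exons), length(unique(x$genes$chrom))))
  invisible(x)
}
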