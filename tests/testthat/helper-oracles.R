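# Independent brute-force oracles used to validate the implementations.

# step-up BH from the definition: sort, p * m / rank, cumulative min
bh_brute <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# character-by-character scan for CCGG cut points
mspi_brute <- function(s) {
  L <- nchar(s)
  cuts <- integer(0)
  i <- 1L
  while (i + 3L <= L) {
    if (substr(s, i, i + 3L) == "CCGG") cuts <- c(cuts, i)
    i <- i + 1L
  }
  bounds <- c(0L, cuts, L)
  data.frame(start = bounds[-length(bounds)], end = bounds[-1],
             width = diff(bounds))
}

# exhaustive maximal passing subinterval over a whole (short) sequence,
# enumerating every (start, length) pair from longest to shortest;
# returns 0-based half-open c(start, end) or NULL
cgi_exhaustive <- function(s, min_gc = 0.5, min_obs_exp = 0.6,
                           min_length = 200L) {
  ch <- strsplit(toupper(s), "", fixed = TRUE)[[1]]
  L <- length(ch)
  if (L < min_length + 1L) return(NULL)
  isC <- ch == "C"; isG <- ch == "G"; ok <- ch %in% c("A", "C", "G", "T")
  cp <- isC & c(isG[-1], FALSE)
  cC <- c(0, cumsum(isC)); cG <- c(0, cumsum(isG))
  cV <- c(0, cumsum(ok)); cP <- c(0, cumsum(cp))
  for (len in seq(L, min_length + 1L, by = -1L)) {
    a <- seq_len(L - len + 1L); b <- a + len - 1L
    nC <- cC[b + 1] - cC[a]; nG <- cG[b + 1] - cG[a]
    nV <- cV[b + 1] - cV[a]; nP <- cP[b] - cP[a]
    pass <- nV > 0 & nC > 0 & nG > 0 & (nC + nG) / nV >= min_gc &
      nP * nV / (nC * nG) >= min_obs_exp
    if (any(pass)) {
      i <- which(pass)[1]
      return(c(a[i] - 1L, b[i]))
    }
  }
  NULL
}

# all-pairs closest gene with the package's tie-break rules
closest_brute <- function(dmrs, genes) {
  out <- data.frame(gene_id = rep(NA_character_, nrow(dmrs)),
                    distance = rep(NA_real_, nrow(dmrs)))
  gap <- function(s1, e1, s2, e2) {
    if (s1 < e2 && e1 > s2) return(0)
    if (e1 <= s2) s2 - e1 else s1 - e2
  }
  for (i in seq_len(nrow(dmrs))) {
    g <- genes[genes$chrom == dmrs$chrom[i], , drop = FALSE]
    if (nrow(g) == 0L) next
    d <- vapply(seq_len(nrow(g)), function(j)
      gap(dmrs$start[i], dmrs$end[i], g$start[j], g$end[j]), numeric(1))
    cand <- which(d == min(d))
    if (length(cand) > 1L) {
      tss <- ifelse(g$strand == "+", g$start, g$end - 1L)
      dtss <- vapply(cand, function(j)
        gap(dmrs$start[i], dmrs$end[i], tss[j], tss[j] + 1L), numeric(1))
      cand <- cand[order(dtss, g$gene_id[cand])]
    }
    out$gene_id[i] <- g$gene_id[cand[1]]
    out$distance[i] <- min(d)
  }
  out
}

# upper-tail hypergeometric by direct enumeration
hyper_brute <- function(N, n_query, K, overlap) {
  ks <- seq(overlap, min(K, n_query))
  sum(choose(K, ks) * choose(N - K, n_query - ks)) / choose(N, n_query)
}

# random DNA string
rand_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# island-like DNA: shuffled 20-bp blocks of fixed composition (GC 0.55)
island_dna <- function(len) {
  block <- c(rep("C", 5), rep("G", 6), rep(c("A", "T"), length.out = 9))
  paste(unlist(lapply(seq_len(ceiling(len / 20)),
                      function(i) sample(block)))[1:len], collapse = "")
}
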