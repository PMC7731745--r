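#' Call differentially expressed genes
#'
#' With raw replicates, the fold change is the ratio of group means (second
#' group over first) and the FDR comes from a two-sided Welch t-test on
#' log2 values with BH adjustment across genes. Tables that already carry
#' `log2_fc`/`fc` and `fdr` columns are thresholded directly. Thresholds are
#' strict: up iff `fc > fc_up` and `fdr < fdr_max`; down iff `fc < fc_down`
#' and `fdr < fdr_max`.
#'
#' @param expr data.frame with `gene_id` plus either `<group>_rep<k>`
#'   replicate columns (linear scale, as written by
#'   [simulate_expression()]) or precomputed `log2_fc` (or `fc`) and `fdr`.
#' @param groups length-2 character (reference first); defaults to the
#'   table's `"groups"` attribute.
#' @param fc_up,fc_down,fdr_max thresholds (fold change > 2 or < 0.5,
#'   FDR < 0.05 by default).
#' @return data.frame `gene_id`, `fc`, `log2_fc`, `fdr`, `direction`
#'   (`up`/`down`/`ns`); genes with missing FDR are excluded with a message.
#' @export
call_degs <- function(expr, groups = NULL, fc_up = 2, fc_down = 0.5,
                      fdr_max = 0.05) {
  if (fc_down >= 1 || fc_up <= 1)
    stopf("call_degs: need fc_down < 1 < fc_up")
  if (all(c("fdr") %in% names(expr)) &&
      any(c("fc", "log2_fc") %in% names(expr))) {
    fc <- if ("fc" %in% names(expr)) expr$fc else 2^expr$log2_fc
    out <- data.frame(gene_id = expr$gene_id, fc = fc, log2_fc = log2(fc),
                      fdr = expr$fdr)
  } else {
    groups <- groups %||% attr(expr, "groups")
    if (is.null(groups) || length(groups) != 2L)
      stopf("call_degs: cannot infer the two group labels; pass 'groups'")
    c1 <- grep(paste0("^", groups[1], "_rep"), names(expr), value = TRUE)
    c2 <- grep(paste0("^", groups[2], "_rep"), names(expr), value = TRUE)
    if (length(c1) < 2L || length(c2) < 2L)
      stopf("call_degs: need >= 2 replicate columns per group")
    m1 <- as.matrix(expr[, c1]); m2 <- as.matrix(expr[, c2])
    if (any(m1 < 0, na.rm = TRUE) || any(m2 < 0, na.rm = TRUE))
      stopf("call_degs: expression values must be non-negative")
    fc <- rowMeans(m2) / rowMeans(m1)
    p <- vapply(seq_len(nrow(expr)), function(i) {
      x <- log2(m2[i, ]); y <- log2(m1[i, ])
      if (stats::sd(x) == 0 && stats::sd(y) == 0)
        return(if (mean(x) == mean(y)) 1 else 0)
      stats::t.test(x, y)$p.value
    }, numeric(1))
    out <- data.frame(gene_id = expr$gene_id, fc = fc, log2_fc = log2(fc),
                      fdr = bh_adjust(p))
  }
  drop <- is.na(out$fdr)
  if (any(drop)) {
    message(sprintf("call_degs: excluding %d gene(s) with missing FDR", sum(drop)))
    out <- out[!drop, , drop = FALSE]
  }
  out$direction <- ifelse(out$fc > fc_up & out$fdr < fdr_max, "up",
                          ifelse(out$fc < fc_down & out$fdr < fdr_max,
                                 "down", "ns"))
  rownames(out) <- NULL
  out
}

#' Co-different genes and methylation-expression quadrants
#'
#' Intersects the DEG set with the DMR-linked genes. Each co-different gene
#' gets a quadrant label from its expression direction and the methylation
#' direction of its linked DMRs (the direction of the largest-|delta| DMR
#' when both directions are linked). DMR-level quadrant counts keep every
#' DMR-DEG link.
#'
#' @param degs output of [call_degs()].
#' @param links data.frame with one row per DMR-gene link: `dmr_id`,
#'   `gene_id`, `direction` (hyper/hypo), `delta`, and optionally
#'   `category`.
#' @return list with `genes` (co-different gene table with `quadrant`),
#'   `quadrant_genes` and `quadrant_dmrs` (named counts over hyper-up,
#'   hypo-up, hyper-down, hypo-down).
#' @export
co_different <- function(degs, links) {
  deg <- degs[degs$direction %in% c("up", "down"), , drop = FALSE]
  links <- links[!is.na(links$gene_id), , drop = FALSE]
  common <- intersect(deg$gene_id, links$gene_id)
  quad_levels <- c("hyper-up", "hypo-up", "hyper-down", "hypo-down")

  rows <- lapply(common, function(g) {
    lk <- links[links$gene_id == g, , drop = FALSE]
    expr_dir <- deg$direction[deg$gene_id == g][1]
    meth_dir <- lk$direction[which.max(abs(lk$delta))]
    data.frame(gene_id = g, expr_direction = expr_dir,
               meth_direction = meth_dir,
               quadrant = paste(meth_dir, expr_dir, sep = "-"),
               n_dmrs = nrow(lk),
               dmr_ids = paste(lk$dmr_id, collapse = ","),
               categories = if (!is.null(lk$category))
                 paste(unique(as.character(lk$category)), collapse = ",")
               else NA_character_,
               log2_fc = deg$log2_fc[deg$gene_id == g][1])
  })
  genes <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene_id = character(0), expr_direction = character(0),
               meth_direction = character(0), quadrant = character(0),
               n_dmrs = integer(0), dmr_ids = character(0),
               categories = character(0), log2_fc = numeric(0))
  genes <- genes[order(genes$gene_id), , drop = FALSE]
  rownames(genes) <- NULL

  lk_deg <- links[links$gene_id %in% common, , drop = FALSE]
  dmr_quad <- paste(lk_deg$direction,
                    deg$direction[match(lk_deg$gene_id, deg$gene_id)],
                    sep = "-")
  list(genes = genes,
       quadrant_genes = table(factor(genes$quadrant, levels = quad_levels)),
       quadrant_dmrs = table(factor(dmr_quad, levels = quad_levels)))
}

#' Compare expression fold changes of hyper- vs hypo-methylated genes
#'
#' For each feature category, splits the genes linked to DMRs of that
#' category into a hyper arm and a hypo arm and compares their log2 fold
#' changes with a two-sided Mann-Whitney rank-sum test (exact for small
#' samples). Categories with fewer than `min_genes` genes in either arm are
#' flagged not testable.
#'
#' @param links DMR-gene link table (`gene_id`, `direction`, `category`).
#' @param expr_fc data.frame with `gene_id` and `log2_fc` (e.g. from
#'   [call_degs()], which reports all detected genes).
#' @param categories categories to test (default: those present).
#' @param min_genes minimum genes per arm (default 3).
#' @return data.frame per category: arm sizes, median log2 FC per arm,
#'   rank-sum `p_value`, `testable`, `significant` (p < 0.05).
#' @export
fold_change_by_category <- function(links, expr_fc, categories = NULL,
                                    min_genes = 3L) {
  links <- links[!is.na(links$gene_id) & !is.na(links$category), , drop = FALSE]
  categories <- categories %||% unique(as.character(links$category))
  out <- lapply(categories, function(cc) {
    lk <- links[as.character(links$category) == cc, , drop = FALSE]
    arm <- function(d) {
      ids <- unique(lk$gene_id[lk$direction == d])
      expr_fc$log2_fc[match(ids, expr_fc$gene_id)]
    }
    hyper <- arm("hyper"); hypo <- arm("hypo")
    hyper <- hyper[!is.na(hyper)]; hypo <- hypo[!is.na(hypo)]
    testable <- length(hyper) >= min_genes && length(hypo) >= min_genes
    p <- if (testable)
      suppressWarnings(stats::wilcox.test(hypo, hyper)$p.value)
    else NA_real_
    data.frame(category = cc, n_hyper = length(hyper), n_hypo = length(hypo),
               median_log2fc_hyper = stats::median(hyper),
               median_log2fc_hypo = stats::median(hypo),
               p_value = p, testable = testable,
               significant = !is.na(p) & p < 0.05)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Transcription-factor subsets
#'
#' @param detected_genes character vector of all detected gene ids.
#' @param tf_names character vector of transcription-factor names, or a
#'   path to a plain-text file with one name per line.
#' @param degs output of [call_degs()].
#' @return list with `expressed` (TFs among detected genes) and `de`
#'   (data.frame of differentially expressed TFs with direction).
#' @export
tf_subset <- function(detected_genes, tf_names, degs) {
  if (length(tf_names) == 1L && file.exists(tf_names))
    tf_names <- readLines(tf_names)
  tf_names <- unique(trimws(tf_names))
  tf_names <- tf_names[nzchar(tf_names)]
  if (length(tf_names) == 0L) {
    warning("tf_subset: empty TF list", call. = FALSE)
    return(list(expressed = character(0),
                de = degs[0, c("gene_id", "fc", "log2_fc", "fdr", "direction")]))
  }
  expressed <- sort(intersect(tf_names, detected_genes))
  de <- degs[degs$gene_id %in% tf_names &
               degs$direction %in% c("up", "down"), , drop = FALSE]
  de <- de[order(de$gene_id), , drop = FALSE]
  rownames(de) <- NULL
  list(expressed = expressed, de = de)
}

#' Read gene sets in GMT format
#'
#' @param path GMT file path.
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) fgsea::gmtPathways(path)

#' Hypergeometric over-representation analysis
#'
#' One-sided upper-tail hypergeometric test, `P(X >= overlap)`, of each
#' pathway against the query within a gene universe, with BH adjustment
#' across pathways. Pathways are intersected with the universe first;
#' pathways left empty are skipped.
#'
#' @param query character vector of genes of interest; must be a subset of
#'   `universe`.
#' @param pathways named list of gene sets (e.g. from [read_gmt()]).
#' @param universe background gene ids (e.g. all detected genes).
#' @param alpha significance threshold applied to `p_value` or `q_value`
#'   per `by`.
#' @param by `"p"` or `"q"`.
#' @return data.frame per pathway: sizes, overlap, `p_value`, `q_value`,
#'   `significant`, sorted by p.
#' @examples
#' ora_enrichment(letters[1:5], list(s = letters[1:4]), letters[1:20])
#' @export
ora_enrichment <- function(query, pathways, universe, alpha = 0.05,
                           by = c("p", "q")) {
  by <- match.arg(by)
  universe <- unique(universe)
  query <- unique(query)
  off <- setdiff(query, universe)
  if (length(off))
    stopf("ora_enrichment: query genes missing from universe: %s",
          paste(utils::head(off, 5), collapse = ", "))
  sets <- lapply(pathways, function(s) intersect(unique(s), universe))
  keep <- lengths(sets) > 0L
  sets <- sets[keep]
  if (!length(sets))
    return(data.frame(pathway = character(0), size = integer(0),
                      overlap = integer(0), p_value = numeric(0),
                      q_value = numeric(0), significant = logical(0)))
  N <- length(universe); n <- length(query)
  K <- lengths(sets)
  ov <- vapply(sets, function(s) length(intersect(s, query)), integer(1))
  p <- stats::phyper(ov - 1L, K, N - K, n, lower.tail = FALSE)
  q <- bh_adjust(p)
  res <- data.frame(pathway = names(sets), size = K, overlap = ov,
                    p_value = p, q_value = q,
                    significant = (if (by == "p") p else q) < alpha)
  res <- res[order(res$p_value, res$pathway), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Relative qPCR expression (2^-ddCt)
#'
#' `2^-[(Ct_target,case - Ct_ref,case) - (Ct_target,ctrl - Ct_ref,ctrl)]`.
#'
#' @param ct_target_case,ct_ref_case,ct_target_ctrl,ct_ref_ctrl Ct values
#'   (vectorized).
#' @return relative expression of the case vs the control condition.
#' @examples
#' ddct(25, 20, 24, 20)  # ddCt = 1 -> 0.5
#' @export
ddct <- function(ct_target_case, ct_ref_case, ct_target_ctrl, ct_ref_ctrl) {
  2^-((ct_target_case - ct_ref_case) - (ct_target_ctrl - ct_ref_ctrl))
}
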