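#' Pipeline configuration
#'
#' Collects every threshold and input of the end-to-end analysis. Exactly
#' one input mode is active: `sim` (a [sim_config()]; the study is
#' simulated) or the real-input paths (`counts_paths` + `sample_table` +
#' `genome_fasta` + `annotation` + `expression`).
#'
#' @param sim a [sim_config()] for simulate mode, or `NULL`.
#' @param counts_paths named character vector of cytosine-report paths (one
#'   per sample) for real-input mode.
#' @param sample_table data.frame `sample`, `animal`, `group` matching
#'   `counts_paths` names.
#' @param genome_fasta,annotation,expression paths to the genome FASTA, the
#'   gene annotation (GTF or BED12) and the expression TSV.
#' @param groups length-2 character, reference group first.
#' @param window_width,window_step,min_cpgs window geometry
#'   (see [tile_windows()]).
#' @param min_depth,autosomes site filters (see [filter_sites()]).
#' @param delta_min,q_max DMR thresholds (see [call_dmrs()]).
#' @param fc_up,fc_down,fdr_max DEG thresholds (see [call_degs()]).
#' @param test_mode `"level"` or `"counts"` (see [dmr_test()]).
#' @param seed integer seed (drives simulate mode).
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = NULL, counts_paths = NULL,
                            sample_table = NULL, genome_fasta = NULL,
                            annotation = NULL, expression = NULL,
                            groups = c("adipogenic", "myogenic"),
                            window_width = 100L, window_step = window_width,
                            min_cpgs = 3L, min_depth = 10L,
                            autosomes = paste0("chr", 1:18),
                            delta_min = 0.03, q_max = 0.05,
                            fc_up = 2, fc_down = 0.5, fdr_max = 0.05,
                            test_mode = c("level", "counts"), seed = 1L) {
  simulate <- !is.null(sim)
  real <- !is.null(counts_paths)
  if (simulate == real)
    stopf("pipeline_config: exactly one of simulate mode ('sim') and real-input mode ('counts_paths' ...) must be set")
  if (real && (is.null(sample_table) || is.null(genome_fasta) ||
               is.null(annotation) || is.null(expression)))
    stopf("pipeline_config: real-input mode needs sample_table, genome_fasta, annotation and expression")
  if (fc_down >= 1 || fc_up <= 1)
    stopf("pipeline_config: need fc_down < 1 < fc_up")
  if (min_depth < 0 || delta_min < 0 || q_max <= 0 || fdr_max <= 0)
    stopf("pipeline_config: thresholds must be positive and consistent")
  structure(list(sim = sim, counts_paths = counts_paths,
                 sample_table = sample_table, genome_fasta = genome_fasta,
                 annotation = annotation, expression = expression,
                 groups = groups, window_width = as.integer(window_width),
                 window_step = as.integer(window_step),
                 min_cpgs = as.integer(min_cpgs),
                 min_depth = as.integer(min_depth), autosomes = autosomes,
                 delta_min = delta_min, q_max = q_max, fc_up = fc_up,
                 fc_down = fc_down, fdr_max = fdr_max,
                 test_mode = match.arg(test_mode), seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' simulate (or read) per-CpG counts, estimate conversion, filter sites,
#' tile windows, run the paired test, call and orient DMRs, detect CpG
#' islands and shores, annotate DMRs and link them to closest genes, call
#' DEGs and co-different genes, and (in simulate mode) score the calls
#' against the planted truth. Per-stage record counts are logged via
#' [message()].
#'
#' @param config a [pipeline_config()].
#' @param outdir optional output directory; when given, the result bundle
#'   is written with [write_outputs()].
#' @return an object of class `rrbs_pipeline` (a list of stage results:
#'   counts, conversion, windows, fit, dmrs, cgis, shores, links, degs,
#'   co-different genes, fold-change comparison, feature distribution, and
#'   a `summary` list; simulate mode adds `truth` and `recovery`).
#' @export
run_pipeline <- function(config, outdir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  }

  if (!is.null(config$sim)) {
    sim <- stage("simulate", {
      cfg <- config$sim
      cfg$seed <- config$seed %||% cfg$seed
      simulate_rrbs(cfg)
    })
    genome <- sim$genome; gm <- sim$gene_models
    counts <- sim$counts; expr <- sim$expression
    truth <- sim$truth
  } else {
    counts <- stage("read_counts", {
      st <- config$sample_table
      xs <- lapply(seq_len(nrow(st)), function(i) {
        read_cpg_report(config$counts_paths[[st$sample[i]]],
                        sample = st$sample[i], animal = st$animal[i],
                        group = st$group[i])
      })
      combine_cpg_counts(xs)
    })
    genome <- stage("read_genome", Biostrings::readDNAStringSet(config$genome_fasta))
    names(genome) <- sub("\\s.*$", "", names(genome))
    gm <- stage("read_annotation", read_gene_annotation(config$annotation))
    expr <- stage("read_expression", {
      e <- utils::read.delim(config$expression, check.names = FALSE)
      attr(e, "groups") <- config$groups
      e
    })
    truth <- NULL
  }
  message(sprintf("[counts] %d CpG dyads x %d samples", nrow(counts$sites),
                  nrow(counts$samples)))

  conversion <- NULL
  if (!is.null(attr(counts, "controls"))) {
    conversion <- estimate_conversion_rate(attr(counts, "controls"))
    message(sprintf("[conversion] pooled estimate %.4f", conversion$pooled))
  }

  filtered <- stage("filter", filter_sites(counts, config$min_depth,
                                           config$autosomes))
  message(sprintf("[filter] %d sites survive depth > %d on autosomes",
                  nrow(filtered$sites), config$min_depth))

  windows <- stage("tile", tile_windows(filtered, config$window_width,
                                        config$window_step, config$min_cpgs))
  message(sprintf("[windows] %d windows with >= %d CpGs",
                  nrow(windows$windows), config$min_cpgs))

  fit <- stage("test", dmr_test(windows, mode = config$test_mode,
                                groups = config$groups))
  dmrs <- stage("call", call_dmrs(fit, config$delta_min, config$q_max))
  message(sprintf("[dmrs] %d called (%d hyper, %d hypo)",
                  dmrs$summary$n_called, dmrs$summary$n_hyper,
                  dmrs$summary$n_hypo))

  cgis <- stage("cgi", find_cgis(genome))
  chrom_lengths <- stats::setNames(Biostrings::width(genome), names(genome))
  shores <- stage("shores", define_shores(cgis, 2000L, chrom_lengths))
  message(sprintf("[cgi] %d islands, %d shore intervals", nrow(cgis),
                  nrow(shores)))

  model <- stage("features", build_feature_model(gm))
  categories <- stage("annotate", annotate_dmr(dmrs, model))
  linked <- stage("closest_gene", closest_gene(dmrs, model))
  links <- cbind(dmrs$dmrs[, c("dmr_id", "chrom", "start", "end", "delta",
                               "direction")],
                 category = as.character(categories), linked)
  featdist <- feature_distribution(categories)

  degs <- stage("degs", call_degs(expr, groups = config$groups,
                                  fc_up = config$fc_up,
                                  fc_down = config$fc_down,
                                  fdr_max = config$fdr_max))
  message(sprintf("[degs] %d of %d genes differentially expressed",
                  sum(degs$direction != "ns"), nrow(degs)))
  codiff <- stage("co_different", co_different(degs, links))
  fc_cat <- stage("fc_by_category", fold_change_by_category(links, degs))

  recovery <- NULL
  if (!is.null(truth))
    recovery <- dmr_recovery(dmrs, truth$dmrs)

  summary <- list(
    n_sites = nrow(counts$sites), n_sites_filtered = nrow(filtered$sites),
    n_windows = nrow(windows$windows), dmr = dmrs$summary,
    conversion = conversion, feature_distribution = featdist,
    n_degs = sum(degs$direction != "ns"),
    n_co_different = nrow(codiff$genes),
    quadrant_genes = codiff$quadrant_genes,
    quadrant_dmrs = codiff$quadrant_dmrs,
    recovery = recovery)

  bundle <- structure(list(config = config, genome = genome,
                           gene_models = gm, counts = counts,
                           conversion = conversion, filtered = filtered,
                           windows = windows, fit = fit, dmrs = dmrs,
                           cgis = cgis, shores = shores, links = links,
                           feature_distribution = featdist, degs = degs,
                           co_different = codiff,
                           fold_change_by_category = fc_cat,
                           truth = truth, recovery = recovery,
                           summary = summary),
                      class = "rrbs_pipeline")
  if (!is.null(outdir)) write_outputs(bundle, outdir)
  bundle
}

#' Score called DMRs against planted truth
#'
#' @param dmrs a `dmr_set` (or data.frame chrom/start/end).
#' @param truth data.frame of planted DMR intervals (chrom/start/end).
#' @return list: `sensitivity` (fraction of planted intervals overlapped by
#'   a called DMR), `fdr` (fraction of called DMRs overlapping no planted
#'   interval; 0 when nothing is called), `n_called`, `n_true`.
#' @export
dmr_recovery <- function(dmrs, truth) {
  df <- if (inherits(dmrs, "dmr_set")) dmrs$dmrs else dmrs
  if (nrow(truth) == 0L)
    return(list(sensitivity = NA_real_,
                fdr = if (nrow(df) > 0) 1 else 0,
                n_called = nrow(df), n_true = 0L))
  if (nrow(df) == 0L)
    return(list(sensitivity = 0, fdr = 0, n_called = 0L,
                n_true = nrow(truth)))
  cg <- GenomicRanges::GRanges(df$chrom,
                               IRanges::IRanges(df$start + 1L, df$end))
  tg <- GenomicRanges::GRanges(truth$chrom,
                               IRanges::IRanges(truth$start + 1L, truth$end))
  list(sensitivity = mean(IRanges::overlapsAny(tg, cg)),
       fdr = mean(!IRanges::overlapsAny(cg, tg)),
       n_called = nrow(df), n_true = nrow(truth))
}

#' @export
print.rrbs_pipeline <- function(x, ...) {
  s <- x$summary
  cat("RRBS differential-methylation pipeline\n")
  cat(sprintf("  sites: %d (%d after filters); windows tested: %d\n",
              s$n_sites, s$n_sites_filtered, s$n_windows))
  cat(sprintf("  DMRs: %d (%d hyper, %d hypo); DEGs: %d; co-different genes: %d\n",
              s$dmr$n_called, s$dmr$n_hyper, s$dmr$n_hypo, s$n_degs,
              s$n_co_different))
  if (!is.null(s$recovery))
    cat(sprintf("  truth recovery: sensitivity %.3f, empirical FDR %.3f\n",
                s$recovery$sensitivity, s$recovery$fdr))
  invisible(x)
}

.write_bed6 <- function(df, path, name, score) {
  bed <- data.frame(chrom = df$chrom, start = df$start, end = df$end,
                    name = name,
                    score = round(pmin(pmax(score, 0), 1000), 3),
                    strand = ".")
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
}

#' Write the pipeline result bundle to disk
#'
#' DMRs, CGIs and shores as 6-column BED (0-based half-open; the DMR score
#' is -log10 q clipped to 0-1000), tables as headered TSV, DMR sequences as
#' multi-FASTA, and a structured-text summary.
#'
#' @param bundle an `rrbs_pipeline` from [run_pipeline()].
#' @param outdir output directory (created if needed).
#' @return invisibly, the vector of written paths.
#' @export
write_outputs <- function(bundle, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  pth <- function(f) file.path(outdir, f)
  d <- bundle$dmrs$dmrs
  .write_bed6(d, pth("dmrs.bed"),
              name = if (nrow(d)) paste(d$dmr_id, d$direction, sep = "|")
                     else character(0),
              score = if (nrow(d)) -log10(pmax(d$q_value, 1e-300)) else numeric(0))
  .write_bed6(bundle$cgis, pth("cgis.bed"),
              name = if (nrow(bundle$cgis))
                sprintf("CGI_%s_%d", bundle$cgis$chrom, bundle$cgis$start)
              else character(0),
              score = rep(0, nrow(bundle$cgis)))
  .write_bed6(bundle$shores, pth("shores.bed"),
              name = if (nrow(bundle$shores))
                sprintf("shore_%s_%d", bundle$shores$chrom,
                        bundle$shores$start)
              else character(0),
              score = rep(0, nrow(bundle$shores)))
  write_tsv(cbind(bundle$windows$windows,
                  as.data.frame(bundle$windows$level)), pth("windows.tsv"))
  write_tsv(bundle$fit$table, pth("window_tests.tsv"))
  write_tsv(bundle$links, pth("dmr_annotation.tsv"))
  write_tsv(bundle$feature_distribution, pth("feature_distribution.tsv"))
  write_tsv(bundle$degs, pth("degs.tsv"))
  write_tsv(bundle$co_different$genes, pth("integration.tsv"))
  write_tsv(bundle$fold_change_by_category, pth("fold_change_by_category.tsv"))
  export_dmr_fasta(bundle$dmrs, bundle$genome, pth("dmr_sequences.fa"))
  writeLines(.summary_text(bundle), pth("summary.txt"))
  invisible(list.files(outdir, full.names = TRUE))
}

.summary_text <- function(bundle) {
  s <- bundle$summary
  cfg <- bundle$config
  out <- c(
    "== RRBS differential-methylation pipeline summary ==",
    sprintf("seed: %d", cfg$seed),
    sprintf("mode: %s", if (is.null(cfg$sim)) "real-input" else "simulate"),
    sprintf("groups: %s (reference) vs %s", cfg$groups[1], cfg$groups[2]),
    sprintf("window: %d bp, step %d, min CpGs %d; depth > %d; |delta| >= %.2f; q < %.2f",
            cfg$window_width, cfg$window_step, cfg$min_cpgs, cfg$min_depth,
            cfg$delta_min, cfg$q_max),
    "",
    sprintf("CpG dyads read: %d; after filters: %d", s$n_sites,
            s$n_sites_filtered),
    sprintf("windows tested: %d", s$n_windows),
    sprintf("DMRs called: %d", s$dmr$n_called))
  if (s$dmr$n_called > 0)
    out <- c(out, sprintf("  hyper: %d (%.1f%%); hypo: %d (%.1f%%)",
                          s$dmr$n_hyper, s$dmr$pct["hyper"],
                          s$dmr$n_hypo, s$dmr$pct["hypo"]))
  if (!is.null(s$conversion))
    out <- c(out, sprintf("bisulfite conversion (pooled): %.4f",
                          s$conversion$pooled))
  out <- c(out, "", "feature distribution of DMRs:",
           sprintf("  %-18s %6d  %6.2f%%", s$feature_distribution$category,
                   s$feature_distribution$count,
                   s$feature_distribution$percent),
           "",
           sprintf("DEGs: %d; co-different genes: %d", s$n_degs,
                   s$n_co_different),
           "quadrants (genes): ",
           sprintf("  %-10s %d", names(s$quadrant_genes),
                   as.integer(s$quadrant_genes)),
           "quadrants (DMR links): ",
           sprintf("  %-10s %d", names(s$quadrant_dmrs),
                   as.integer(s$quadrant_dmrs)))
  if (!is.null(s$recovery)) {
    r <- s$recovery
    out <- c(out, "",
             sprintf("truth-vs-called: %d planted, %d called; sensitivity %.3f; empirical FDR %.3f",
                     r$n_true, r$n_called, r$sensitivity, r$fdr))
  }
  out
}
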