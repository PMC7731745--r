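# Internal helpers shared across modules.

# Deterministic per-stage seed substreams: one top-level seed fans out into
# independent stage seeds so that, e.g., regenerating expression does not
# perturb the methylome stream.
.STAGES <- c("genome", "genes", "methylome", "counts", "expression", "misc")

stage_seed <- function(seed, stage) {
  stage <- match.arg(stage, .STAGES)
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  draws <- sample.int(.Machine$integer.max - 1L, length(.STAGES))
  draws[match(stage, .STAGES)]
}

# random DNA with a given GC fraction
random_seq <- function(n, gc) {
  if (n <= 0L) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# clamp a methylation fraction away from 0/1 so logit transforms stay finite
clamp01 <- function(x, eps = 0.001) pmin(pmax(x, eps), 1 - eps)

logit <- function(p) log(p / (1 - p))
inv_logit <- function(x) 1 / (1 + exp(-x))

`%||%` <- function(a, b) if (is.null(a)) b else a

# 0-based half-open interval overlap on one chromosome
.overlaps_any <- function(start, end, starts, ends) {
  if (length(starts) == 0L) return(FALSE)
  any(start < ends & end > starts)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# write a data.frame as a plain TSV with stable formatting
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
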