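# compact study configuration used across tests: one 300 kb chromosome,
# enough MspI targets for a few hundred analysis windows
small_cfg <- function(seed = 1, n_dmr = 30, ...) {
  sim_config(seed = seed, n_chrom = 1, chrom_length = 3e5, n_genes = 20,
             n_cgi = 5, n_rrbs_targets = 120, n_dmr = n_dmr, ...)
}

# one cached small simulation shared by read-only tests
cached_sim <- local({
  sim <- NULL
  function() {
    if (is.null(sim)) sim <<- simulate_rrbs(small_cfg(seed = 42))
    sim
  }
})

# hand-built count object: sites x samples with paired design metadata
toy_counts <- function(pos, meth, total, chrom = "chr1",
                       groups = c("adipogenic", "myogenic"), n_animals = 3) {
  samples <- data.frame(
    sample = paste(rep(groups, each = n_animals),
                   rep(seq_len(n_animals), 2), sep = "_"),
    animal = rep(paste0("animal", seq_len(n_animals)), 2),
    group = rep(groups, each = n_animals))
  cpg_counts(data.frame(chrom = rep(chrom, length.out = length(pos)),
                        pos = pos), samples, meth, total)
}
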