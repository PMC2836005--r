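# Shared fixtures, built once per test run.

fixture_env <- new.env(parent = emptyenv())

# A small zero-divergence Ginger1 simulation reused by several files.
small_sim <- function() {
  if (is.null(fixture_env$small_sim)) {
    fixture_env$small_sim <- simulate_genome(sim_config(
      genome_length = 1e5, n_elements = 5, copy_divergence = 0, seed = 3))
  }
  fixture_env$small_sim
}

# Build a spliced gene region fixture: a peptide's CDS with introns planted
# at the given CDS offsets, surrounded by random sequence. Returns the
# region string and the truth (intron bounds within the region).
gene_region_fixture <- function(pep, offsets, intron_len = 64, flank = 80,
                                donors = rep("GT", length(offsets))) {
  cds <- gingerscan:::backtranslate(pep)
  offsets <- sort(offsets)
  gene <- ""
  prev <- 0
  introns <- list()
  pos <- 0
  for (k in seq_along(offsets)) {
    ex <- substr(cds, prev + 1, offsets[k])
    pos <- pos + nchar(ex)
    intron <- paste0(donors[k], random_dna(intron_len - 4), "AG")
    introns[[k]] <- c(start0 = flank + pos, end0 = flank + pos + intron_len,
                      phase = offsets[k] %% 3)
    pos <- pos + intron_len
    gene <- paste0(gene, ex, intron)
    prev <- offsets[k]
  }
  gene <- paste0(gene, substr(cds, prev + 1, nchar(cds)))
  list(region = paste0(random_dna(flank), gene, random_dna(flank)),
       introns = do.call(rbind, introns))
}
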