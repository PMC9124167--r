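# hand-built verdict tables: one phylum, n genomes, all 26 categories tied
# except those named in cat_wins = list(<letter> = c(n_small_wins,
# n_large_wins)); used by the aggregation and acceptance tests
make_verdicts <- function(n_genomes, phylum = "TestPhylum",
                          cat_wins = list()) {
  ids <- sprintf("%s_%04d", phylum, seq_len(n_genomes))
  base <- tidyr::expand_grid(genome_id = ids,
                             category = cog_categories()$category)
  base$phylum <- phylum
  base$p_value <- 0.001
  base$ind_small <- 0L
  base$ind_large <- 0L
  for (cat in names(cat_wins)) {
    w <- cat_wins[[cat]]
    rows <- which(base$category == cat)
    base$ind_small[rows[seq_len(w[1])]] <- 1L
    if (w[2] > 0) base$ind_large[rows[w[1] + seq_len(w[2])]] <- 1L
  }
  base[, c("genome_id", "phylum", "p_value", "category",
           "ind_small", "ind_large")]
}
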