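# A reduced synthetic cluster set for fast integration tests: smaller
# spans, two decoys per species, and the anchored element placed at a
# common 3 kb distance so its normalized positions stay comparable in the
# smaller intergenic gaps.

small_spec <- function(seed = 7L, ...) {
  synthetic_cluster_spec(
    cluster_span = c(30000L, 24000L, 27000L),
    n_decoys = 2L,
    anchor_distances = list("DR5-6" = c(3000L, 3000L, 3000L)),
    seed = seed, ...)
}

# simple three-gene plus-strand gene table on one sequence
toy_genes <- function(species = "sp1", seq_id = "chr",
                      lo = c(25000L, 55000L, 85000L), width = 8000L) {
  data.frame(species = species, seq_id = seq_id,
             gene_id = paste0("gene", seq_along(lo)),
             start_codon_pos = lo, stop_codon_end = lo + width,
             strand = "+", cluster_rank = seq_along(lo),
             stringsAsFactors = FALSE)
}
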