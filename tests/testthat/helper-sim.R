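# Small, fast configurations shared by the module tests.

small_config <- function(...) {
  args <- utils::modifyList(
    list(n_genes = 60, n_mito_genes = 8, n_chloro_genes = 3,
         gene_length_range = c(300L, 600L), n_sites = 15,
         n_pos_regulators = 5, n_neg_regulators = 5),
    list(...))
  do.call(sim_config, args)
}

# A tiny hand-written pileup row.
pileup_row <- function(gene = "g1", pos = 1L, ref = "C", A = 0, C = 0,
                       G = 0, T = 0, sample = "s1") {
  data.frame(gene_id = gene, pos = pos, ref = ref, A = A, C = C, G = G,
             T = T, sample = sample, stringsAsFactors = FALSE)
}
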