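#!/usr/bin/env Rscript
# Stage 4: RNA secondary structure and editing.
#
# Folds each organellar CDS with the base-pair-maximisation local fold,
# merges structured regions, computes structure%, and tests whether edited
# cytidines are depleted from structured regions (Fisher exact).

library(cuedit)

sim <- "results/sim"
out <- "results/structure"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

ref <- read_reference(file.path(sim, "reference.fa"),
                      file.path(sim, "annotation.tsv"))
es <- read.delim(file.path("results/sites", "editing_sites.tsv"))
org <- ref$annotation$gene_id[ref$annotation$compartment != "nuclear"]

summaries <- lapply(setNames(org, org), function(g) {
  fr <- fold_local(ref$sequences[[g]])$regions
  merge_regions(fr, nchar(ref$sequences[[g]]), gene_id = g)
})
sp <- vapply(summaries, `[[`, numeric(1), "structure_percent")
cat(sprintf("genome structure%%: %.1f%% (over %d organellar CDSs)\n",
            100 * mean(sp), length(sp)))
regions <- do.call(rbind, lapply(summaries, function(s) {
  if (nrow(s$merged_regions) == 0) return(NULL)
  data.frame(gene_id = s$gene_id, s$merged_regions)
}))
write.table(regions, file.path(out, "structured_regions.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

in_struct <- function(df) {
  vapply(seq_len(nrow(df)), function(i) {
    positions_in_regions(df$pos[i],
                         summaries[[df$gene_id[i]]]$merged_regions)
  }, logical(1))
}
uned <- unedited_cytidines(list(sites = es), ref$sequences)
test <- structure_overlap_test(in_struct(es), in_struct(uned))
print(test$table)
cat(sprintf("edited in structure: %.1f%%, unedited: %.1f%%, Fisher p = %.3g\n",
            100 * test$edited_fraction, 100 * test$unedited_fraction,
            test$p_value))
write.table(data.frame(population = c("edited", "unedited"),
                       structured_fraction = c(test$edited_fraction,
                                               test$unedited_fraction),
                       fisher_p = test$p_value),
            file.path(out, "structure_overlap.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

cat("done: structure tables under", out, "\n")
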