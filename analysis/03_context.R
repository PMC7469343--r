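#!/usr/bin/env Rscript
# Stage 3: sequence context of edited cytidines.
#
# Compares the -4..+4 context of edited vs unedited cytidines against the
# background composition, groups editing levels by the 5' (-1) base, and
# annotates codon consequences.

library(cuedit)

sim <- "results/sim"
out <- "results/context"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

ref <- read_reference(file.path(sim, "reference.fa"),
                      file.path(sim, "annotation.tsv"))
es <- read.delim(file.path("results/sites", "editing_sites.tsv"))
lv <- as.matrix(es[, grep("^level_", names(es))])
rownames(lv) <- paste0(es$gene_id, ":", es$pos)

ctx <- vapply(seq_len(nrow(es)), function(i) {
  extract_context(es$pos[i], ref$sequences[[es$gene_id[i]]])
}, character(1))

prof <- composition_profile(ctx, "edited")
uned <- unedited_cytidines(list(sites = es), ref$sequences)
ctx_u <- vapply(seq_len(nrow(uned)), function(i) {
  extract_context(uned$pos[i], ref$sequences[[uned$gene_id[i]]])
}, character(1))
prof_u <- composition_profile(ctx_u, "unedited_C")
bg <- background_profile(ref$sequences[unique(es$gene_id)])
write.table(rbind(prof, prof_u), file.path(out, "motif_profiles.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

cat(sprintf("5'-T fraction: edited %.2f, unedited %.2f, background %.2f\n",
            prof$fraction[prof$offset == -1 & prof$base == "T"],
            prof_u$fraction[prof_u$offset == -1 & prof_u$base == "T"],
            bg[["T"]]))

grp <- level_by_flanking_base(ctx, lv, offset = -1)
cat("median level by 5' base:\n")
print(round(grp$medians, 3))
cat(sprintf("Wilcoxon p (T vs G): %.3g\n", grp$pairwise_p["T", "G"]))

codon <- do.call(rbind, lapply(seq_len(nrow(es)), function(i) {
  annotate_codon_effect(es$pos[i], ref$sequences[[es$gene_id[i]]])
}))
cat("codon consequences:\n")
print(table(codon$class))
write.table(cbind(es[, c("gene_id", "pos")], codon),
            file.path(out, "codon_effects.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

cat("done: context tables under", out, "\n")
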