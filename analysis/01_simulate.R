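#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study.
#
# Emulates the study design downstream stages expect: ~2000 CDSs (42
# organellar, the rest nuclear), 100 true C-to-U editing sites whose levels
# depend on the 5' base, depleted from base-paired regions, and coupled to
# 20 positive + 20 negative nuclear trans-regulators across 3 root + 3
# shoot samples; matched pileups and a Ribo-seq-like count matrix.

library(cuedit)

out <- "results/sim"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- sim_config(seed = 1)
print(cfg)

ref <- generate_reference(cfg)
print(ref)
write_reference(ref, file.path(out, "reference.fa"),
                file.path(out, "annotation.tsv"))

truth <- generate_truth(ref, cfg)
print(truth)
write.table(cbind(truth$sites, truth$levels),
            file.path(out, "truth_sites.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(truth$regulators, file.path(out, "truth_regulators.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

pileup <- generate_pileups(ref, truth, cfg)
write_pileup(pileup, file.path(out, "pileup.tsv"))
cat("pileup rows:", nrow(pileup), "\n")

exprs <- generate_expression(truth, cfg)
print(exprs)
write.table(data.frame(gene_id = rownames(exprs$counts),
                       length = exprs$lengths, exprs$counts),
            file.path(out, "counts.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

cat("done: synthetic study written under", out, "\n")
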