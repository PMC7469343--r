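#!/usr/bin/env Rscript
# Stage 2: variant calling and editing-site selection.
#
# Calls RNA-level variants from the pileup (depth >= 10, level > 0.05,
# single variation type), summarises the substitution spectrum (C-to-U
# should dominate), and collapses C>T records into editing sites with
# 6-sample level vectors.

library(cuedit)

sim <- "results/sim"
out <- "results/sites"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

pileup <- read_pileup(file.path(sim, "pileup.tsv"))
ref <- read_reference(file.path(sim, "reference.fa"),
                      file.path(sim, "annotation.tsv"))

variants <- call_variants(pileup)
cat("variant records:", nrow(variants), " (",
    nrow(attr(variants, "discarded")), "discarded as multi-type )\n")

sp <- variant_spectrum(variants)
cat(sprintf("C-to-U fraction of all variants: %.1f%%\n", 100 * sp["C>T"]))
write.table(data.frame(type = names(sp), fraction = as.numeric(sp)),
            file.path(out, "spectrum.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

sites <- select_editing_sites(variants, pileup, ref$annotation)
print(sites)
cat(sprintf("detectable in all six samples: %d / %d\n",
            sum(sites$sites$detectable_all), nrow(sites$sites)))
write.table(cbind(sites$sites,
                  setNames(as.data.frame(sites$levels),
                           paste0("level_", colnames(sites$levels)))),
            file.path(out, "editing_sites.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

cat("done: sites written under", out, "\n")
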