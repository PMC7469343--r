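#' Variation level of a site
#'
#' The level is the alternative allele count divided by the total depth;
#' for a C-to-U editing site this is T / (C + T) when only C and T reads
#' cover the position.
#'
#' @param alt_count alternative-base read count.
#' @param depth total covering reads.
#' @return fraction in `[0, 1]`.
#' @export
#' @examples
#' compute_variant_level(103, 103)  # 1.0
#' compute_variant_level(0, 31)     # 0.0
compute_variant_level <- function(alt_count, depth) {
  if (any(depth <= 0)) stopf("variation level undefined at zero depth")
  if (any(alt_count < 0 | alt_count > depth)) {
    stopf("alt_count must lie in [0, depth]")
  }
  alt_count / depth
}

#' Call RNA-level variants from a pileup table
#'
#' Retains positions with total depth >= `min_depth`, level strictly >
#' `min_level`, and exactly one qualifying alternative base. A second
#' alternative base counts as present (and the site is discarded as
#' multi-type) when it reaches `second_alt_min_reads` reads and
#' `second_alt_min_frac` of the depth; weaker second signals are treated as
#' sequencing noise. Discarded multi-type sites are attached as the
#' `"discarded"` attribute with a reason.
#'
#' @param pileup a `pileup_table` data.frame (gene_id, pos, ref, A, C, G, T,
#'   sample).
#' @param min_depth minimum covering reads (kept when depth >= min_depth).
#' @param min_level minimum level, strict (kept when level > min_level).
#' @param second_alt_min_reads,second_alt_min_frac thresholds defining a
#'   "present" second variation type.
#' @return data.frame of variant records: gene_id, pos, ref, alt, depth,
#'   alt_count, level, sample.
#' @export
call_variants <- function(pileup, min_depth = 10, min_level = 0.05,
                          second_alt_min_reads = 2,
                          second_alt_min_frac = 0.01) {
  bases <- c("A", "C", "G", "T")
  bad_ref <- !(pileup$ref %in% bases)
  if (any(bad_ref)) {
    warning(sprintf("%d pileup rows with unknown reference base skipped",
                    sum(bad_ref)))
    pileup <- pileup[!bad_ref, , drop = FALSE]
  }
  cnt <- as.matrix(pileup[, bases])
  depth <- rowSums(cnt)
  ref_idx <- match(pileup$ref, bases)
  alt <- cnt
  alt[cbind(seq_len(nrow(alt)), ref_idx)] <- -1L  # mask reference base
  top <- max.col(alt, ties.method = "first")
  top_count <- alt[cbind(seq_len(nrow(alt)), top)]
  top_count[top_count < 0] <- 0L

  # additional "present" variation types beyond the primary alternative
  present <- alt >= pmax(second_alt_min_reads, second_alt_min_frac * depth)
  n_other <- rowSums(present) - present[cbind(seq_len(nrow(alt)), top)]

  level <- ifelse(depth > 0, top_count / depth, 0)
  keep <- depth >= min_depth & level > min_level & n_other == 0
  multi <- depth >= min_depth & level > min_level & n_other > 0

  out <- data.frame(gene_id = pileup$gene_id[keep], pos = pileup$pos[keep],
                    ref = pileup$ref[keep], alt = bases[top[keep]],
                    depth = depth[keep], alt_count = top_count[keep],
                    level = level[keep], sample = pileup$sample[keep],
                    stringsAsFactors = FALSE)
  discarded <- data.frame(gene_id = pileup$gene_id[multi],
                          pos = pileup$pos[multi],
                          sample = pileup$sample[multi],
                          reason = rep("multiple variation types", sum(multi)),
                          stringsAsFactors = FALSE)
  attr(out, "discarded") <- discarded
  out
}

#' Substitution-type spectrum of called variants
#'
#' @param variants data.frame from [call_variants()].
#' @return named numeric vector over the 12 substitution types
#'   (`"C>T"`, ...), fractions summing to 1.
#' @export
variant_spectrum <- function(variants) {
  if (nrow(variants) == 0) stopf("no variants to summarise")
  bases <- c("A", "C", "G", "T")
  types <- unlist(lapply(bases, function(r) {
    paste0(r, ">", setdiff(bases, r))
  }))
  obs <- paste0(variants$ref, ">", variants$alt)
  tab <- table(factor(obs, levels = types))
  setNames(as.numeric(tab) / nrow(variants), types)
}

#' Select bona fide C-to-U editing sites across samples
#'
#' Keeps C>T variant records only, collapses them to one site per
#' (gene, position), and reports for every sample the editing level
#' T / (C + T) and the total depth from the pileup — including samples in
#' which the site did not pass the discovery filters (the level filter
#' applies to site discovery, not to the reported per-sample vector).
#'
#' @param variants data.frame from [call_variants()] (all samples pooled).
#' @param pileup the full `pileup_table` the variants were called from.
#' @param annotation data.frame with gene_id and compartment.
#' @param min_depth depth required in every sample for `detectable_all`.
#' @return list of class `editing_site_set`: `sites` (gene_id, pos,
#'   compartment, detectable_all), `levels` and `depths` (site x sample
#'   matrices), `samples`.
#' @export
select_editing_sites <- function(variants, pileup, annotation,
                                 min_depth = 10) {
  ct <- variants[variants$ref == "C" & variants$alt == "T", , drop = FALSE]
  key <- unique(paste0(ct$gene_id, ":", ct$pos))
  samples <- unique(pileup$sample)
  sites <- unique(ct[, c("gene_id", "pos")])
  sites <- sites[order(sites$gene_id, sites$pos), , drop = FALSE]
  rownames(sites) <- NULL

  pk <- paste0(pileup$gene_id, ":", pileup$pos)
  ref_by_key <- tapply(pileup$ref, pk, function(r) length(unique(r)))
  if (any(ref_by_key[paste0(sites$gene_id, ":", sites$pos)] > 1)) {
    stopf("conflicting reference bases across samples at an editing site")
  }

  nL <- nrow(sites)
  levels <- matrix(NA_real_, nL, length(samples),
                   dimnames = list(paste0(sites$gene_id, ":", sites$pos),
                                   samples))
  depths <- matrix(NA_real_, nL, length(samples),
                   dimnames = dimnames(levels))
  for (si in seq_along(samples)) {
    sub <- pileup[pileup$sample == samples[si], , drop = FALSE]
    m <- match(paste0(sites$gene_id, ":", sites$pos),
               paste0(sub$gene_id, ":", sub$pos))
    ctot <- sub$C[m]; ttot <- sub$T[m]
    levels[, si] <- ifelse(ctot + ttot > 0, ttot / (ctot + ttot), NA_real_)
    depths[, si] <- sub$A[m] + sub$C[m] + sub$G[m] + sub$T[m]
  }
  sites$compartment <- annotation$compartment[match(sites$gene_id,
                                                    annotation$gene_id)]
  sites$detectable_all <- apply(depths >= min_depth, 1, all)

  structure(list(sites = sites, levels = levels, depths = depths,
                 samples = samples),
            class = "editing_site_set")
}

#' @export
print.editing_site_set <- function(x, ...) {
  cat("editing_site_set:", nrow(x$sites), "C-to-U sites;",
      sum(x$sites$detectable_all), "detectable in all",
      length(x$samples), "samples\n")
  invisible(x)
}
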