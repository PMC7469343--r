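#' Run the full editing analysis on synthetic data
#'
#' Orchestrates every stage: generate the reference, truth, pileups,
#' expression matrix and hybrid alleles; call variants and select editing
#' sites; context and codon annotation; structured-region overlap; hybrid
#' species-specific calls; and the Spearman/FDR trans-regulator screen with
#' site and gene classification. When `out_dir` is given, the stage tables
#' are written as TSV plus a JSON manifest recording every effective
#' threshold.
#'
#' @param config a [sim_config()].
#' @param out_dir optional output directory.
#' @param min_depth,min_level variant filters (see [call_variants()]).
#' @param alpha FDR threshold for the correlation screen.
#' @param family BH family: `"global"` (all site x gene pairs) or
#'   `"per_site"`.
#' @param n_min,dominance site-class thresholds ([classify_sites()]).
#' @param k_min gene-class threshold ([classify_genes()]).
#' @param run_hybrid simulate and call the hybrid stage.
#' @return list of class `pipeline_result` with the stage outputs and a
#'   `manifest` of all effective settings.
#' @export
run_pipeline <- function(config, out_dir = NULL, min_depth = 10,
                         min_level = 0.05, alpha = 0.05,
                         family = "global", n_min = 5, dominance = 2.0,
                         k_min = 10, run_hybrid = TRUE) {
  validate_sim_config(config)

  ref <- generate_reference(config)
  truth <- generate_truth(ref, config)
  pileup <- generate_pileups(ref, truth, config)
  exprs <- generate_expression(truth, config)

  variants <- call_variants(pileup, min_depth = min_depth,
                            min_level = min_level)
  site_set <- select_editing_sites(variants, pileup, ref$annotation,
                                   min_depth = min_depth)
  spectrum <- variant_spectrum(variants)

  site_ids <- paste0(site_set$sites$gene_id, ":", site_set$sites$pos)
  contexts <- vapply(seq_len(nrow(site_set$sites)), function(i) {
    extract_context(site_set$sites$pos[i],
                    ref$sequences[[site_set$sites$gene_id[i]]])
  }, character(1))
  names(contexts) <- site_ids
  codon <- do.call(rbind, lapply(seq_len(nrow(site_set$sites)), function(i) {
    annotate_codon_effect(site_set$sites$pos[i],
                          ref$sequences[[site_set$sites$gene_id[i]]])
  }))

  # structure overlap: called sites vs unedited Cs on the same CDSs
  uned <- unedited_cytidines(site_set, ref$sequences)
  in_struct <- function(df) {
    vapply(seq_len(nrow(df)), function(i) {
      st <- truth$structured_truth[[df$gene_id[i]]]
      if (is.null(st)) return(FALSE)
      positions_in_regions(df$pos[i], st$merged_regions)
    }, logical(1))
  }
  structure_test <- structure_overlap_test(in_struct(site_set$sites),
                                           in_struct(uned))

  hybrid <- NULL
  hybrid_calls <- NULL
  if (run_hybrid) {
    hybrid <- generate_hybrid(ref, config, truth)
    hybrid_calls <- call_hybrid_sites(hybrid$pileups, min_depth = min_depth)
  }

  # trans-regulator screen on sites detectable in all samples
  # SE filter on log2 RPKM: expression profiles are approximately normal on
  # the log scale, which is what the within-vs-between-group SE comparison
  # assumes. Constant (zero-variance) genes cannot be correlated and drop.
  rpkm <- compute_rpkm(exprs$counts, exprs$lengths)
  keep_genes <- se_filter(log2(rpkm + 0.5), exprs$groups) &
    apply(rpkm, 1, function(x) sd(x) > 0)
  det <- site_set$sites$detectable_all
  screen_levels <- site_set$levels[det, , drop = FALSE]
  corr <- spearman_site_gene(screen_levels,
                             rpkm[keep_genes, , drop = FALSE])
  corr <- correlation_significance(corr, alpha = alpha, family = family)
  site_classes <- classify_sites(corr, n_min = n_min, dominance = dominance)
  gene_classes <- classify_genes(corr, k_min = k_min)
  stats <- class_site_stats(site_classes, screen_levels,
                            codon$class[match(site_classes$site, site_ids)])
  five_prime <- setNames(substr(contexts, 4, 4), site_ids)
  fp_by_class <- five_prime_by_gene_class(gene_classes, corr, five_prime)

  manifest <- list(
    seed = config$seed, n_genes = config$n_genes,
    n_sites = config$n_sites, samples = config$samples,
    min_depth = min_depth, min_level = min_level, alpha = alpha,
    fdr_family = family, n_min = n_min, dominance = dominance,
    k_min = k_min,
    depth_range = config$depth_range, error_rate = config$error_rate,
    regulator_effect = config$regulator_effect,
    noise_sd = config$noise_sd,
    structure_avoidance = config$structure_avoidance,
    se_pass_fraction = config$se_pass_fraction,
    tested_genes = sum(keep_genes),
    screened_sites = nrow(screen_levels),
    package_version = as.character(utils::packageVersion("cuedit")))

  res <- structure(list(
    ref = ref, truth = truth, pileup = pileup, expression = exprs,
    variants = variants, site_set = site_set, spectrum = spectrum,
    contexts = contexts, codon = codon, structure_test = structure_test,
    hybrid = hybrid, hybrid_calls = hybrid_calls, rpkm = rpkm,
    tested_genes = rownames(rpkm)[keep_genes], correlation = corr,
    site_classes = site_classes, gene_classes = gene_classes,
    class_stats = stats, five_prime_by_class = fp_by_class,
    manifest = manifest), class = "pipeline_result")

  if (!is.null(out_dir)) write_pipeline(res, out_dir)
  res
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("pipeline_result:", nrow(x$site_set$sites), "called sites;",
      "C-to-U fraction", round(x$spectrum["C>T"], 3), ";",
      "site classes:", paste(names(table(x$site_classes$class)),
                             table(x$site_classes$class), collapse = " "),
      "\n")
  invisible(x)
}

write_pipeline <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(df, name) {
    write.table(df, file.path(out_dir, name), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  tsv(res$variants, "variants.tsv")
  tsv(cbind(res$site_set$sites,
            setNames(as.data.frame(res$site_set$levels),
                     paste0("level_", colnames(res$site_set$levels)))),
      "editing_sites.tsv")
  tsv(data.frame(type = names(res$spectrum),
                 fraction = as.numeric(res$spectrum)), "spectrum.tsv")
  tsv(res$site_classes, "site_classes.tsv")
  tsv(res$gene_classes[res$gene_classes$label != "none", , drop = FALSE],
      "gene_classes.tsv")
  tsv(res$five_prime_by_class, "five_prime_by_gene_class.tsv")
  tsv(res$class_stats$summary, "class_stats.tsv")
  if (!is.null(res$hybrid_calls)) tsv(res$hybrid_calls, "hybrid_calls.tsv")
  st <- res$structure_test
  tsv(data.frame(population = c("edited", "unedited"),
                 structured_fraction = c(st$edited_fraction,
                                         st$unedited_fraction),
                 fisher_p = st$p_value), "structure_overlap.tsv")
  jsonlite::write_json(res$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}
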