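#' Compare a pipeline run against its synthetic ground truth
#'
#' Computes the recovery statistics the generator is designed to support:
#' how many true regulators receive the correct positive/negative label,
#' how many non-regulator genes are falsely labelled, and how many
#' regulator-targeted sites land in class I or III.
#'
#' @param res a `pipeline_result` from [run_pipeline()].
#' @return list: `sign_recovery` (fraction of true regulators with the
#'   correct label), `false_regulator_rate` (fraction of non-regulator
#'   genes labelled positive/negative/both), `targeted_class_recovery`
#'   (fraction of screened regulator-targeted sites in class I or III),
#'   `site_recall` (called true sites / true sites), plus the underlying
#'   counts.
#' @export
evaluate_recovery <- function(res) {
  truth <- res$truth
  gc <- res$gene_classes
  labels <- setNames(gc$label, gc$gene_id)

  want <- ifelse(truth$regulators$sign == "+", "positive", "negative")
  got <- labels[truth$regulators$gene_id]
  got[is.na(got)] <- "none"
  sign_recovery <- mean(got == want)

  all_genes <- truth$annotation$gene_id
  non_reg <- setdiff(all_genes, truth$regulators$gene_id)
  lab_nr <- labels[intersect(non_reg, names(labels))]
  false_regulator_rate <- sum(lab_nr != "none") / length(non_reg)

  truth_ids <- paste0(truth$sites$gene_id, ":", truth$sites$pos)
  targeted <- truth_ids[truth$sites$target != "none"]
  sc <- res$site_classes
  screened_targeted <- intersect(targeted, sc$site)
  targeted_class_recovery <- if (length(screened_targeted)) {
    mean(sc$class[match(screened_targeted, sc$site)] %in% c("I", "III"))
  } else {
    NA_real_
  }

  called_ids <- paste0(res$site_set$sites$gene_id, ":",
                       res$site_set$sites$pos)
  site_recall <- mean(truth_ids %in% called_ids)

  list(sign_recovery = sign_recovery,
       false_regulator_rate = false_regulator_rate,
       targeted_class_recovery = targeted_class_recovery,
       site_recall = site_recall,
       n_regulators = nrow(truth$regulators),
       n_non_regulators = length(non_reg),
       n_targeted_screened = length(screened_targeted))
}
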