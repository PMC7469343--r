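#' Simulation configuration for the synthetic editing study
#'
#' Builds the configuration object consumed by the synthetic-data generators
#' ([generate_reference()], [generate_truth()], [generate_pileups()],
#' [generate_expression()], [generate_hybrid()]). Defaults emulate the study
#' design the analysis targets: six samples (three root, three shoot
#' replicates), editing restricted to a small set of organellar CDSs, editing
#' levels that depend on the base 5' of the edited cytidine, placement biased
#' away from base-paired regions, and a positive and a negative set of
#' nuclear trans-regulator genes whose expression is coupled to the levels of
#' the sites they target.
#'
#' @param n_genes total number of CDSs (organellar + nuclear).
#' @param n_mito_genes,n_chloro_genes number of mitochondrial / chloroplast
#'   CDSs; editing sites are placed on these. The remainder are nuclear.
#' @param gene_length_range CDS length range in nt; both ends must be
#'   multiples of 3.
#' @param n_sites number of true C-to-U editing sites.
#' @param samples sample identifiers, ordered.
#' @param groups group label (`"root"`/`"shoot"`) per sample.
#' @param mean_level_by_5prime named fractions in `[0,1]`: the mean editing
#'   level for sites whose 5' (-1) neighbour is T, C, A or G. The default
#'   ordering T > C > A > G mirrors the observed level ordering by upstream
#'   base; the values themselves are generator choices.
#' @param base_level_sd logit-scale spread of a site's base level around the
#'   5'-base mean.
#' @param depth_range per-position read depth range (uniform).
#' @param error_rate per-base sequencing error rate at non-edited positions.
#' @param n_pos_regulators,n_neg_regulators numbers of positively /
#'   negatively coupled regulator genes (nuclear).
#' @param regulator_effect logit-scale slope per unit regulator expression
#'   z-score (per regulator; a site targeted by a regulator set accumulates
#'   their summed contribution).
#' @param noise_sd logit-scale sample-level noise for regulator-targeted
#'   sites.
#' @param idle_noise_sd logit-scale noise for untargeted sites. Larger than
#'   `noise_sd` by default so that regulated sites are the *stabler* ones.
#' @param targeted_fraction fraction of sites coupled to regulators (split
#'   evenly between the positive and negative regulator sets).
#' @param se_pass_fraction fraction of non-regulator genes constructed to
#'   pass the standard-error filter (tissue-consistent differential
#'   expression larger than within-tissue variability).
#' @param group_shift,within_group_sd latent trans-factor structure: log2
#'   expression shift between root and shoot, and within-group spread.
#' @param total_reads total mapped reads per sample for the expression
#'   matrix.
#' @param structure_avoidance probability that a true site is placed outside
#'   base-paired regions.
#' @param hybrid_divergence per-nt substitution rate between the two parental
#'   alleles of the hybrid.
#' @param n_hybrid_sites number of allele-exclusive editing sites in the
#'   hybrid simulation.
#' @param read_length hybrid read length (nt).
#' @param seed master RNG seed; every generator stage derives its own
#'   sub-seed from it.
#'
#' @return an object of class `sim_config` (a validated named list).
#' @export
#' @examples
#' cfg <- sim_config(n_genes = 50, n_sites = 10, seed = 1)
#' cfg$samples
sim_config <- function(n_genes = 2000,
                       n_mito_genes = 30,
                       n_chloro_genes = 12,
                       gene_length_range = c(300L, 1500L),
                       n_sites = 100,
                       samples = c("root1", "root2", "root3",
                                   "shoot1", "shoot2", "shoot3"),
                       groups = c("root", "root", "root",
                                  "shoot", "shoot", "shoot"),
                       mean_level_by_5prime = c(T = 0.80, C = 0.60,
                                                A = 0.40, G = 0.15),
                       base_level_sd = 0.35,
                       depth_range = c(800L, 3000L),
                       error_rate = 0.002,
                       n_pos_regulators = 20,
                       n_neg_regulators = 20,
                       regulator_effect = 0.11,
                       noise_sd = 0.02,
                       idle_noise_sd = 1.0,
                       targeted_fraction = 0.8,
                       se_pass_fraction = 0.05,
                       group_shift = 2.5,
                       within_group_sd = 1.0,
                       total_reads = 2e6,
                       structure_avoidance = 0.9,
                       hybrid_divergence = 0.03,
                       n_hybrid_sites = 10,
                       read_length = 100L,
                       seed = 1L) {
  cfg <- list(
    n_genes = n_genes, n_mito_genes = n_mito_genes,
    n_chloro_genes = n_chloro_genes,
    gene_length_range = as.integer(gene_length_range),
    n_sites = n_sites, samples = samples, groups = groups,
    mean_level_by_5prime = mean_level_by_5prime,
    base_level_sd = base_level_sd,
    depth_range = as.integer(depth_range), error_rate = error_rate,
    n_pos_regulators = n_pos_regulators,
    n_neg_regulators = n_neg_regulators,
    regulator_effect = regulator_effect, noise_sd = noise_sd,
    idle_noise_sd = idle_noise_sd,
    targeted_fraction = targeted_fraction,
    se_pass_fraction = se_pass_fraction,
    group_shift = group_shift, within_group_sd = within_group_sd,
    total_reads = total_reads,
    structure_avoidance = structure_avoidance,
    hybrid_divergence = hybrid_divergence,
    n_hybrid_sites = n_hybrid_sites,
    read_length = as.integer(read_length),
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    if (!is_count(n_genes) || n_genes < 1) {
      stopf("n_genes must be a positive count")
    }
    if (n_mito_genes + n_chloro_genes > n_genes) {
      stopf("organellar gene counts exceed n_genes")
    }
    if (length(gene_length_range) != 2 ||
        gene_length_range[1] > gene_length_range[2] ||
        any(gene_length_range %% 3 != 0) || gene_length_range[1] < 9) {
      stopf("gene_length_range must be an increasing pair of multiples of 3")
    }
    if (length(samples) != length(groups)) {
      stopf("samples and groups must have equal length")
    }
    if (any(table(groups) < 2)) stopf("need >= 2 samples per group")
    if (!setequal(names(mean_level_by_5prime), c("A", "C", "G", "T")) ||
        any(mean_level_by_5prime < 0 | mean_level_by_5prime > 1)) {
      stopf("mean_level_by_5prime must map A/C/G/T to fractions in [0,1]")
    }
    probs <- c(error_rate, targeted_fraction, se_pass_fraction,
               structure_avoidance, hybrid_divergence)
    if (any(probs < 0 | probs > 1)) stopf("probabilities must lie in [0,1]")
    if (length(depth_range) != 2 || depth_range[1] > depth_range[2] ||
        depth_range[1] < 1) {
      stopf("depth_range must be an increasing positive pair")
    }
  })
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:", x$n_genes, "genes (",
      x$n_mito_genes, "mito,", x$n_chloro_genes, "chloro ),",
      x$n_sites, "editing sites,", length(x$samples), "samples,",
      x$n_pos_regulators, "+", x$n_neg_regulators, "regulators, seed",
      x$seed, "\n")
  invisible(x)
}
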