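#' Generate the ground-truth editing table for a synthetic reference
#'
#' Places `n_sites` C-to-U editing sites on the organellar CDSs and draws
#' their per-sample editing levels. The generator encodes the statistical
#' structure the downstream analysis is designed to detect:
#'
#' * placement is weighted by the 5'-base level map, so edited cytidines are
#'   enriched for an upstream T/C and depleted for an upstream G;
#' * a site's base level is drawn (logit-normal) around
#'   `mean_level_by_5prime[-1 base]`;
#' * sites land inside base-paired regions (from [fold_local()] on the
#'   reference) only with probability `1 - structure_avoidance`;
#' * a `targeted_fraction` of sites is coupled to trans-regulators: half to
#'   the positive set, half to the negative set. Two latent factors (one per
#'   set), group-structured across the root/shoot samples, drive both the
#'   regulators' expression z-scores and the targeted sites' levels:
#'   `level = inv_logit(logit(base) + sum_r effect * sign_r * z_r + noise)`.
#'   Positive-set targets are sampled with stronger weight on high-base-level
#'   (5'-T) sites; untargeted sites receive larger level noise
#'   (`idle_noise_sd`), so regulated sites are both higher and stabler.
#'
#' @param ref a `reference_set` from [generate_reference()].
#' @param config the same [sim_config()].
#' @return object of class `truth_table`: `sites` (data.frame), `levels`
#'   (site x sample matrix of true levels), `regulators` (gene_id, sign),
#'   `regulator_z` (regulator x sample z-score matrix), `structured_truth`
#'   (per-gene merged structured intervals), `annotation`, `samples`,
#'   `groups`.
#' @export
generate_truth <- function(ref, config) {
  validate_sim_config(config)
  ann <- ref$annotation
  org <- ann$gene_id[ann$compartment != "nuclear"]
  if (length(org) == 0) stopf("no organellar genes to place sites on")
  ns <- length(config$samples)

  # structured regions of the organellar reference (deterministic)
  structured_truth <- lapply(setNames(org, org), function(g) {
    fr <- fold_local(ref$sequences[[g]])$regions
    merge_regions(fr, nchar(ref$sequences[[g]]), gene_id = g)
  })

  with_seed(stage_seed(config$seed, 2L), {
    # candidate cytidines (pos >= 2 so the -1 base exists)
    cand <- do.call(rbind, lapply(org, function(g) {
      s <- strsplit(ref$sequences[[g]], "")[[1]]
      pos <- which(s == "C")
      pos <- pos[pos >= 2]
      if (length(pos) == 0) return(NULL)
      data.frame(gene_id = g, pos = pos, five_prime = s[pos - 1L],
                 stringsAsFactors = FALSE)
    }))
    cand$structured <- logical(nrow(cand))
    for (g in org) {
      sel <- cand$gene_id == g
      cand$structured[sel] <- positions_in_regions(
        cand$pos[sel], structured_truth[[g]]$merged_regions)
    }
    cand$w <- unname(config$mean_level_by_5prime[cand$five_prime])

    n_in <- rbinom(1, config$n_sites, 1 - config$structure_avoidance)
    n_out <- config$n_sites - n_in
    pool_in <- which(cand$structured)
    pool_out <- which(!cand$structured)
    if (length(pool_in) < n_in || length(pool_out) < n_out) {
      stopf("fewer eligible C positions than n_sites (structured: %d/%d, unstructured: %d/%d)",
            length(pool_in), n_in, length(pool_out), n_out)
    }
    pick <- c(
      if (n_in > 0) sample(pool_in, n_in, prob = cand$w[pool_in]),
      if (n_out > 0) sample(pool_out, n_out, prob = cand$w[pool_out]))
    sites <- cand[pick, c("gene_id", "pos", "five_prime", "structured")]
    rownames(sites) <- NULL

    base_mean <- config$mean_level_by_5prime[sites$five_prime]
    sites$base_level <- inv_logit(logit(pmin(pmax(base_mean, 0.02), 0.98)) +
                                  rnorm(nrow(sites), 0, config$base_level_sd))

    # latent trans factors: group shift plus within-group variation
    g01 <- ifelse(config$groups == config$groups[1], 1, -1)
    # regulators are *defined* as tissue-differential genes, so the factor
    # draw is rejected until its realised within-group spread stays below
    # the between-group spread with margin (the SE-filter property holds by
    # construction, not merely in expectation)
    groups_f <- factor(config$groups)
    min_gap <- 0.45 * config$within_group_sd
    make_factor <- function() {
      for (try in 1:500) {
        f <- sample(c(-1, 1), 1) * config$group_shift * g01 +
          rnorm(ns, 0, config$within_group_sd)
        v_all <- stats::var(f)
        v_groups <- tapply(f, groups_f, stats::var)
        gaps <- tapply(f, groups_f, function(x) min(diff(sort(x))))
        if (max(v_groups) < 0.35 * v_all && min(gaps) >= min_gap) return(f)
      }
      f
    }
    f_pos <- make_factor()
    # the two regulator modules must have rank-distinct activity profiles,
    # otherwise every regulator correlates with every targeted site and the
    # positive/negative labels collapse into "both"
    for (try in 1:100) {
      f_neg <- make_factor()
      o_p <- order(f_pos); o_n <- order(f_neg)
      if (!identical(o_n, o_p) && !identical(o_n, rev(o_p))) break
    }

    nuclear <- ann$gene_id[ann$compartment == "nuclear"]
    n_reg <- config$n_pos_regulators + config$n_neg_regulators
    if (length(nuclear) < n_reg) stopf("not enough nuclear genes for regulators")
    reg_ids <- sample(nuclear, n_reg)
    regulators <- data.frame(
      gene_id = reg_ids,
      sign = rep(c("+", "-"), c(config$n_pos_regulators,
                                config$n_neg_regulators)),
      stringsAsFactors = FALSE)
    regulator_z <- t(vapply(seq_len(n_reg), function(i) {
      f <- if (regulators$sign[i] == "+") f_pos else f_neg
      z <- f + rnorm(ns, 0, 0.02)
      as.numeric(scale(z))
    }, numeric(ns)))
    dimnames(regulator_z) <- list(reg_ids, config$samples)

    # regulator targeting: positive set prefers high-base-level (5'-T) sites
    n_t <- round(config$targeted_fraction * config$n_sites)
    n_tp <- floor(n_t / 2); n_tn <- n_t - n_tp
    sites$target <- "none"
    idx <- seq_len(nrow(sites))
    tp <- if (n_tp > 0) sample(idx, n_tp, prob = sites$base_level^2) else integer(0)
    rest <- setdiff(idx, tp)
    tn <- if (n_tn > 0) sample(rest, n_tn, prob = sites$base_level[rest]) else integer(0)
    sites$target[tp] <- "pos"
    sites$target[tn] <- "neg"

    shift_pos <- config$regulator_effect *
      colSums(regulator_z[regulators$sign == "+", , drop = FALSE])
    shift_neg <- -config$regulator_effect *
      colSums(regulator_z[regulators$sign == "-", , drop = FALSE])
    levels <- matrix(NA_real_, nrow(sites), ns,
                     dimnames = list(NULL, config$samples))
    for (i in idx) {
      shift <- switch(sites$target[i], pos = shift_pos, neg = shift_neg,
                      none = rep(0, ns))
      nsd <- if (sites$target[i] == "none") config$idle_noise_sd else
        config$noise_sd
      levels[i, ] <- inv_logit(logit(sites$base_level[i]) + shift +
                               rnorm(ns, 0, nsd))
    }
    rownames(levels) <- paste0(sites$gene_id, ":", sites$pos)

    structure(list(sites = sites, levels = levels, regulators = regulators,
                   regulator_z = regulator_z,
                   structured_truth = structured_truth,
                   annotation = ann, samples = config$samples,
                   groups = config$groups),
              class = "truth_table")
  })
}

#' @export
print.truth_table <- function(x, ...) {
  cat("truth_table:", nrow(x$sites), "sites on",
      length(unique(x$sites$gene_id)), "genes;",
      sum(x$regulators$sign == "+"), "positive +",
      sum(x$regulators$sign == "-"), "negative regulators;",
      sum(x$sites$structured), "sites in structured regions\n")
  invisible(x)
}
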