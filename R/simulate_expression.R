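#' Generate the expression (read-count) matrix
#'
#' Builds a gene x sample read-count matrix whose RPKM structure matches the
#' editing truth: regulator genes' log2 RPKM reproduces the z-score vectors
#' stored in the truth table (so their expression rank order follows the
#' levels they inject); a `se_pass_fraction` of the remaining genes shows
#' tissue-consistent differential expression (constructed to satisfy
#' SE_root < SE_all and SE_shoot < SE_all); all other genes get equal group
#' means with within-group spread exceeding the between-group spread, so
#' they fail the SE filter by construction.
#'
#' @param truth a `truth_table` (carries gene annotation and regulator
#'   z-scores).
#' @param config the [sim_config()].
#' @return list of class `expression_set`: `counts` (integer matrix),
#'   `lengths` (nt, named), `samples`, `groups`, `constructed_pass`
#'   (logical, named: genes built to pass the SE filter).
#' @export
generate_expression <- function(truth, config) {
  validate_sim_config(config)
  ann <- truth$annotation
  n <- nrow(ann)
  ns <- length(config$samples)
  g01 <- ifelse(config$groups == config$groups[1], 1, -1)

  with_seed(stage_seed(config$seed, 4L), {
    mu <- runif(n, 2, 8)
    log2rpkm <- matrix(mu, n, ns)
    reg_rows <- match(truth$regulators$gene_id, ann$gene_id)
    constructed_pass <- setNames(rep(FALSE, n), ann$gene_id)

    # regulators: track their stored z-score vector
    sig <- runif(length(reg_rows), 0.8, 1.2)
    log2rpkm[reg_rows, ] <- mu[reg_rows] + sig * truth$regulator_z
    constructed_pass[reg_rows] <- TRUE

    others <- setdiff(seq_len(n), reg_rows)
    n_pass <- round(config$se_pass_fraction * length(others))
    pass <- sample(others, n_pass)
    fail <- setdiff(others, pass)

    # pass genes: group shift dominates small within-group noise
    b <- runif(n_pass, 0.8, 1.2) * sample(c(-1, 1), n_pass, replace = TRUE)
    log2rpkm[pass, ] <- mu[pass] + outer(b, g01) +
      matrix(rnorm(n_pass * ns, 0, 0.2), n_pass, ns)
    constructed_pass[pass] <- TRUE

    # fail genes: equal group means, large within-group spread; the spread
    # pattern is permuted per gene and group so per-sample totals balance
    cf <- runif(length(fail), 0.8, 1.2)
    pat <- matrix(0, length(fail), ns)
    for (gr in unique(config$groups)) {
      sel <- which(config$groups == gr)
      base_pat <- seq(-1, 1, length.out = length(sel))
      pat[, sel] <- t(vapply(seq_along(fail),
                             function(i) sample(base_pat),
                             numeric(length(sel))))
    }
    log2rpkm[fail, ] <- mu[fail] + cf * pat +
      matrix(rnorm(length(fail) * ns, 0, 0.05), length(fail), ns)

    rpkm <- 2^log2rpkm
    lens_kb <- ann$length / 1000
    counts <- round(rpkm * lens_kb * (config$total_reads / 1e6))
    storage.mode(counts) <- "integer"
    dimnames(counts) <- list(ann$gene_id, config$samples)

    structure(list(counts = counts,
                   lengths = setNames(ann$length, ann$gene_id),
                   samples = config$samples, groups = config$groups,
                   constructed_pass = constructed_pass),
              class = "expression_set")
  })
}

#' @export
print.expression_set <- function(x, ...) {
  cat("expression_set:", nrow(x$counts), "genes x", ncol(x$counts),
      "samples;", sum(x$constructed_pass), "genes built to pass SE filter\n")
  invisible(x)
}
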