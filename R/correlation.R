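#' RPKM expression matrix from read counts
#'
#' RPKM = (reads / gene length in kb) / (total mapped reads / 1e6), per
#' gene per sample.
#'
#' @param counts gene x sample integer matrix.
#' @param lengths gene lengths in nt (named or aligned with rows).
#' @param total_reads optional per-sample totals; defaults to column sums.
#' @return matrix of RPKM values, same dimensions as `counts`.
#' @export
compute_rpkm <- function(counts, lengths, total_reads = NULL) {
  stopifnot(nrow(counts) == length(lengths), all(lengths > 0))
  totals <- total_reads %||% colSums(counts)
  if (any(totals <= 0)) stopf("per-sample total mapped reads must be > 0")
  sweep(counts / (lengths / 1000), 2, totals / 1e6, "/")
}

#' Standard-error filter for group-consistent expression
#'
#' A gene passes when its standard error of the mean within each group is
#' strictly smaller than the standard error over all samples
#' (SE_root < SE_all and SE_shoot < SE_all): expression varies between
#' tissues more than within them.
#'
#' @param expr gene x sample matrix (RPKM).
#' @param groups group label per sample (two or more groups, each >= 2
#'   samples).
#' @return logical vector per gene.
#' @export
se_filter <- function(expr, groups) {
  groups <- as.character(groups)
  sizes <- table(groups)
  if (any(sizes < 2)) stopf("each group needs >= 2 samples")
  se <- function(x) sd(x) / sqrt(length(x))
  se_all <- apply(expr, 1, se)
  pass <- rep(TRUE, nrow(expr))
  for (g in names(sizes)) {
    se_g <- apply(expr[, groups == g, drop = FALSE], 1, se)
    pass <- pass & (se_g < se_all)
  }
  unname(pass)
}

# All permutations of 1..n (n! x n matrix), deterministic order.
permutations_n <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- permutations_n(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  r <- 0L
  for (i in seq_len(n)) {
    rows <- r + seq_len(nrow(sub))
    out[rows, 1] <- i
    rest <- seq_len(n)[-i]
    out[rows, -1] <- matrix(rest[sub], nrow(sub), n - 1L)
    r <- r + nrow(sub)
  }
  out
}

# Tie-aware Spearman rho between rank-standardised row matrices.
rank_standardise <- function(m) {
  r <- t(apply(m, 1, rank))
  ctr <- r - rowMeans(r)
  s <- sqrt(rowSums(ctr^2))
  list(z = ctr / ifelse(s == 0, NA_real_, s), constant = s == 0)
}

#' Site-by-gene Spearman correlation screen with exact permutation p-values
#'
#' Correlates each editing site's per-sample level vector with each gene's
#' per-sample expression vector. Rho is Pearson correlation on average
#' ranks (tie-aware). With `n <= max_exact` samples the two-sided p-value
#' is exact: the proportion of all n! permutations of the site's ranks with
#' |rho| at least the observed |rho|. Pairs involving a constant vector are
#' skipped (NA, counted in `skipped`).
#'
#' @param levels site x sample editing-level matrix.
#' @param expr gene x sample expression (RPKM) matrix.
#' @param max_exact largest n for exact permutation (default 8).
#' @return list of class `correlation_result`: `rho` and `p` (site x gene
#'   matrices), `n`, `skipped` (count of constant-vector pairs).
#' @export
spearman_site_gene <- function(levels, expr, max_exact = 8) {
  stopifnot(ncol(levels) == ncol(expr))
  n <- ncol(levels)
  if (n < 3) stopf("need >= 3 samples for the correlation screen")
  zs <- rank_standardise(levels)
  zg <- rank_standardise(expr)
  rho <- zs$z %*% t(zg$z)  # standardised cross-products = rho
  dimnames(rho) <- list(rownames(levels), rownames(expr))

  if (n <= max_exact) {
    perms <- permutations_n(n)
    p <- matrix(NA_real_, nrow(rho), ncol(rho), dimnames = dimnames(rho))
    ok_g <- which(!zg$constant)
    tzg <- t(zg$z[ok_g, , drop = FALSE])
    for (s in which(!zs$constant)) {
      zperm <- matrix(zs$z[s, perms], nrow(perms), n)
      null_rho <- abs(zperm %*% tzg)
      obs <- matrix(abs(rho[s, ok_g]), nrow(perms), length(ok_g),
                    byrow = TRUE)
      p[s, ok_g] <- colMeans(null_rho >= obs - 1e-12)
    }
  } else {
    # asymptotic t approximation for larger sample counts
    tstat <- rho * sqrt((n - 2) / pmax(1 - rho^2, 1e-12))
    p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  }
  skipped <- sum(zs$constant) * ncol(rho) +
    sum(zg$constant) * nrow(rho) - sum(zs$constant) * sum(zg$constant)
  structure(list(rho = rho, p = p, n = n, skipped = skipped),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat("correlation_result:", nrow(x$rho), "sites x", ncol(x$rho),
      "genes, n =", x$n, "samples,", x$skipped, "pairs skipped\n")
  invisible(x)
}

#' Benjamini-Hochberg step-up q-values
#'
#' @param pvalues numeric vector (NAs preserved).
#' @return q-values of the same length.
#' @export
bh_fdr <- function(pvalues) {
  p.adjust(pvalues, method = "BH")
}

#' Significance calls for a correlation screen
#'
#' Applies BH FDR control over the family of all tested (site, gene) pairs
#' (`family = "global"`) or per site (`family = "per_site"`).
#'
#' @param result a `correlation_result`.
#' @param alpha FDR threshold.
#' @param family `"global"` or `"per_site"`.
#' @return `result` with added `q` matrix and logical `significant` matrix
#'   (q < alpha).
#' @export
correlation_significance <- function(result, alpha = 0.05,
                                     family = c("global", "per_site")) {
  family <- match.arg(family)
  q <- result$p
  if (family == "global") {
    q[] <- bh_fdr(as.vector(result$p))
  } else {
    for (i in seq_len(nrow(q))) q[i, ] <- bh_fdr(result$p[i, ])
  }
  result$q <- q
  result$significant <- !is.na(q) & q < alpha
  result$alpha <- alpha
  result$family <- family
  result
}

#' Classify editing sites by their correlated-gene counts
#'
#' Class I: at least `n_min` significant positive genes and at least
#' `dominance` times more positive than negative. Class III: symmetric for
#' negative. Class II: everything else (few or balanced correlations).
#'
#' @param result a `correlation_result` after
#'   [correlation_significance()].
#' @param n_min minimum dominant-sign gene count for class I/III.
#' @param dominance required ratio between dominant and minor sign counts.
#' @return data.frame: site, n_pos, n_neg, class.
#' @export
classify_sites <- function(result, n_min = 5, dominance = 2.0) {
  stopifnot(!is.null(result$significant))
  sig <- result$significant
  pos <- sig & result$rho > 0
  neg <- sig & result$rho < 0
  n_pos <- rowSums(pos, na.rm = TRUE)
  n_neg <- rowSums(neg, na.rm = TRUE)
  cls <- ifelse(n_pos >= n_min & n_pos >= dominance * n_neg, "I",
         ifelse(n_neg >= n_min & n_neg >= dominance * n_pos, "III", "II"))
  data.frame(site = rownames(sig), n_pos = n_pos, n_neg = n_neg,
             class = cls, row.names = NULL, stringsAsFactors = FALSE)
}

#' Classify genes by the editing sites they correlate with
#'
#' n1 = genes significantly positively correlated with at least `k_min`
#' sites; n2 = the negative analogue. Labels: positive = n1 minus n2,
#' negative = n2 minus n1, both = n1 intersect n2, none otherwise.
#'
#' @param result a `correlation_result` after
#'   [correlation_significance()].
#' @param k_min minimum number of correlated sites.
#' @return data.frame: gene_id, m_pos, m_neg, label.
#' @export
classify_genes <- function(result, k_min = 10) {
  stopifnot(!is.null(result$significant))
  sig <- result$significant
  pos <- sig & result$rho > 0
  neg <- sig & result$rho < 0
  m_pos <- colSums(pos, na.rm = TRUE)
  m_neg <- colSums(neg, na.rm = TRUE)
  in1 <- m_pos >= k_min
  in2 <- m_neg >= k_min
  label <- ifelse(in1 & in2, "both",
           ifelse(in1, "positive", ifelse(in2, "negative", "none")))
  data.frame(gene_id = colnames(sig), m_pos = m_pos, m_neg = m_neg,
             label = label, row.names = NULL, stringsAsFactors = FALSE)
}

#' Per-class site statistics
#'
#' Mean editing level, per-site level standard deviation and nonsynonymous
#' fraction per site class, with pairwise Wilcoxon rank-sum tests on levels
#' and on standard deviations.
#'
#' @param site_classes data.frame from [classify_sites()].
#' @param levels site x sample level matrix (rows aligned by site name).
#' @param codon_classes optional character vector per site
#'   (synonymous/nonsynonymous/stop-related).
#' @return list: `summary` (per class: n, mean_level, mean_sd, nonsyn
#'   fraction), `level_p` and `sd_p` (pairwise Wilcoxon p matrices).
#' @export
class_site_stats <- function(site_classes, levels, codon_classes = NULL) {
  m <- match(site_classes$site, rownames(levels))
  site_mean <- rowMeans(levels, na.rm = TRUE)[m]
  site_sd <- apply(levels, 1, sd, na.rm = TRUE)[m]
  cl <- factor(site_classes$class, levels = c("I", "II", "III"))
  summary <- data.frame(
    class = levels(cl),
    n = as.integer(table(cl)),
    mean_level = as.numeric(tapply(site_mean, cl, mean)[levels(cl)]),
    mean_sd = as.numeric(tapply(site_sd, cl, function(x) {
      if (length(x) < 2) NA_real_ else mean(x)
    })[levels(cl)]),
    nonsyn_fraction = if (is.null(codon_classes)) NA_real_ else
      as.numeric(tapply(codon_classes == "nonsynonymous", cl,
                        mean)[levels(cl)]),
    row.names = NULL)
  pair_wilcox <- function(v) {
    nm <- levels(cl)
    pw <- matrix(NA_real_, 3, 3, dimnames = list(nm, nm))
    for (i in 1:2) for (j in (i + 1):3) {
      a <- v[cl == nm[i]]; b <- v[cl == nm[j]]
      if (length(a) > 0 && length(b) > 0) {
        pw[i, j] <- pw[j, i] <- suppressWarnings(
          wilcox.test(a, b, exact = FALSE)$p.value)
      }
    }
    pw
  }
  list(summary = summary, level_p = pair_wilcox(site_mean),
       sd_p = pair_wilcox(site_sd))
}

#' Genes whose editing sites belong to exactly one class
#'
#' A gene carrying sites of two or more classes is excluded.
#'
#' @param site_classes data.frame from [classify_sites()] (site names are
#'   `gene:pos`).
#' @return data.frame: gene_id, class, n_sites.
#' @export
class_specific_genes <- function(site_classes) {
  gene <- sub(":[0-9]+$", "", site_classes$site)
  tab <- table(gene, site_classes$class)
  n_classes <- rowSums(tab > 0)
  keep <- names(n_classes)[n_classes == 1]
  out <- do.call(rbind, lapply(keep, function(g) {
    cl <- colnames(tab)[tab[g, ] > 0]
    data.frame(gene_id = g, class = cl, n_sites = sum(tab[g, ]),
               stringsAsFactors = FALSE)
  }))
  if (is.null(out)) {
    out <- data.frame(gene_id = character(0), class = character(0),
                      n_sites = integer(0))
  }
  out[order(out$class, out$gene_id), , drop = FALSE]
}

#' Relative editing-level profiles along a gene's expression gradient
#'
#' Orders the samples by the gene's RPKM and shifts every significant
#' site's level series so its minimum is zero (profiles comparable across
#' sites).
#'
#' @param gene_id the gene.
#' @param result a `correlation_result` after significance calling.
#' @param expr gene x sample RPKM matrix.
#' @param levels site x sample level matrix.
#' @return list: `sample_order` (sample names by increasing RPKM),
#'   `profiles` (site x sample matrix of shifted levels, columns in that
#'   order).
#' @export
relative_profiles <- function(gene_id, result, expr, levels) {
  if (!gene_id %in% rownames(expr)) stopf("gene %s not in expression", gene_id)
  ord <- order(expr[gene_id, ])
  sites <- rownames(result$significant)[result$significant[, gene_id]]
  prof <- levels[sites, ord, drop = FALSE]
  prof <- prof - apply(prof, 1, min, na.rm = TRUE)
  list(sample_order = colnames(levels)[ord], profiles = prof)
}

#' 5' base composition of sites pooled per gene class
#'
#' Pools the significantly correlated sites of each gene class (positive /
#' negative / both; multiplicity removed) and reports the composition of
#' the base 5' of the edited cytidine against the background composition
#' over all called sites.
#'
#' @param gene_classes data.frame from [classify_genes()].
#' @param result a `correlation_result` after significance calling.
#' @param five_prime named character vector: -1 base per site (names =
#'   site ids).
#' @return data.frame: population (positive/negative/both/bg), base,
#'   fraction.
#' @export
five_prime_by_gene_class <- function(gene_classes, result, five_prime) {
  sig <- result$significant
  comp <- function(sites, label) {
    tab <- table(factor(five_prime[sites], levels = c("A", "C", "G", "T")))
    data.frame(population = label, base = names(tab),
               fraction = if (length(sites)) as.numeric(tab) / length(sites)
                          else NA_real_,
               stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, lapply(c("positive", "negative", "both"),
    function(lab) {
      genes <- gene_classes$gene_id[gene_classes$label == lab]
      genes <- intersect(genes, colnames(sig))
      sites <- rownames(sig)[rowSums(sig[, genes, drop = FALSE]) > 0]
      comp(sites, lab)
    }))
  rbind(out, comp(names(five_prime), "bg"))
}

#' Hypergeometric term enrichment
#'
#' For each annotation term, tests over-representation of the gene set
#' against the universe with an upper-tail hypergeometric test, and adjusts
#' with BH.
#'
#' @param gene_set character vector of genes of interest (non-empty).
#' @param universe all genes considered.
#' @param term_annotation data.frame: gene_id, term.
#' @return data.frame: term, set_hits, set_size, universe_hits,
#'   universe_size, fold_enrichment, p, q.
#' @export
term_enrichment <- function(gene_set, universe, term_annotation) {
  gene_set <- unique(gene_set)
  universe <- unique(universe)
  if (length(gene_set) == 0) stopf("empty gene set")
  gene_set <- intersect(gene_set, universe)
  ann <- term_annotation[term_annotation$gene_id %in% universe, , drop = FALSE]
  terms <- unique(ann$term)
  N <- length(universe); n <- length(gene_set)
  out <- do.call(rbind, lapply(terms, function(tm) {
    tg <- unique(ann$gene_id[ann$term == tm])
    K <- length(tg)
    k <- length(intersect(tg, gene_set))
    p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term = tm, set_hits = k, set_size = n, universe_hits = K,
               universe_size = N,
               fold_enrichment = if (k == 0) 0 else (k / n) / (K / N),
               p = p, stringsAsFactors = FALSE)
  }))
  out$q <- bh_fdr(out$p)
  out[order(out$p), , drop = FALSE]
}
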