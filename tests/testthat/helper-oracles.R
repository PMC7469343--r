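# Independent brute-force oracles used to validate the package's
# implementations. Deliberately written with different algorithms / code
# paths than the functions they check.

# All permutations of 1..n by filtering the full n^n grid (n <= 7).
all_perms <- function(n) {
  g <- as.matrix(expand.grid(rep(list(seq_len(n)), n)))
  g[apply(g, 1, function(r) length(unique(r)) == n), , drop = FALSE]
}

# Exact two-sided Spearman permutation p-value via stats::cor on every
# permutation of x.
oracle_spearman_p <- function(x, y, perms = all_perms(length(x))) {
  obs <- abs(cor(x, y, method = "spearman"))
  null <- apply(perms, 1, function(pp) {
    abs(cor(x[pp], y, method = "spearman"))
  })
  mean(null >= obs - 1e-12)
}

# BH step-up from the definition: q_i = min over j with p_(j) >= p_(i) of
# p_(j) * m / j, computed by direct search.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    rank_i <- which(o == i)
    cand <- vapply(rank_i:m, function(j) p[o[j]] * m / j, numeric(1))
    q[i] <- min(1, min(cand))
  }
  q
}

# Two-sided Fisher exact p for a 2x2 table by hypergeometric enumeration
# with exact binomial-coefficient arithmetic (log scale). Uses R's
# two-sided convention: sum the probabilities of all tables (same margins)
# not exceeding the observed one by more than a factor 1 + 1e-7.
oracle_fisher_p <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  lo <- max(0, k - n); hi <- min(k, m)
  lp <- vapply(lo:hi, function(x) {
    lchoose(m, x) + lchoose(n, k - x) - lchoose(m + n, k)
  }, numeric(1))
  pr <- exp(lp - max(lp))
  pr <- pr / sum(pr)
  p_obs <- pr[a - lo + 1]
  sum(pr[pr <= p_obs * (1 + 1e-7)])
}

# Maximum base pairs by exhaustive enumeration of all non-crossing
# structures (exponential; sequences <= ~14 nt).
oracle_max_pairs <- function(seq, min_loop = 3) {
  ch <- strsplit(toupper(chartr("U", "T", seq)), "")[[1]]
  pairable <- function(x, y) {
    s <- paste0(sort(c(x, y)), collapse = "")
    s %in% c("AT", "CG", "GT")
  }
  count_best <- function(avail) {
    if (length(avail) < min_loop + 2) return(0L)
    i <- avail[1]
    b <- count_best(avail[-1])  # i unpaired
    for (j in avail[-1]) {
      if (j - i <= min_loop || !pairable(ch[i], ch[j])) next
      inside <- avail[avail > i & avail < j]
      outside <- avail[avail > j]
      v <- 1L + count_best(inside) + count_best(outside)
      if (v > b) b <- v
    }
    b
  }
  count_best(seq_along(ch))
}

# Row-by-row predicate scan equivalent of call_variants, written naively.
oracle_variant_scan <- function(pileup, min_depth = 10, min_level = 0.05,
                                second_alt_min_reads = 2,
                                second_alt_min_frac = 0.01) {
  bases <- c("A", "C", "G", "T")
  keep <- list()
  for (i in seq_len(nrow(pileup))) {
    row <- pileup[i, ]
    if (!row$ref %in% bases) next
    counts <- c(A = row$A, C = row$C, G = row$G, T = row$T)
    depth <- sum(counts)
    alts <- counts[setdiff(bases, row$ref)]
    present <- alts[alts >= second_alt_min_reads &
                    alts >= second_alt_min_frac * depth]
    top_base <- names(alts)[which.max(alts)]
    top <- max(alts)
    level <- if (depth > 0) top / depth else 0
    n_other <- sum(names(present) != top_base)
    if (depth >= min_depth && level > min_level && n_other == 0) {
      keep[[length(keep) + 1]] <- data.frame(
        gene_id = row$gene_id, pos = row$pos, ref = row$ref,
        alt = top_base, depth = depth, alt_count = top,
        level = level, sample = row$sample, stringsAsFactors = FALSE)
    }
  }
  if (length(keep) == 0) {
    return(data.frame(gene_id = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      depth = numeric(0), alt_count = numeric(0),
                      level = numeric(0), sample = character(0)))
  }
  do.call(rbind, keep)
}

# Codon-effect oracle: mutate the full CDS string and translate both
# versions with Biostrings.
oracle_codon_class <- function(pos, cds_seq) {
  alt <- cds_seq
  substr(alt, pos, pos) <- "T"
  aa_ref <- as.character(Biostrings::translate(
    Biostrings::DNAString(cds_seq), no.init.codon = TRUE))
  aa_alt <- as.character(Biostrings::translate(
    Biostrings::DNAString(alt), no.init.codon = TRUE))
  d <- which(strsplit(aa_ref, "")[[1]] != strsplit(aa_alt, "")[[1]])
  if (length(d) == 0) return("synonymous")
  r <- substr(aa_ref, d, d); a <- substr(aa_alt, d, d)
  if (r == "*" || a == "*") "stop-related" else "nonsynonymous"
}
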