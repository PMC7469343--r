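#' Extract the sequence context around an edited cytidine
#'
#' Returns the `2k + 1`-mer centred on the site; positions outside the CDS
#' are padded with `N` (and excluded from composition profiles).
#'
#' @param pos 1-based CDS position of the site (must be a C).
#' @param cds_seq the CDS sequence.
#' @param k flanking width on each side.
#' @return character string of length `2k + 1`.
#' @export
extract_context <- function(pos, cds_seq, k = 4) {
  L <- nchar(cds_seq)
  if (pos < 1 || pos > L) stopf("site position %d outside CDS (1..%d)", pos, L)
  if (substr(cds_seq, pos, pos) != "C") {
    stopf("reference base at position %d is not C", pos)
  }
  idx <- (pos - k):(pos + k)
  ch <- ifelse(idx < 1 | idx > L, "N",
               vapply(idx, function(i) substr(cds_seq, i, i), character(1)))
  paste(ch, collapse = "")
}

#' Per-offset base composition of site contexts
#'
#' @param contexts character vector of equal-length context strings (odd
#'   length, centre excluded from the profile).
#' @param label population label attached to the profile.
#' @return data.frame of class `motif_profile`: offset (-k..k without 0),
#'   base, fraction. `N` padding is excluded from the denominators.
#' @export
composition_profile <- function(contexts, label = "edited") {
  stopifnot(length(contexts) >= 1)
  w <- unique(nchar(contexts))
  if (length(w) != 1 || w %% 2 != 1) {
    stopf("contexts must share one odd length")
  }
  k <- (w - 1) / 2
  mat <- do.call(rbind, strsplit(contexts, ""))
  offsets <- setdiff(-k:k, 0)
  out <- do.call(rbind, lapply(offsets, function(o) {
    col <- mat[, o + k + 1]
    col <- col[col != "N"]
    if (length(col) == 0) {
      return(data.frame(offset = o, base = c("A", "C", "G", "T"),
                        fraction = NA_real_))
    }
    tab <- table(factor(col, levels = c("A", "C", "G", "T")))
    data.frame(offset = o, base = names(tab),
               fraction = as.numeric(tab) / length(col))
  }))
  out$population <- label
  class(out) <- c("motif_profile", "data.frame")
  out
}

#' Overall base composition of a CDS set (background profile)
#'
#' @param cds_set named character vector of CDS sequences.
#' @return named fractions over A/C/G/T.
#' @export
background_profile <- function(cds_set) {
  ch <- strsplit(paste(cds_set, collapse = ""), "")[[1]]
  tab <- table(factor(ch, levels = c("A", "C", "G", "T")))
  setNames(as.numeric(tab) / sum(tab), c("A", "C", "G", "T"))
}

#' Editing level grouped by a flanking base
#'
#' Groups sites by the base at `offset` (e.g. -1 for the 5' neighbour) and
#' compares per-site mean levels between groups with pairwise two-sided
#' Wilcoxon rank-sum tests. A site's level is its mean across samples.
#'
#' @param contexts per-site context strings (as from [extract_context()]).
#' @param levels site x sample level matrix (rows aligned with `contexts`).
#' @param offset flanking offset (negative = 5').
#' @return list: `groups` (named list of per-site mean levels), `medians`,
#'   `pairwise_p` (matrix of Wilcoxon p-values), `dropped` (empty groups).
#' @export
level_by_flanking_base <- function(contexts, levels, offset = -1) {
  stopifnot(length(contexts) == nrow(levels))
  k <- (nchar(contexts[1]) - 1) / 2
  if (abs(offset) > k || offset == 0) stopf("offset out of context range")
  b <- substr(contexts, offset + k + 1, offset + k + 1)
  site_level <- rowMeans(levels, na.rm = TRUE)
  groups <- split(site_level, factor(b, levels = c("A", "C", "G", "T")))
  dropped <- names(groups)[vapply(groups, length, 1L) == 0]
  groups <- groups[vapply(groups, length, 1L) > 0]
  nm <- names(groups)
  pw <- matrix(NA_real_, length(nm), length(nm), dimnames = list(nm, nm))
  if (length(nm) > 1) {
    for (i in seq_along(nm)[-length(nm)]) {
      for (j in (i + 1):length(nm)) {
        p <- suppressWarnings(
          wilcox.test(groups[[i]], groups[[j]], exact = FALSE)$p.value)
        pw[i, j] <- pw[j, i] <- p
      }
    }
  }
  list(groups = groups,
       medians = vapply(groups, stats::median, numeric(1)),
       pairwise_p = pw, dropped = dropped)
}

#' Codon consequence of a C-to-U edit
#'
#' @param pos 1-based CDS position of the edited C.
#' @param cds_seq the CDS (length divisible by 3).
#' @return data.frame: codon_index, pos_in_codon, ref_codon, alt_codon,
#'   ref_aa, alt_aa, class (synonymous / nonsynonymous / stop-related).
#' @export
#' @examples
#' # ACA (Thr) -> ATA (Ile), nonsynonymous
#' annotate_codon_effect(5, "ATGACATAA")
annotate_codon_effect <- function(pos, cds_seq) {
  L <- nchar(cds_seq)
  if (L %% 3 != 0) stopf("CDS length %d not divisible by 3", L)
  if (pos < 1 || pos > L) stopf("position outside CDS")
  if (substr(cds_seq, pos, pos) != "C") {
    stopf("reference base at position %d is not C", pos)
  }
  codon_index <- ceiling(pos / 3)
  pos_in_codon <- pos - 3 * (codon_index - 1)
  ref_codon <- substr(cds_seq, 3 * codon_index - 2, 3 * codon_index)
  alt_codon <- ref_codon
  substr(alt_codon, pos_in_codon, pos_in_codon) <- "T"
  code <- Biostrings::GENETIC_CODE  # DNA-alphabet codons, standard code
  ref_aa <- unname(code[ref_codon])
  alt_aa <- unname(code[alt_codon])
  cls <- if (ref_aa == alt_aa) {
    "synonymous"
  } else if (ref_aa == "*" || alt_aa == "*") {
    "stop-related"
  } else {
    "nonsynonymous"
  }
  data.frame(codon_index = codon_index, pos_in_codon = pos_in_codon,
             ref_codon = ref_codon, alt_codon = alt_codon,
             ref_aa = ref_aa, alt_aa = alt_aa, class = cls,
             stringsAsFactors = FALSE)
}

#' All unedited cytidines of CDSs carrying at least one editing site
#'
#' The comparison population for context and structure analyses: every C in
#' an edited CDS that is not itself a called site (keeps compartment
#' composition comparable between populations).
#'
#' @param site_set an `editing_site_set`.
#' @param sequences named CDS character vector.
#' @return data.frame: gene_id, pos.
#' @export
unedited_cytidines <- function(site_set, sequences) {
  genes <- unique(site_set$sites$gene_id)
  out <- do.call(rbind, lapply(genes, function(g) {
    s <- strsplit(sequences[[g]], "")[[1]]
    cs <- which(s == "C")
    edited <- site_set$sites$pos[site_set$sites$gene_id == g]
    cs <- setdiff(cs, edited)
    if (length(cs) == 0) return(NULL)
    data.frame(gene_id = g, pos = cs, stringsAsFactors = FALSE)
  }))
  if (is.null(out)) {
    out <- data.frame(gene_id = character(0), pos = integer(0))
  }
  out
}
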