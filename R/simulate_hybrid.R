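#' Generate an interspecies-hybrid allele pair with allele-exclusive editing
#'
#' Emulates the hybrid setting in which two diverged parental alleles share
#' one trans environment. Allele A is the reference CDS; allele B carries
#' per-nt substitutions at rate `hybrid_divergence` (never at the designated
#' editing positions, which stay C on both alleles). Each designated site is
#' fully edited on exactly one allele and unedited on the other. Per-allele
#' pileups (error-free C/T counts) and fixed-length reads carrying the
#' allele-diagnostic substitutions are emitted.
#'
#' @param ref a `reference_set`.
#' @param config the [sim_config()].
#' @param truth optional `truth_table`; when given, hybrid sites are drawn
#'   from its true sites, otherwise cytidines are picked de novo on the
#'   first organellar CDSs.
#' @return list of class `hybrid_set`: `alleles` (per gene: list with `A`,
#'   `B` sequences), `sites` (gene_id, pos, edited_allele), `pileups`
#'   (per-allele C/T counts per site), `reads` (read_id, gene_id,
#'   allele_true, start, seq).
#' @export
generate_hybrid <- function(ref, config, truth = NULL) {
  validate_sim_config(config)
  ann <- ref$annotation
  org <- ann$gene_id[ann$compartment != "nuclear"]

  with_seed(stage_seed(config$seed, 5L), {
    if (!is.null(truth)) {
      ns <- min(config$n_hybrid_sites, nrow(truth$sites))
      pick <- sample(nrow(truth$sites), ns)
      sites <- truth$sites[pick, c("gene_id", "pos")]
    } else {
      sites <- data.frame(gene_id = character(0), pos = integer(0))
      for (g in org) {
        s <- strsplit(ref$sequences[[g]], "")[[1]]
        cs <- which(s == "C")
        cs <- cs[cs >= 2]
        take <- head(cs, config$n_hybrid_sites - nrow(sites))
        if (length(take)) {
          sites <- rbind(sites, data.frame(gene_id = g, pos = take))
        }
        if (nrow(sites) >= config$n_hybrid_sites) break
      }
    }
    rownames(sites) <- NULL
    sites$edited_allele <- sample(c("A", "B"), nrow(sites), replace = TRUE)

    genes <- unique(sites$gene_id)
    alleles <- lapply(setNames(genes, genes), function(g) {
      a <- strsplit(ref$sequences[[g]], "")[[1]]
      b <- a
      protect <- sites$pos[sites$gene_id == g]
      subs <- which(runif(length(b)) < config$hybrid_divergence)
      subs <- setdiff(subs, protect)
      for (i in subs) b[i] <- sample(setdiff(c("A", "C", "G", "T"), b[i]), 1)
      list(A = paste(a, collapse = ""), B = paste(b, collapse = ""))
    })

    dr <- config$depth_range
    pileups <- do.call(rbind, lapply(seq_len(nrow(sites)), function(i) {
      dA <- sample(dr[1]:dr[2], 1)
      dB <- sample(dr[1]:dr[2], 1)
      ea <- sites$edited_allele[i]
      data.frame(gene_id = sites$gene_id[i], pos = sites$pos[i],
                 edited_allele = ea,
                 C_A = if (ea == "A") 0L else dA,
                 T_A = if (ea == "A") dA else 0L,
                 C_B = if (ea == "B") 0L else dB,
                 T_B = if (ea == "B") dB else 0L,
                 stringsAsFactors = FALSE)
    }))

    rl <- config$read_length
    reads <- do.call(rbind, lapply(genes, function(g) {
      al <- alleles[[g]]
      L <- nchar(al$A)
      if (L < rl) return(NULL)
      n_reads <- max(20L, ceiling(4 * L / rl))  # ~4x coverage per allele
      do.call(rbind, lapply(c("A", "B"), function(which_a) {
        st <- sample.int(L - rl + 1L, n_reads, replace = TRUE)
        seqs <- vapply(st, function(s0) {
          chars <- strsplit(substr(al[[which_a]], s0, s0 + rl - 1L), "")[[1]]
          # apply editing: site positions edited on this allele read as T
          sp <- sites$pos[sites$gene_id == g &
                          sites$edited_allele == which_a]
          hit <- sp[sp >= s0 & sp <= s0 + rl - 1L]
          if (length(hit)) chars[hit - s0 + 1L] <- "T"
          paste(chars, collapse = "")
        }, character(1))
        data.frame(gene_id = g, allele_true = which_a, start = st,
                   seq = seqs, stringsAsFactors = FALSE)
      }))
    }))
    if (!is.null(reads)) {
      reads <- data.frame(read_id = sprintf("r%06d", seq_len(nrow(reads))),
                          reads, stringsAsFactors = FALSE)
    }

    structure(list(alleles = alleles, sites = sites, pileups = pileups,
                   reads = reads),
              class = "hybrid_set")
  })
}

#' @export
print.hybrid_set <- function(x, ...) {
  cat("hybrid_set:", length(x$alleles), "genes,", nrow(x$sites),
      "allele-exclusive sites,",
      if (is.null(x$reads)) 0 else nrow(x$reads), "reads\n")
  invisible(x)
}

#' Synthetic worked example: NADH dehydrogenase subunit 4-like CDS
#'
#' Constructs a synthetic stand-in for the mitochondrial nad4 CDS worked
#' example: a 570-nt CDS whose codon 121 is ACA (so the C at position 362
#' is codon position 2; C-to-U gives AUA, Thr->Ile) and whose codon 126 is
#' CGT (C at position 376 is codon position 1; C-to-U gives UGU... i.e.
#' CGU->UGU, Arg->Cys). The surrounding codons are arbitrary non-stop
#' codons; only the two annotated positions matter.
#'
#' @return list: `cds` (character), `sites` (positions 362 and 376),
#'   `depths` (allele A = 103, allele B = 31 covering reads).
#' @export
hybrid_example <- function() {
  codons <- rep(c("GCT", "GAA", "TTC", "GGA", "CTT", "AAC"), length.out = 190)
  codons[1] <- "ATG"
  codons[121] <- "ACA"
  codons[126] <- "CGT"
  list(cds = paste(codons, collapse = ""),
       sites = c(362L, 376L),
       depths = c(A = 103L, B = 31L))
}
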