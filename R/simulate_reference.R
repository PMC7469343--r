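#' Generate a synthetic CDS reference set
#'
#' Draws `n_genes` coding sequences over A/C/G/T, each starting with ATG and
#' with length a multiple of 3 inside `gene_length_range`. The first
#' `n_mito_genes` are labelled mitochondrial, the next `n_chloro_genes`
#' chloroplast, the rest nuclear. Editing sites are later placed on the
#' organellar CDSs only; nuclear genes enter the analysis through the
#' expression matrix.
#'
#' @param config a [sim_config()].
#' @return list of class `reference_set`: `sequences` (named character
#'   vector), `annotation` (data.frame: gene_id, compartment, length).
#' @export
generate_reference <- function(config) {
  validate_sim_config(config)
  with_seed(stage_seed(config$seed, 1L), {
    n <- config$n_genes
    lo <- config$gene_length_range[1] %/% 3L
    hi <- config$gene_length_range[2] %/% 3L
    n_codons <- if (lo == hi) rep(lo, n) else sample(lo:hi, n, replace = TRUE)
    lens <- 3L * n_codons
    comp <- rep("nuclear", n)
    if (config$n_mito_genes > 0) comp[seq_len(config$n_mito_genes)] <- "mito"
    if (config$n_chloro_genes > 0) {
      comp[config$n_mito_genes + seq_len(config$n_chloro_genes)] <- "chloro"
    }
    prefix <- c(mito = "SMG", chloro = "SCG", nuclear = "SNG")[comp]
    ids <- sprintf("%s%05d", prefix, seq_len(n))
    seqs <- vapply(lens, function(L) {
      paste0("ATG", paste(sample(c("A", "C", "G", "T"), L - 3L,
                                 replace = TRUE), collapse = ""))
    }, character(1))
    names(seqs) <- ids
    structure(list(sequences = seqs,
                   annotation = data.frame(gene_id = ids, compartment = comp,
                                           length = lens,
                                           stringsAsFactors = FALSE)),
              class = "reference_set")
  })
}

#' @export
print.reference_set <- function(x, ...) {
  tb <- table(x$annotation$compartment)
  cat("reference_set:", length(x$sequences), "CDS (",
      paste(names(tb), tb, collapse = ", "), "),",
      sum(x$annotation$length), "nt total\n")
  invisible(x)
}

#' Write / read a reference set as FASTA plus annotation TSV
#'
#' @param ref a `reference_set`.
#' @param fasta,annotation output file paths.
#' @return `write_reference` returns the paths invisibly; `read_reference`
#'   returns a `reference_set`.
#' @export
write_reference <- function(ref, fasta, annotation) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(ref$sequences), fasta)
  write.table(ref$annotation, annotation, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(c(fasta = fasta, annotation = annotation))
}

#' @rdname write_reference
#' @export
read_reference <- function(fasta, annotation) {
  ss <- Biostrings::readDNAStringSet(fasta)
  seqs <- as.character(ss)
  names(seqs) <- sub("\\s.*$", "", names(ss))
  ann <- read.delim(annotation, stringsAsFactors = FALSE)
  structure(list(sequences = seqs, annotation = ann),
            class = "reference_set")
}
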