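#' Generate per-sample pileup base-count tables
#'
#' Emits quality-filtered base counts per (gene, position, sample) for the
#' organellar CDSs (where editing sites live). Depth is uniform on
#' `depth_range`; at a true site the T count is Binomial(depth, true level)
#' and C = depth - T; at other positions each non-reference base receives
#' Binomial(depth, error_rate / 3) sequencing-error reads.
#'
#' @param ref a `reference_set`.
#' @param truth the matching `truth_table`.
#' @param config the [sim_config()].
#' @return data.frame (class `pileup_table`): gene_id, pos, ref, A, C, G, T,
#'   sample. Counts always sum to depth.
#' @export
generate_pileups <- function(ref, truth, config) {
  validate_sim_config(config)
  ann <- truth$annotation
  org <- ann$gene_id[ann$compartment != "nuclear"]
  bases <- c("A", "C", "G", "T")

  pos_tab <- do.call(rbind, lapply(org, function(g) {
    s <- strsplit(ref$sequences[[g]], "")[[1]]
    data.frame(gene_id = g, pos = seq_along(s), ref = s,
               stringsAsFactors = FALSE)
  }))
  np <- nrow(pos_tab)
  key <- paste0(pos_tab$gene_id, ":", pos_tab$pos)
  site_row <- match(paste0(truth$sites$gene_id, ":", truth$sites$pos), key)
  stopifnot(!anyNA(site_row))

  with_seed(stage_seed(config$seed, 3L), {
    out <- vector("list", length(config$samples))
    for (si in seq_along(config$samples)) {
      depth <- sample(config$depth_range[1]:config$depth_range[2], np,
                      replace = TRUE)
      cnt <- matrix(0L, np, 4, dimnames = list(NULL, bases))
      # sequencing errors at non-site positions
      err <- matrix(rbinom(np * 3L, depth, config$error_rate / 3), np, 3)
      err[rowSums(err) > depth, ] <- 0L
      total_err <- rowSums(err)
      ref_idx <- match(pos_tab$ref, bases)
      for (b in 1:4) {
        rows <- which(ref_idx == b)
        cnt[rows, b] <- depth[rows] - total_err[rows]
        alt <- setdiff(1:4, b)
        for (k in 1:3) cnt[rows, alt[k]] <- err[rows, k]
      }
      # true sites: clean C/T split at the true level
      tt <- rbinom(length(site_row), depth[site_row],
                   truth$levels[, si])
      cnt[site_row, ] <- 0L
      cnt[site_row, "T"] <- tt
      cnt[site_row, "C"] <- depth[site_row] - tt
      out[[si]] <- data.frame(pos_tab, cnt,
                              sample = config$samples[si],
                              stringsAsFactors = FALSE)
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    class(res) <- c("pileup_table", "data.frame")
    res
  })
}

#' Write / read a pileup table as TSV
#' @param pileup a `pileup_table` data.frame.
#' @param path file path.
#' @export
write_pileup <- function(pileup, path) {
  write.table(pileup, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pileup
#' @export
read_pileup <- function(path) {
  p <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "pos", "ref", "A", "C", "G", "T", "sample")
  if (!all(need %in% names(p))) {
    stopf("pileup file missing columns: %s",
          paste(setdiff(need, names(p)), collapse = ", "))
  }
  class(p) <- c("pileup_table", "data.frame")
  p
}
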