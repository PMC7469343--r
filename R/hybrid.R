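#' Assign a read to one of two parental alleles
#'
#' A read is assigned to allele A when it matches allele A exactly and
#' mismatches allele B at one or more positions (and symmetrically for B);
#' otherwise it is `"ambiguous"`. At catalogued editing positions
#' (`known_c_sites`, where the allele carries C) both C and T are accepted,
#' so editing itself cannot break the assignment.
#'
#' @param read_seq read sequence (gapless alignment assumed).
#' @param read_start 1-based start of the read on both alleles.
#' @param alleleA_seq,alleleB_seq full allele sequences.
#' @param known_c_sites integer positions (allele coordinates) of known
#'   editable cytidines.
#' @return `"A"`, `"B"` or `"ambiguous"`.
#' @export
assign_read_to_allele <- function(read_seq, read_start, alleleA_seq,
                                  alleleB_seq, known_c_sites = integer(0)) {
  rl <- nchar(read_seq)
  if (read_start < 1 || read_start + rl - 1L > nchar(alleleA_seq) ||
      read_start + rl - 1L > nchar(alleleB_seq)) {
    stopf("read outside allele sequence bounds")
  }
  rch <- strsplit(read_seq, "")[[1]]
  matches <- function(allele_seq) {
    ach <- strsplit(substr(allele_seq, read_start,
                           read_start + rl - 1L), "")[[1]]
    ok <- rch == ach
    # tolerate C->T at catalogued C sites
    for (k in which(!ok)) {
      p <- read_start + k - 1L
      if (p %in% known_c_sites && ach[k] == "C" && rch[k] %in% c("C", "T")) {
        ok[k] <- TRUE
      }
    }
    all(ok)
  }
  mA <- matches(alleleA_seq)
  mB <- matches(alleleB_seq)
  if (mA && !mB) "A" else if (mB && !mA) "B" else "ambiguous"
}

#' Call species-specific editing from per-allele C/T counts
#'
#' Quantifies "fully edited" / "completely unedited" as level at or above
#' `edited_min` / at or below `unedited_max`. A site is `A_specific` when
#' allele A is fully edited, allele B unedited, and both allele depths reach
#' `min_depth`; symmetrically `B_specific`; `shared` when both alleles are
#' fully edited; otherwise `undetermined`.
#'
#' @param c_a,t_a C and T read counts on allele A.
#' @param c_b,t_b counts on allele B.
#' @param min_depth minimum covering reads per allele.
#' @param edited_min,unedited_max level thresholds.
#' @return data.frame (one row): level_A, level_B, depth_A, depth_B, status.
#' @export
#' @examples
#' call_species_specific(0, 103, 31, 0)  # fully edited A, unedited B
call_species_specific <- function(c_a, t_a, c_b, t_b, min_depth = 10,
                                  edited_min = 0.95, unedited_max = 0.05) {
  stopifnot(c_a >= 0, t_a >= 0, c_b >= 0, t_b >= 0)
  depth_a <- c_a + t_a
  depth_b <- c_b + t_b
  level_a <- if (depth_a > 0) t_a / depth_a else NA_real_
  level_b <- if (depth_b > 0) t_b / depth_b else NA_real_
  status <- if (depth_a < min_depth || depth_b < min_depth) {
    "undetermined"
  } else if (level_a >= edited_min && level_b <= unedited_max) {
    "A_specific"
  } else if (level_b >= edited_min && level_a <= unedited_max) {
    "B_specific"
  } else if (level_a >= edited_min && level_b >= edited_min) {
    "shared"
  } else {
    "undetermined"
  }
  data.frame(level_A = level_a, level_B = level_b,
             depth_A = depth_a, depth_B = depth_b, status = status,
             stringsAsFactors = FALSE)
}

#' Hybrid calls for a table of per-allele site counts
#'
#' @param pileups data.frame with columns gene_id, pos, C_A, T_A, C_B, T_B
#'   (as emitted by [generate_hybrid()]).
#' @param ... thresholds passed to [call_species_specific()].
#' @return data.frame of hybrid calls, one row per site.
#' @export
call_hybrid_sites <- function(pileups, ...) {
  calls <- do.call(rbind, lapply(seq_len(nrow(pileups)), function(i) {
    call_species_specific(pileups$C_A[i], pileups$T_A[i],
                          pileups$C_B[i], pileups$T_B[i], ...)
  }))
  cbind(pileups[, c("gene_id", "pos")], calls)
}
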