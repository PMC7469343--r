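#' Local RNA secondary structure by base-pair maximisation
#'
#' Partitions a CDS into structured (base-paired) and single-stranded
#' regions. Each non-overlapping window of `window` nt is folded with a
#' Nussinov-style maximum-pairing dynamic program (Watson-Crick plus G.U
#' pairs, minimum hairpin loop of `min_loop` nt). Maximal runs of stacked
#' pairs (helices) of at least `min_helix` pairs are reported as structured
#' regions; when a helix closes a terminal hairpin loop the loop positions
#' are included in the region (controlled by `loops_structured`).
#'
#' The score reported per region is a pairing-density score
#' (`-helix_length / window`); it is *not* a thermodynamic energy Z-score.
#' Lower means more structured, matching the convention of keeping regions
#' with negative scores.
#'
#' @param seq a single character string over A/C/G/T/U.
#' @param window fold window size (nt); windows tile the sequence.
#' @param min_helix minimum stacked pairs for a reported helix.
#' @param min_loop minimum hairpin loop length (nt).
#' @param loops_structured logical; count terminal hairpin loops as
#'   structured.
#' @return list with `dotbracket` (string, same length as `seq`) and
#'   `regions` (data.frame: start, end, score, source), 1-based inclusive
#'   coordinates.
#' @export
#' @examples
#' fold_local("GGGAAACCC")$regions
fold_local <- function(seq, window = 150L, min_helix = 3L, min_loop = 3L,
                       loops_structured = TRUE) {
  if (window < 2 * min_helix + min_loop) {
    stopf("window (%d) smaller than 2*min_helix + min_loop", window)
  }
  codes <- encode_rna(seq)
  n <- length(codes)
  partner <- integer(n)
  starts <- seq.int(1L, n, by = window)
  for (s in starts) {
    e <- min(s + window - 1L, n)
    if (e - s + 1L < min_loop + 2L) next
    p <- nussinov_pairs(codes[s:e], as.integer(min_loop))
    idx <- which(p > 0L)
    partner[s + idx - 1L] <- p[idx] + s - 1L
  }
  db <- rep(".", n)
  db[partner > seq_len(n)] <- "("
  db[partner > 0L & partner < seq_len(n)] <- ")"
  regions <- helix_regions(partner, min_helix, loops_structured, window)
  list(dotbracket = paste(db, collapse = ""), regions = regions)
}

encode_rna <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1)
  ch <- strsplit(toupper(chartr("U", "T", seq)), "")[[1]]
  codes <- match(ch, c("A", "C", "G", "T")) - 1L
  if (anyNA(codes)) stopf("sequence contains non-ACGTU characters")
  codes
}

# Extract maximal stacked-helix runs from a partner vector.
helix_regions <- function(partner, min_helix, loops_structured, window) {
  n <- length(partner)
  opens <- which(partner > seq_len(n))
  starts <- integer(0); ends <- integer(0); scores <- numeric(0)
  i_run <- 0L
  run <- integer(0)
  for (i in opens) {
    if (length(run) > 0 && i == run[length(run)] + 1L &&
        partner[i] == partner[run[length(run)]] - 1L) {
      run <- c(run, i)
    } else {
      res <- close_run(run, partner, min_helix, loops_structured, window)
      starts <- c(starts, res$s); ends <- c(ends, res$e)
      scores <- c(scores, res$score)
      run <- i
    }
  }
  res <- close_run(run, partner, min_helix, loops_structured, window)
  starts <- c(starts, res$s); ends <- c(ends, res$e)
  scores <- c(scores, res$score)
  data.frame(start = starts, end = ends, score = scores,
             source = rep("builtin", length(starts)),
             stringsAsFactors = FALSE)
}

close_run <- function(run, partner, min_helix, loops_structured, window) {
  none <- list(s = integer(0), e = integer(0), score = numeric(0))
  k <- length(run)
  if (k < min_helix) return(none)
  i1 <- run[1]; ik <- run[k]
  j1 <- partner[i1]; jk <- partner[ik]
  score <- -k / window
  # terminal hairpin: nothing paired strictly inside the innermost pair
  inner <- if (jk - ik > 1) partner[(ik + 1):(jk - 1)] else integer(0)
  terminal <- all(inner == 0L)
  if (loops_structured && terminal) {
    list(s = i1, e = j1, score = score)
  } else {
    list(s = c(i1, jk), e = c(ik, j1), score = c(score, score))
  }
}

#' Parse an RNALfold-style local-structure output file
#'
#' Reads lines of the dialect `"((((...)))) ( -5.40) 17 z= -1.20"`
#' (dot-bracket, free energy in parentheses, 1-based start position,
#' optional z-score) and returns the structured regions with score < 0.
#'
#' @param path file path.
#' @param gene_id gene identifier attached to the regions.
#' @return data.frame of regions (gene_id, start, end, score, source).
#' @export
#' @examples
#' f <- system.file("extdata", "example_rnalfold.txt", package = "cuedit")
#' parse_fold_regions(f, gene_id = "example")
parse_fold_regions <- function(path, gene_id = NA_character_) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  out <- data.frame(gene_id = character(0), start = integer(0),
                    end = integer(0), score = numeric(0),
                    source = character(0), stringsAsFactors = FALSE)
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (!grepl("^[.()]+\\s", ln)) {
      # a bare sequence line (RNALfold echoes the input) is skipped
      if (grepl("^[ACGTUNacgtun]+$", ln) || grepl("^>", ln)) next
      stopf("malformed fold line %d: %s", i, ln)
    }
    m <- regmatches(ln, regexec(
      "^([.()]+)\\s+\\(\\s*(-?[0-9.]+)\\)\\s+(\\d+)(?:\\s+z=\\s*(-?[0-9.]+))?",
      ln))[[1]]
    if (length(m) == 0) stopf("malformed fold line %d: %s", i, ln)
    db <- m[2]
    start <- as.integer(m[4])
    score <- if (m[5] != "") as.numeric(m[5]) else as.numeric(m[3])
    if (score < 0) {
      out <- rbind(out, data.frame(
        gene_id = gene_id, start = start,
        end = start + nchar(db) - 1L, score = score, source = "external",
        stringsAsFactors = FALSE))
    }
  }
  out
}

#' Merge structured regions within a CDS and compute structure%
#'
#' @param regions data.frame with `start`, `end` (1-based inclusive).
#' @param cds_length CDS length in nt.
#' @param gene_id identifier for the summary row.
#' @return list with `gene_id`, `merged_regions` (disjoint, sorted) and
#'   `structure_percent` (total structured length / CDS length).
#' @export
merge_regions <- function(regions, cds_length, gene_id = NA_character_) {
  stopifnot(cds_length >= 1)
  if (nrow(regions) == 0) {
    return(list(gene_id = gene_id,
                merged_regions = data.frame(start = integer(0),
                                            end = integer(0)),
                structure_percent = 0))
  }
  if (any(regions$start > regions$end) || any(regions$start < 1) ||
      any(regions$end > cds_length)) {
    stopf("region outside CDS bounds")
  }
  o <- order(regions$start, regions$end)
  s <- regions$start[o]; e <- regions$end[o]
  ms <- s[1]; me <- e[1]
  outs <- integer(0); oute <- integer(0)
  for (i in seq_along(s)[-1]) {
    if (s[i] <= me + 1L) {
      me <- max(me, e[i])
    } else {
      outs <- c(outs, ms); oute <- c(oute, me)
      ms <- s[i]; me <- e[i]
    }
  }
  outs <- c(outs, ms); oute <- c(oute, me)
  list(gene_id = gene_id,
       merged_regions = data.frame(start = outs, end = oute),
       structure_percent = sum(oute - outs + 1) / cds_length)
}

#' Do edited cytidines avoid structured regions?
#'
#' Builds the 2x2 table (edited/unedited x structured/unstructured) and
#' tests association with a two-sided Fisher exact test.
#'
#' @param edited_structured logical vector: for each edited site, is it
#'   inside a merged structured region?
#' @param unedited_structured logical vector over the unedited cytidines.
#' @return list with `table` (2x2 matrix), `edited_fraction`,
#'   `unedited_fraction`, and `p_value`.
#' @export
structure_overlap_test <- function(edited_structured, unedited_structured) {
  if (length(edited_structured) == 0 || length(unedited_structured) == 0) {
    stopf("both site populations must be non-empty")
  }
  tab <- matrix(c(sum(edited_structured), sum(!edited_structured),
                  sum(unedited_structured), sum(!unedited_structured)),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("edited", "unedited"),
                                c("structured", "unstructured")))
  list(table = tab,
       edited_fraction = mean(edited_structured),
       unedited_fraction = mean(unedited_structured),
       p_value = fisher.test(tab)$p.value)
}

#' Are positions inside a set of merged regions?
#'
#' @param pos integer positions (1-based).
#' @param merged data.frame with `start`, `end` columns (disjoint or not).
#' @return logical vector along `pos`.
#' @export
positions_in_regions <- function(pos, merged) {
  if (nrow(merged) == 0) return(rep(FALSE, length(pos)))
  vapply(pos, function(p) any(p >= merged$start & p <= merged$end), logical(1))
}
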