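#' Flag duplicate reads
#'
#' Marks PCR/optical duplicate reads before pileup, in the spirit of
#' Picard MarkDuplicates. Proper mate pairs are grouped on fragment
#' coordinates (reference, leftmost fragment start, fragment length);
#' single-end reads and unpaired mates on (reference, start, strand,
#' reference span). Within a group the fragment with the highest total
#' base quality is kept; all other reads get `is_duplicate = TRUE`.
#' Downstream pileups exclude flagged reads.
#'
#' @param reads A `read_alignments` data.frame (any order; both mates of
#'   a pair must be present for fragment grouping).
#' @return The same table with `is_duplicate` set.
#' @export
mark_duplicates <- function(reads) {
  if (nrow(reads) == 0L) return(reads)
  span <- cigar_ref_span(reads$cigar)
  end <- reads$start + span

  ## fragment-level table
  frag <- split(seq_len(nrow(reads)), reads$frag_id)
  fid <- names(frag)
  qsum_read <- vapply(seq_len(nrow(reads)),
                      function(i) sum(qual_ints(reads$qual[i])), numeric(1))
  key <- character(length(frag))
  qsum <- numeric(length(frag))
  for (k in seq_along(frag)) {
    idx <- frag[[k]]
    qsum[k] <- sum(qsum_read[idx])
    if (length(idx) == 2L && all(reads$paired[idx]) &&
        reads$ref_id[idx[1L]] == reads$ref_id[idx[2L]]) {
      fs <- min(reads$start[idx])
      fl <- max(end[idx]) - fs
      key[k] <- paste("P", reads$ref_id[idx[1L]], fs, fl, sep = ":")
    } else {
      ## single-end (or orphan mates): one key per read; concatenating is
      ## fine because orphan groups have a single read each
      key[k] <- paste(paste("S", reads$ref_id[idx], reads$start[idx],
                            reads$strand[idx], span[idx], sep = ":"),
                      collapse = "|")
    }
  }

  dup_frag <- logical(length(frag))
  for (g in split(seq_along(frag), key)) {
    if (length(g) < 2L) next
    best <- g[which.max(qsum[g])]
    dup_frag[setdiff(g, best)] <- TRUE
  }
  is_dup <- logical(nrow(reads))
  for (k in which(dup_frag)) is_dup[frag[[k]]] <- TRUE
  reads$is_duplicate <- is_dup
  reads
}
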