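#' Build a per-site pileup
#'
#' Tallies base calls per covered reference position from non-duplicate
#' reads. Insertions consume no reference position and are skipped;
#' deletions cover the position but contribute no allele; base calls
#' below `min_base_qual` (default phred 13) are excluded from the counts.
#' One column is emitted per reference position covered by at least one
#' read (even if all its bases were quality-filtered); column `depth` is
#' the sum of the retained counts.
#'
#' @param reads A `read_alignments` table; duplicates must be flagged
#'   beforehand ([mark_duplicates()]) and are excluded here.
#' @param reference A `genome_sequence` the reads are mapped to.
#' @param min_base_qual Minimum phred base quality for a call to count.
#' @return A data.frame of class `pileup` with columns `pos` (0-based),
#'   `ref`, `A`, `C`, `G`, `T`, `qA`, `qC`, `qG`, `qT`, `depth`, and
#'   attributes `ref_length` and `span_coverage` (integer vector of raw
#'   read-span depth over the whole reference).
#' @export
build_pileup <- function(reads, reference, min_base_qual = 13L) {
  L <- genome_length(reference)
  base_idx <- c(A = 1L, C = 2L, G = 3L, T = 4L)
  counts <- matrix(0L, nrow = 4L, ncol = L)
  qsums <- matrix(0, nrow = 4L, ncol = L)
  spand <- integer(L + 1L)

  use <- which(!reads$is_duplicate)
  for (i in use) {
    ap <- read_aligned_positions(reads$start[i], reads$cigar[i])
    span <- cigar_ref_span(reads$cigar[i])
    if (reads$start[i] + span > L) {
      if (!reference$circular)
        stop("read ", reads$read_id[i],
             " extends past the end of non-circular reference '",
             reference$id, "'")
      ap$ref <- ap$ref %% L
    }
    ## raw span coverage (difference array; wrapped reads handled as two arcs)
    s <- reads$start[i] %% L
    e <- s + span
    if (e <= L) {
      spand[s + 1L] <- spand[s + 1L] + 1L
      spand[e + 1L] <- spand[e + 1L] - 1L
    } else {
      spand[s + 1L] <- spand[s + 1L] + 1L
      spand[L + 1L] <- spand[L + 1L] - 1L
      spand[1L] <- spand[1L] + 1L
      spand[e - L + 1L] <- spand[e - L + 1L] - 1L
    }
    if (!length(ap$ref)) next
    bases <- s2c(reads$seq[i])[ap$qidx]
    quals <- qual_ints(reads$qual[i])[ap$qidx]
    ok <- quals >= min_base_qual & bases %in% names(base_idx)
    if (!any(ok)) next
    ij <- cbind(base_idx[bases[ok]], ap$ref[ok] + 1L)
    counts[ij] <- counts[ij] + 1L
    qsums[ij] <- qsums[ij] + quals[ok]
  }
  spancov <- cumsum(spand[seq_len(L)])
  covered <- which(spancov > 0L)
  refv <- genome_chars(reference)
  pu <- data.frame(pos = covered - 1L,
                   ref = refv[covered],
                   A = counts[1L, covered], C = counts[2L, covered],
                   G = counts[3L, covered], T = counts[4L, covered],
                   qA = qsums[1L, covered], qC = qsums[2L, covered],
                   qG = qsums[3L, covered], qT = qsums[4L, covered],
                   stringsAsFactors = FALSE)
  pu$depth <- pu$A + pu$C + pu$G + pu$T
  class(pu) <- c("pileup", "data.frame")
  attr(pu, "ref_length") <- L
  attr(pu, "span_coverage") <- spancov
  pu
}

## full-length vectors of allele-count depth (sum of retained counts),
## 0 where no column was emitted
pileup_depth_vector <- function(pileup) {
  L <- attr(pileup, "ref_length")
  d <- integer(L)
  d[pileup$pos + 1L] <- pileup$depth
  d
}

#' Per-window mean read depth
#'
#' Raw (span-based, non-duplicate) depth averaged over fixed windows.
#' Exposed per iteration as the coverage-normalization diagnostic: depth
#' over an insertion's source region starts inflated by cross-mapping
#' reads and flattens as the consensus improves and those reads stop
#' mapping.
#'
#' @param reads A `read_alignments` table (duplicates excluded).
#' @param reference A `genome_sequence`.
#' @param window Window size in bp.
#' @return data.frame with columns `start` (0-based window start), `end`,
#'   `mean_depth`.
#' @export
coverage_profile <- function(reads, reference, window = 100L) {
  L <- genome_length(reference)
  spand <- integer(L + 1L)
  use <- which(!reads$is_duplicate)
  for (i in use) {
    s <- reads$start[i] %% L
    e <- s + cigar_ref_span(reads$cigar[i])
    if (e > L && !reference$circular)
      stop("read extends past the end of non-circular reference")
    if (e <= L) {
      spand[s + 1L] <- spand[s + 1L] + 1L
      spand[e + 1L] <- spand[e + 1L] - 1L
    } else {
      spand[s + 1L] <- spand[s + 1L] + 1L
      spand[L + 1L] <- spand[L + 1L] - 1L
      spand[1L] <- spand[1L] + 1L
      spand[e - L + 1L] <- spand[e - L + 1L] - 1L
    }
  }
  cov <- cumsum(spand[seq_len(L)])
  starts <- seq(0L, L - 1L, by = window)
  ends <- pmin(starts + window, L)
  md <- vapply(seq_along(starts), function(k) {
    mean(cov[(starts[k] + 1L):ends[k]])
  }, numeric(1))
  data.frame(start = starts, end = ends, mean_depth = md)
}
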