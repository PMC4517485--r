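## Haplotype reconstruction and organellar-vs-insertion classification.
##
## Each phased block yields two sequences: the primary-reference backbone
## over the block interval with one haplotype's alleles substituted in.
## Positions with no haplotype-specific read coverage are masked to N.
## The haplotype scoring higher against the secondary reference is the
## organellar one; the other is the odin (organellar-derived insertion).

#' Reconstruct the two haplotype sequences of a phased block
#'
#' @param block A `phased_block` with read sets filled.
#' @param reads A `read_alignments` table (the same reads the block was
#'   phased from).
#' @param primary_ref The `genome_sequence` used for mapping.
#' @return List of class `block_haplotypes`: `block`, `hap_seqs`
#'   (two strings over `[start, end)`), `masks` (two logical vectors,
#'   `TRUE` where masked to N), `hap_read_counts`.
#' @export
reconstruct_block_haplotypes <- function(block, reads, primary_ref) {
  if (block$end <= block$start)
    stop("reconstruct_block_haplotypes: empty block interval")
  width <- block$end - block$start
  backbone <- genome_chars(primary_ref)[(block$start + 1L):block$end]
  offs <- block$sites$pos - block$start + 1L
  use <- reads[!reads$is_duplicate, , drop = FALSE]
  hap_seqs <- character(2L)
  masks <- vector("list", 2L)
  haps <- list(block$hap0, block$hap1)
  for (h in 1:2) {
    v <- backbone
    v[offs] <- haps[[h]]
    ids <- block$hap_read_ids[[h]]
    cov <- integer(width)
    sel <- use[use$read_id %in% ids, , drop = FALSE]
    for (i in seq_len(nrow(sel))) {
      ap <- read_aligned_positions(sel$start[i], sel$cigar[i])
      p <- ap$ref[ap$ref >= block$start & ap$ref < block$end]
      cov[p - block$start + 1L] <- cov[p - block$start + 1L] + 1L
    }
    m <- cov == 0L
    v[m] <- "N"
    hap_seqs[h] <- c2s(v)
    masks[[h]] <- m
  }
  structure(list(block = block, hap_seqs = hap_seqs, masks = masks,
                 hap_read_counts = lengths(block$hap_read_ids)),
            class = "block_haplotypes")
}

#' Semi-global alignment score against the secondary reference
#'
#' Aligns the (possibly N-masked) haplotype sequence to a window of the
#' secondary reference: query end gaps are penalized, reference end gaps
#' are free. Scoring is a conventional DNA scheme — match +1, mismatch
#' -1, gap opening -2 plus -1 per gapped base — and N scores 0 against
#' anything, so masked positions neither help nor hurt. When a hint
#' interval is given (block coordinates on a coordinate-compatible
#' secondary), the search window is the hint padded by twice the query
#' length; otherwise the whole secondary sequence is scanned.
#'
#' @param seq Nucleotide string (may contain N; at least one unmasked base).
#' @param secondary_ref A `genome_sequence`.
#' @param hint_interval Optional `c(start, end)` 0-based half-open hint.
#' @param match,mismatch,gap_open,gap_extend Scoring parameters (positive
#'   penalties for the gap terms).
#' @return Best alignment score (numeric).
#' @export
align_score <- function(seq, secondary_ref, hint_interval = NULL,
                        match = 1, mismatch = -1, gap_open = 2,
                        gap_extend = 1) {
  v <- genome_chars(seq)
  if (!any(v != "N"))
    stop("align_score: unalignable block (fully masked sequence)")
  L <- genome_length(secondary_ref)
  if (!is.null(hint_interval)) {
    pad <- 2L * length(v)
    lo <- max(0L, hint_interval[1L] - pad)
    hi <- min(L, hint_interval[2L] + pad)
    subject <- substr(secondary_ref$bases, lo + 1L, hi)
  } else {
    subject <- secondary_ref$bases
  }
  mat <- matrix(mismatch, 5L, 5L,
                dimnames = list(c("A", "C", "G", "T", "N"),
                                c("A", "C", "G", "T", "N")))
  diag(mat) <- match
  mat["N", ] <- 0; mat[, "N"] <- 0
  pa <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAString(c2s(v)),
    subject = Biostrings::DNAString(subject),
    type = "global-local", substitutionMatrix = mat,
    gapOpening = gap_open, gapExtension = gap_extend)
  Biostrings::score(pa)
}

#' Classify the haplotypes of a block as organellar vs odin
#'
#' The haplotype with the strictly higher alignment score against the
#' secondary reference is called organellar and the other one odin. On a
#' score tie the haplotype with the larger supporting read count is
#' provisionally organellar and the call is flagged `tie = TRUE` for
#' review. The decision is invariant to swapping the hap0/hap1 labels.
#'
#' @param bh A `block_haplotypes` from [reconstruct_block_haplotypes()].
#' @param secondary_ref The `genome_sequence` used for classification
#'   (may equal the primary reference).
#' @param hint_interval Optional coordinate hint passed to [align_score()];
#'   defaults to the block's own interval (use `NA` to force a full scan).
#' @param ... Scoring parameters forwarded to [align_score()].
#' @return An `origin_call`: `block`, `organellar_hap`, `odin_hap` (0/1),
#'   `score_org`, `score_odin`, `tie`.
#' @export
classify_block <- function(bh, secondary_ref, hint_interval = NULL, ...) {
  if (is.null(hint_interval))
    hint_interval <- c(bh$block$start, bh$block$end)
  if (length(hint_interval) == 1L && is.na(hint_interval))
    hint_interval <- NULL
  s <- vapply(bh$hap_seqs, align_score, numeric(1),
              secondary_ref = secondary_ref,
              hint_interval = hint_interval, ...)
  tie <- s[1L] == s[2L]
  org <- if (tie) {
    if (bh$hap_read_counts[1L] >= bh$hap_read_counts[2L]) 0L else 1L
  } else if (s[1L] > s[2L]) 0L else 1L
  structure(list(block = bh$block, haplotypes = bh,
                 organellar_hap = org, odin_hap = 1L - org,
                 score_org = s[org + 1L], score_odin = s[2L - org],
                 tie = tie), class = "origin_call")
}

#' @export
print.origin_call <- function(x, ...) {
  cat(sprintf(
    "origin_call [%d,%d): hap%d organellar (score %g) vs hap%d odin (score %g)%s\n",
    x$block$start, x$block$end, x$organellar_hap, x$score_org,
    x$odin_hap, x$score_odin, if (x$tie) "  [tie]" else ""))
  invisible(x)
}

#' Emit odin regions as BED3 and FASTA
#'
#' Writes one BED3 line per classified block (the interval that contains
#' an odin-derived haplotype) and a multi-FASTA of the odin haplotype
#' sequences, headers encoding interval and both scores.
#'
#' @param origin_calls List of `origin_call` objects.
#' @param bed_path,fasta_path Output paths.
#' @return data.frame of the emitted regions (invisibly).
#' @export
emit_odin_regions <- function(origin_calls, bed_path, fasta_path) {
  n <- length(origin_calls)
  df <- data.frame(chrom = character(n), start = integer(n),
                   end = integer(n), score_org = numeric(n),
                   score_odin = numeric(n), tie = logical(n),
                   seq = character(n), stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    oc <- origin_calls[[i]]
    df$chrom[i] <- oc$block$ref_id
    df$start[i] <- oc$block$start
    df$end[i] <- oc$block$end
    df$score_org[i] <- oc$score_org
    df$score_odin[i] <- oc$score_odin
    df$tie[i] <- oc$tie
    df$seq[i] <- oc$haplotypes$hap_seqs[oc$odin_hap + 1L]
  }
  if (n > 1L) {
    o <- order(df$chrom, df$start)
    df <- df[o, , drop = FALSE]
    same <- df$chrom[-1L] == df$chrom[-n]
    if (any(same & df$start[-1L] < df$end[-n]))
      stop("emit_odin_regions: overlapping blocks (invariant violation)")
  }
  write_bed(df[, c("chrom", "start", "end")], bed_path)
  fa <- file(fasta_path, "w")
  on.exit(close(fa))
  for (i in seq_len(nrow(df))) {
    writeLines(sprintf(">odin|%s:%d-%d|score_org=%g|score_odin=%g%s",
                       df$chrom[i], df$start[i], df$end[i],
                       df$score_org[i], df$score_odin[i],
                       if (df$tie[i]) "|tie" else ""), fa)
    writeLines(df$seq[i], fa)
  }
  invisible(df)
}

#' Merge nearby intervals
#'
#' bedtools-merge-style union of intervals closer than `gap`. A single
#' insertion yields several phased blocks when a stretch without called
#' SNVs (or longer than the library insert) breaks read linkage;
#' merging blocks within the fragment length recovers the extent of the
#' region that contains the odin.
#'
#' @param df data.frame with `chrom`, `start`, `end`.
#' @param gap Maximum separation (bp) for two intervals to be merged.
#' @return data.frame with the merged intervals.
#' @export
merge_intervals <- function(df, gap = 0L) {
  if (nrow(df) < 2L) return(df)
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  out <- df[1L, c("chrom", "start", "end"), drop = FALSE]
  for (i in 2L:nrow(df)) {
    j <- nrow(out)
    if (df$chrom[i] == out$chrom[j] && df$start[i] <= out$end[j] + gap) {
      out$end[j] <- max(out$end[j], df$end[i])
    } else {
      out <- rbind(out, df[i, c("chrom", "start", "end")])
    }
  }
  rownames(out) <- NULL
  out
}

#' Write a BED3 file
#' @param df data.frame with columns `chrom`, `start`, `end` (0-based,
#'   half-open).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(df, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (nrow(df))
    writeLines(sprintf("%s\t%d\t%d", df$chrom, df$start, df$end), con)
  invisible(path)
}

#' Read a BED3 file
#' @param path BED path.
#' @return data.frame with columns `chrom`, `start`, `end`.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  ln <- readLines(path)
  ln <- ln[nzchar(ln)]
  if (!length(ln))
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE))
  f <- strsplit(ln, "\t", fixed = TRUE)
  data.frame(chrom = vapply(f, `[`, character(1), 1L),
             start = as.integer(vapply(f, `[`, character(1), 2L)),
             end = as.integer(vapply(f, `[`, character(1), 3L)),
             stringsAsFactors = FALSE)
}

#' Write the per-block classification report as TSV
#' @param origin_calls List of `origin_call` objects.
#' @param path Output path.
#' @return The report data.frame, invisibly.
#' @export
write_block_report <- function(origin_calls, path) {
  rows <- lapply(origin_calls, function(oc) {
    data.frame(chrom = oc$block$ref_id, start = oc$block$start,
               end = oc$block$end, n_sites = nrow(oc$block$sites),
               organellar_hap = oc$organellar_hap,
               score_org = oc$score_org, score_odin = oc$score_odin,
               tie = oc$tie, multiallelic = oc$block$multiallelic,
               chimeric_fraction = round(oc$block$chimeric_fraction, 4),
               stringsAsFactors = FALSE)
  })
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chrom = character(0), start = integer(0), end = integer(0),
               n_sites = integer(0), organellar_hap = integer(0),
               score_org = numeric(0), score_odin = numeric(0),
               tie = logical(0), multiallelic = logical(0),
               chimeric_fraction = numeric(0))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
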