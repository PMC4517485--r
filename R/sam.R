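## SAM text I/O and CIGAR arithmetic.
##
## Plain-text SAM (subset: header, FLAG, POS, MAPQ, CIGAR with M/I/D/S,
## SEQ, QUAL) is the interchange dialect; binary BAM/CRAM is out of scope.
## Coordinates are 0-based half-open internally and converted exactly once,
## here at the boundary.

SAM_FLAG_PAIRED <- 0x1L
SAM_FLAG_PROPER <- 0x2L
SAM_FLAG_UNMAPPED <- 0x4L
SAM_FLAG_REVERSE <- 0x10L
SAM_FLAG_FIRST <- 0x40L
SAM_FLAG_SECOND <- 0x80L
SAM_FLAG_DUP <- 0x400L

#' Construct a read-alignment table
#'
#' The pipeline's container for mapped reads: a `data.frame` with one row
#' per read and class `read_alignments`. Positions are 0-based; `qual` is
#' a phred+33 string of the same length as `seq`; `frag_id` groups the
#' two mates of a pair (equal to `read_id` for single-end reads).
#'
#' @param read_id,frag_id,ref_id Character vectors.
#' @param start Integer 0-based leftmost reference positions.
#' @param cigar CIGAR strings restricted to operations M, I, D, S.
#' @param seq,qual Base and phred+33 quality strings.
#' @param mapq Integer mapping qualities.
#' @param strand `"+"` or `"-"`.
#' @param paired,first_of_pair,proper,is_duplicate Logical vectors.
#' @return A `read_alignments` data.frame.
#' @export
read_alignments <- function(read_id, ref_id, start, cigar, seq, qual,
                            mapq = 60L, strand = "+", frag_id = read_id,
                            paired = FALSE, first_of_pair = TRUE,
                            proper = FALSE, is_duplicate = FALSE) {
  df <- data.frame(read_id = as.character(read_id),
                   frag_id = as.character(frag_id),
                   ref_id = as.character(ref_id),
                   start = as.integer(start),
                   cigar = as.character(cigar),
                   seq = toupper(as.character(seq)),
                   qual = as.character(qual),
                   mapq = as.integer(mapq),
                   strand = as.character(strand),
                   paired = as.logical(paired),
                   first_of_pair = as.logical(first_of_pair),
                   proper = as.logical(proper),
                   is_duplicate = as.logical(is_duplicate),
                   stringsAsFactors = FALSE)
  validate_read_alignments(df)
  class(df) <- c("read_alignments", "data.frame")
  df
}

validate_read_alignments <- function(df) {
  if (nrow(df) == 0L) return(invisible(df))
  if (any(df$start < 0L)) stop("read_alignments: negative start position")
  if (any(nchar(df$qual) != nchar(df$seq)))
    stop("read_alignments: qual length != seq length")
  qlen <- cigar_query_length(df$cigar)
  bad <- which(qlen != nchar(df$seq))
  if (length(bad))
    stop("read_alignments: CIGAR query length != SEQ length for read ",
         df$read_id[bad[1L]])
  invisible(df)
}

## ---- CIGAR arithmetic -------------------------------------------------

#' Parse a CIGAR string into operations
#' @param cigar A single CIGAR string.
#' @return data.frame with columns `op` and `len`.
#' @export
cigar_ops <- function(cigar) {
  if (cigar == "*" || !nzchar(cigar)) return(data.frame(op = character(0), len = integer(0)))
  lens <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1L]])
  ops <- regmatches(cigar, gregexpr("[A-Z=]", cigar))[[1L]]
  if (length(lens) != length(ops) || !length(ops))
    stop("malformed CIGAR: ", cigar)
  data.frame(op = ops, len = lens, stringsAsFactors = FALSE)
}

cigar_sum_ops <- function(cigars, which_ops) {
  vapply(cigars, function(cg) {
    o <- cigar_ops(cg)
    sum(o$len[o$op %in% which_ops])
  }, integer(1), USE.NAMES = FALSE)
}

#' Number of query bases consumed by a CIGAR (M + I + S)
#' @param cigars Character vector of CIGAR strings.
#' @return Integer vector.
#' @export
cigar_query_length <- function(cigars) cigar_sum_ops(cigars, c("M", "I", "S"))

#' Number of reference bp consumed by a CIGAR (M + D)
#' @param cigars Character vector of CIGAR strings.
#' @return Integer vector.
#' @export
cigar_ref_span <- function(cigars) cigar_sum_ops(cigars, c("M", "D"))

## Aligned (M) positions of one read: 0-based reference positions and
## matching 1-based indices into the read string.
read_aligned_positions <- function(start, cigar) {
  if (grepl("^[0-9]+M$", cigar)) {
    n <- as.integer(sub("M$", "", cigar))
    return(list(ref = start + seq_len(n) - 1L, qidx = seq_len(n)))
  }
  o <- cigar_ops(cigar)
  rpos <- start
  qpos <- 1L
  refs <- vector("list", nrow(o))
  qidx <- vector("list", nrow(o))
  for (i in seq_len(nrow(o))) {
    op <- o$op[i]; len <- o$len[i]
    if (op == "M") {
      refs[[i]] <- rpos + seq_len(len) - 1L
      qidx[[i]] <- qpos + seq_len(len) - 1L
      rpos <- rpos + len; qpos <- qpos + len
    } else if (op == "I" || op == "S") {
      qpos <- qpos + len
    } else if (op == "D") {
      rpos <- rpos + len
    } else stop("unsupported CIGAR op '", op, "'")
  }
  list(ref = unlist(refs, use.names = FALSE),
       qidx = unlist(qidx, use.names = FALSE))
}

## ---- SAM parsing ------------------------------------------------------

#' Parse SAM records into a read-alignment table
#'
#' Accepts the text of a SAM file (character vector of lines). Header
#' lines are used to collect reference names/lengths; unmapped records
#' are skipped; hard-clipped records are rejected (the subset dialect
#' excludes H). SAM 1-based POS is converted to internal 0-based.
#'
#' @param lines Character vector of SAM lines (header included).
#' @return A `read_alignments` data.frame with attribute `"references"`
#'   (named integer vector of reference lengths, possibly empty).
#' @export
parse_alignments <- function(lines) {
  is_hdr <- startsWith(lines, "@")
  refs <- integer(0)
  hdr <- lines[is_hdr]
  sq <- hdr[startsWith(hdr, "@SQ")]
  if (length(sq)) {
    nm <- sub(".*\tSN:([^\t]+).*", "\\1", sq)
    ln <- as.integer(sub(".*\tLN:([0-9]+).*", "\\1", sq))
    refs <- stats::setNames(ln, nm)
  }
  body_idx <- which(!is_hdr & nzchar(lines))
  rows <- vector("list", length(body_idx))
  keep <- logical(length(body_idx))
  for (k in seq_along(body_idx)) {
    i <- body_idx[k]
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 11L)
      stop("SAM parse error at line ", i, ": fewer than 11 fields")
    flag <- suppressWarnings(as.integer(f[2L]))
    pos <- suppressWarnings(as.integer(f[4L]))
    if (is.na(flag) || is.na(pos))
      stop("SAM parse error at line ", i, ": non-numeric FLAG or POS")
    if (bitwAnd(flag, SAM_FLAG_UNMAPPED) != 0L) next
    cigar <- f[6L]
    if (grepl("H", cigar, fixed = TRUE))
      stop("SAM parse error at line ", i, ": hard-clipped CIGAR not supported")
    if (grepl("[^0-9MIDS]", cigar))
      stop("SAM parse error at line ", i, ": unsupported CIGAR op in '", cigar, "'")
    seqs <- toupper(f[10L])
    if (cigar_query_length(cigar) != nchar(seqs))
      stop("SAM parse error at line ", i, ": CIGAR/SEQ length mismatch")
    qual <- f[11L]
    if (qual == "*") qual <- strrep("I", nchar(seqs))
    paired <- bitwAnd(flag, SAM_FLAG_PAIRED) != 0L
    first <- !paired || bitwAnd(flag, SAM_FLAG_FIRST) != 0L
    rid <- if (paired) paste0(f[1L], if (first) "/1" else "/2") else f[1L]
    rows[[k]] <- data.frame(
      read_id = rid, frag_id = f[1L], ref_id = f[3L], start = pos - 1L,
      cigar = cigar, seq = seqs, qual = qual,
      mapq = as.integer(f[5L]), strand = if (bitwAnd(flag, SAM_FLAG_REVERSE)) "-" else "+",
      paired = paired, first_of_pair = first,
      proper = bitwAnd(flag, SAM_FLAG_PROPER) != 0L,
      is_duplicate = bitwAnd(flag, SAM_FLAG_DUP) != 0L,
      stringsAsFactors = FALSE)
    keep[k] <- TRUE
  }
  df <- if (any(keep)) do.call(rbind, rows[keep]) else
    data.frame(read_id = character(0), frag_id = character(0),
               ref_id = character(0), start = integer(0), cigar = character(0),
               seq = character(0), qual = character(0), mapq = integer(0),
               strand = character(0), paired = logical(0),
               first_of_pair = logical(0), proper = logical(0),
               is_duplicate = logical(0), stringsAsFactors = FALSE)
  validate_read_alignments(df)
  class(df) <- c("read_alignments", "data.frame")
  attr(df, "references") <- refs
  df
}

#' Read a SAM file
#' @param path SAM file path.
#' @return A `read_alignments` data.frame (see [parse_alignments()]).
#' @export
read_sam <- function(path) {
  if (!file.exists(path)) stop("SAM file not found: ", path)
  parse_alignments(readLines(path))
}

#' Write a read-alignment table as SAM
#'
#' Emits a minimal valid SAM with `@HD`/`@SQ` headers and one record per
#' read; FLAG is reconstructed from strand, pairing and duplicate status.
#'
#' @param reads A `read_alignments` data.frame.
#' @param references Named integer vector of reference lengths, or a
#'   `genome_sequence` (list of them) from which names/lengths are taken.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(reads, references, path) {
  if (inherits(references, "genome_sequence")) references <- list(references)
  if (is.list(references))
    references <- stats::setNames(
      vapply(references, genome_length, integer(1)),
      vapply(references, function(g) g$id, character(1)))
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(references), references))
  flag <- ifelse(reads$strand == "-", SAM_FLAG_REVERSE, 0L)
  flag <- flag + ifelse(reads$paired,
                        SAM_FLAG_PAIRED +
                          ifelse(reads$proper, SAM_FLAG_PROPER, 0L) +
                          ifelse(reads$first_of_pair, SAM_FLAG_FIRST, SAM_FLAG_SECOND),
                        0L)
  flag <- flag + ifelse(reads$is_duplicate, SAM_FLAG_DUP, 0L)
  o <- order(reads$ref_id, reads$start)
  r <- reads[o, , drop = FALSE]
  rec <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s",
                 r$frag_id, flag[o], r$ref_id, r$start + 1L, r$mapq,
                 r$cigar, r$seq, r$qual)
  writeLines(c(hdr, rec), path)
  invisible(path)
}

## ---- FASTQ ------------------------------------------------------------

#' Write reads to FASTQ (phred+33)
#' @param ids,seqs,quals Character vectors of equal length.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(ids, seqs, quals, path) {
  stopifnot(length(ids) == length(seqs), length(seqs) == length(quals))
  out <- character(4L * length(ids))
  out[seq(1, by = 4, length.out = length(ids))] <- paste0("@", ids)
  out[seq(2, by = 4, length.out = length(ids))] <- seqs
  out[seq(3, by = 4, length.out = length(ids))] <- "+"
  out[seq(4, by = 4, length.out = length(ids))] <- quals
  writeLines(out, path)
  invisible(path)
}

#' Read a FASTQ file (phred+33)
#' @param path FASTQ path.
#' @return data.frame with columns `read_id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("FASTQ file not found: ", path)
  ln <- readLines(path)
  ln <- ln[nzchar(ln)]
  if (length(ln) %% 4L != 0L) stop("truncated FASTQ: ", path)
  i <- seq(1, length(ln), by = 4)
  data.frame(read_id = sub("\\s.*$", "", sub("^@", "", ln[i])),
             seq = toupper(ln[i + 1L]), qual = ln[i + 3L],
             stringsAsFactors = FALSE)
}

## phred score vector from a phred+33 string
qual_ints <- function(q) utf8ToInt(q) - 33L
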