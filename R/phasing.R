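## Read-backed phasing of heterozygous-looking SNVs.
##
## Cross-mapping reads from an organellar insertion make its divergent
## sites look heterozygous; haplotype-informative reads (fragments
## covering two or more such sites) link their alleles into phased
## blocks, one haplotype per origin. Blocks are grown left to right over
## adjacent site pairs whose phase quality clears the threshold.

## Per-READ allele observations at called het sites.
## Returns data.frame(row = read row index, site = site index, code)
## with code 1 = allele1, 2 = allele2, 0 = any other base.
read_site_codes <- function(reads, site_pos, allele1, allele2,
                            min_base_qual = 13L) {
  empty <- data.frame(row = integer(0), site = integer(0), code = integer(0))
  if (nrow(reads) == 0L || length(site_pos) == 0L) return(empty)
  span <- cigar_ref_span(reads$cigar)
  ir_reads <- IRanges::IRanges(start = reads$start + 1L,
                               end = reads$start + pmax(span, 1L))
  ir_sites <- IRanges::IRanges(start = site_pos + 1L, width = 1L)
  hits <- IRanges::findOverlaps(ir_sites, ir_reads)
  si <- S4Vectors::queryHits(hits)
  ri <- S4Vectors::subjectHits(hits)
  if (!length(si)) return(empty)

  qidx <- integer(length(si))
  simple <- grepl("^[0-9]+M$", reads$cigar[ri])
  qidx[simple] <- site_pos[si[simple]] - reads$start[ri[simple]] + 1L
  for (k in which(!simple)) {
    ap <- read_aligned_positions(reads$start[ri[k]], reads$cigar[ri[k]])
    m <- match(site_pos[si[k]], ap$ref)
    qidx[k] <- if (is.na(m)) NA_integer_ else ap$qidx[m]
  }
  ok <- !is.na(qidx)
  si <- si[ok]; ri <- ri[ok]; qidx <- qidx[ok]
  if (!length(si)) return(empty)
  bases <- substring(reads$seq[ri], qidx, qidx)
  quals <- utf8ToInt(paste0(substring(reads$qual[ri], qidx, qidx),
                            collapse = "")) - 33L
  pass <- quals >= min_base_qual
  si <- si[pass]; ri <- ri[pass]; bases <- bases[pass]
  code <- integer(length(si))
  code[bases == allele1[si]] <- 1L
  code[bases == allele2[si]] <- 2L
  data.frame(row = ri, site = si, code = code)
}

## Fragment-level codes: mates merged; mate disagreement at a shared
## site becomes code 0 (non-called, ignored for pair counting).
fragment_site_codes <- function(reads, codes) {
  if (nrow(codes) == 0L)
    return(data.frame(frag = character(0), site = integer(0), code = integer(0)))
  frag <- reads$frag_id[codes$row]
  key <- paste(frag, codes$site, sep = "\r")
  agg_min <- tapply(codes$code, key, min)
  agg_max <- tapply(codes$code, key, max)
  code <- ifelse(agg_min == agg_max, agg_min, 0L)
  parts <- strsplit(names(agg_min), "\r", fixed = TRUE)
  data.frame(frag = vapply(parts, `[`, character(1), 1L),
             site = as.integer(vapply(parts, `[`, character(1), 2L)),
             code = as.integer(code), stringsAsFactors = FALSE)
}

#' Count cis/trans haplotype-informative fragments per adjacent site pair
#'
#' A fragment (single read, or the two mates of a pair taken together)
#' observing both sites of an adjacent heterozygous pair supports either
#' the cis configuration (allele1 with allele1, or allele2 with allele2)
#' or trans (mixed). Fragments showing a non-called allele at either
#' site, or whose mates disagree there, are ignored for that pair.
#'
#' @param reads A `read_alignments` table (duplicates excluded upstream).
#' @param snvs An `snv_calls` table; only het rows are used.
#' @param min_base_qual Minimum phred quality of the observed base.
#' @return data.frame with one row per adjacent het pair: `pos1`, `pos2`
#'   (0-based), `cis`, `trans`.
#' @export
collect_informative_reads <- function(reads, snvs, min_base_qual = 13L) {
  het <- snvs[snvs$genotype == "het", , drop = FALSE]
  het <- het[order(het$pos), , drop = FALSE]
  k <- nrow(het)
  if (k < 2L)
    return(data.frame(pos1 = integer(0), pos2 = integer(0),
                      cis = integer(0), trans = integer(0)))
  use <- reads[!reads$is_duplicate, , drop = FALSE]
  codes <- read_site_codes(use, het$pos, het$allele1, het$allele2,
                           min_base_qual)
  fc <- fragment_site_codes(use, codes)
  fc <- fc[fc$code != 0L, , drop = FALSE]
  cis <- integer(k - 1L); trans <- integer(k - 1L)
  if (nrow(fc)) {
    by_site <- split(fc, fc$site)
    for (i in seq_len(k - 1L)) {
      a <- by_site[[as.character(i)]]
      b <- by_site[[as.character(i + 1L)]]
      if (is.null(a) || is.null(b)) next
      m <- match(a$frag, b$frag)
      hit <- !is.na(m)
      if (!any(hit)) next
      same <- a$code[hit] == b$code[m[hit]]
      cis[i] <- sum(same)
      trans[i] <- sum(!same)
    }
  }
  data.frame(pos1 = het$pos[-k], pos2 = het$pos[-1L],
             cis = cis, trans = trans)
}

#' Phred-scaled phase quality of an adjacent site pair
#'
#' Likelihood-ratio form with a fixed per-fragment error probability:
#' `PQ = 10 * |cis - trans| * log10((1 - eps) / eps)`. With the default
#' `eps = 0.01` each net supporting fragment contributes about 19.96
#' phred, so a single clean fragment already clears the conventional
#' threshold of 10.
#'
#' @param cis,trans Non-negative fragment counts (vectorized).
#' @param eps Per-fragment error probability.
#' @return Phred score(s).
#' @export
pair_phase_quality <- function(cis, trans, eps = 0.01) {
  stopifnot(all(cis >= 0), all(trans >= 0), eps > 0, eps < 0.5)
  10 * abs(cis - trans) * log10((1 - eps) / eps)
}

#' Link heterozygous sites into phased blocks
#'
#' Sweeps the het sites left to right and extends the current block
#' across an adjacent pair exactly when its phase quality reaches
#' `phase_quality_thresh`, taking the majority configuration. Singleton
#' het sites become unphased single-site blocks. By convention haplotype
#' 0 carries `allele1` (the reference allele, when the genotype contains
#' it) at the first site of the block, which makes output deterministic;
#' all downstream operations are invariant to swapping the two labels.
#'
#' A block is flagged multiallelic when any member site carries a
#' substantial third allele, or when the fraction of chimeric reads
#' among its informative reads reaches `chimeric_fraction_thresh` —
#' the read-level signature of more than two haplotypes contributing
#' (e.g. several insertion copies).
#'
#' @param snvs An `snv_calls` table.
#' @param reads A `read_alignments` table.
#' @param phase_quality_thresh Phred threshold for linking (default 10.0).
#' @param eps Per-fragment error probability of the phase-quality form.
#' @param min_base_qual Minimum phred quality for an observed allele.
#' @param chimeric_fraction_thresh Chimeric-read fraction that flags a
#'   block multiallelic (with at least `min_informative` informative reads).
#' @param min_informative Minimum informative reads for the chimeric flag.
#' @param ref_id Reference name stored on the blocks.
#' @return List of `phased_block` objects, ordered by position.
#' @export
phase_blocks <- function(snvs, reads, phase_quality_thresh = 10.0,
                         eps = 0.01, min_base_qual = 13L,
                         chimeric_fraction_thresh = 0.10,
                         min_informative = 10L, ref_id = "ref") {
  het <- snvs[snvs$genotype == "het", , drop = FALSE]
  het <- het[order(het$pos), , drop = FALSE]
  k <- nrow(het)
  if (k == 0L) return(list())
  use <- reads[!reads$is_duplicate, , drop = FALSE]
  pairs <- collect_informative_reads(use, het, min_base_qual)
  pq <- if (k > 1L) pair_phase_quality(pairs$cis, pairs$trans, eps) else numeric(0)
  linked <- pq >= phase_quality_thresh & (pairs$cis + pairs$trans) > 0L
  orient_trans <- pairs$trans > pairs$cis

  ## parity sweep: flip[i] says hap0 switches allele side after pair i
  blocks <- list()
  bstart <- 1L
  for (i in seq_len(k)) {
    end_block <- i == k || !linked[i]
    if (!end_block) next
    idx <- bstart:i
    side <- integer(length(idx)); side[1L] <- 1L
    if (length(idx) > 1L) {
      for (j in 2L:length(idx)) {
        p <- idx[j] - 1L   # pair between idx[j-1] and idx[j]
        side[j] <- if (orient_trans[p]) 3L - side[j - 1L] else side[j - 1L]
      }
    }
    hap0 <- ifelse(side == 1L, het$allele1[idx], het$allele2[idx])
    hap1 <- ifelse(side == 1L, het$allele2[idx], het$allele1[idx])
    blk <- structure(list(
      ref_id = ref_id,
      start = het$pos[idx[1L]],
      end = het$pos[idx[length(idx)]] + 1L,
      sites = het[idx, , drop = FALSE],
      hap0 = hap0, hap1 = hap1,
      pair_pq = if (length(idx) > 1L) pq[idx[-length(idx)]] else numeric(0),
      phased = length(idx) > 1L,
      hap_read_ids = list(character(0), character(0)),
      chimeric_read_ids = character(0),
      uninformative_read_ids = character(0),
      chimeric_fraction = 0,
      multiallelic = any(het$multiallelic[idx])), class = "phased_block")
    sep <- separate_reads_by_allele(blk, use, min_base_qual)
    blk$hap_read_ids <- list(sep$hap0, sep$hap1)
    blk$chimeric_read_ids <- sep$chimeric
    blk$uninformative_read_ids <- sep$uninformative
    n_inf <- length(sep$hap0) + length(sep$hap1) + length(sep$chimeric)
    blk$chimeric_fraction <- if (n_inf > 0L) length(sep$chimeric) / n_inf else 0
    if (n_inf >= min_informative &&
        blk$chimeric_fraction >= chimeric_fraction_thresh)
      blk$multiallelic <- TRUE
    blocks[[length(blocks) + 1L]] <- blk
    bstart <- i + 1L
  }
  blocks
}

#' @export
print.phased_block <- function(x, ...) {
  cat(sprintf(
    "phased_block %s:[%d,%d) %d site(s)%s  reads hap0=%d hap1=%d chimeric=%d%s\n",
    x$ref_id, x$start, x$end, nrow(x$sites),
    if (x$phased) "" else " (unphased singleton)",
    length(x$hap_read_ids[[1L]]), length(x$hap_read_ids[[2L]]),
    length(x$chimeric_read_ids),
    if (x$multiallelic) "  [multiallelic]" else ""))
  invisible(x)
}

#' Separate reads by haplotype allele
#'
#' Assigns each read overlapping a phased block to the haplotype whose
#' alleles it matches at all covered sites. Reads matching different
#' haplotypes at different sites — or carrying a third allele — are
#' chimeric: they are never "fixed" or reassigned, because a chimeric
#' read may itself derive from another insertion copy. Reads covering
#' no called site are uninformative.
#'
#' @param block A `phased_block`.
#' @param reads A `read_alignments` table.
#' @param min_base_qual Minimum phred quality for an observed allele.
#' @return List of read-id character vectors: `hap0`, `hap1`, `chimeric`,
#'   `uninformative` (a partition of the block-overlapping reads).
#' @export
separate_reads_by_allele <- function(block, reads, min_base_qual = 13L) {
  use <- reads[!reads$is_duplicate, , drop = FALSE]
  span <- cigar_ref_span(use$cigar)
  over <- which(use$start < block$end & (use$start + span) > block$start)
  if (!length(over))
    return(list(hap0 = character(0), hap1 = character(0),
                chimeric = character(0), uninformative = character(0)))
  sub <- use[over, , drop = FALSE]
  codes <- read_site_codes(sub, block$sites$pos,
                           block$sites$allele1, block$sites$allele2,
                           min_base_qual)
  ## translate allele1/allele2 codes into hap0/hap1 matches
  site_side1 <- block$hap0 == block$sites$allele1   # TRUE: hap0 carries allele1
  m0 <- ifelse(site_side1[codes$site], codes$code == 1L, codes$code == 2L)
  m1 <- ifelse(site_side1[codes$site], codes$code == 2L, codes$code == 1L)
  n0 <- tapply(m0, codes$row, sum)
  n1 <- tapply(m1, codes$row, sum)
  ntot <- tapply(rep(1L, nrow(codes)), codes$row, sum)
  rows_cov <- as.integer(names(ntot))
  cat0 <- n0 == ntot
  cat1 <- n1 == ntot
  list(hap0 = sub$read_id[rows_cov[cat0]],
       hap1 = sub$read_id[rows_cov[cat1]],
       chimeric = sub$read_id[rows_cov[!cat0 & !cat1]],
       uninformative = sub$read_id[setdiff(seq_len(nrow(sub)), rows_cov)])
}
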