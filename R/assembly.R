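## Consensus assembly: two coverage-based baselines (majority count and
## the 2/3 ratio) and the phasing-based method. All three are
## length-preserving — indels are excluded from calling — and mask
## positions with coverage below 1 to N.

assembly_result <- function(consensus, depth, method, odin_regions = NULL) {
  mask <- n_runs_bed(consensus)
  structure(list(consensus = consensus, mask = mask,
                 odin_regions = odin_regions, depth = depth,
                 method = method), class = "assembly_result")
}

#' @export
print.assembly_result <- function(x, ...) {
  cat(sprintf("assembly_result (%s): %d bp, %d masked position(s)%s\n",
              x$method, genome_length(x$consensus),
              sum(genome_chars(x$consensus) == "N"),
              if (!is.null(x$odin_regions) && nrow(x$odin_regions))
                sprintf(", %d odin region(s)", nrow(x$odin_regions)) else ""))
  invisible(x)
}

## BED intervals of N runs in a consensus
n_runs_bed <- function(g) {
  v <- genome_chars(g) == "N"
  if (!any(v))
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE))
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values
  data.frame(chrom = g$id, start = starts[keep], end = ends[keep],
             stringsAsFactors = FALSE)
}

## shared scaffold: per-position counts matrix (4 x L) and depth vector
consensus_counts <- function(pileup, reference) {
  L <- genome_length(reference)
  cm <- matrix(0L, 4L, L, dimnames = list(c("A", "C", "G", "T"), NULL))
  j <- pileup$pos + 1L
  cm[1L, j] <- pileup$A; cm[2L, j] <- pileup$C
  cm[3L, j] <- pileup$G; cm[4L, j] <- pileup$T
  cm
}

#' Majority-count consensus
#'
#' Keeps the most common nucleotide at each position; ties go to the
#' reference base; positions with coverage below 1 are masked to N.
#' This is the weakest baseline: insertion reads at higher copy depth
#' outvote the organellar allele.
#'
#' @param pileup A `pileup`.
#' @param reference The `genome_sequence` the pileup was built on.
#' @return An `assembly_result`.
#' @export
consensus_mc <- function(pileup, reference) {
  cm <- consensus_counts(pileup, reference)
  depth <- colSums(cm)
  refv <- genome_chars(reference)
  out <- refv
  al <- rownames(cm)
  mx <- apply(cm, 2L, max)
  best <- apply(cm, 2L, which.max)
  ntop <- colSums(cm == rep(mx, each = 4L))
  take <- depth > 0L & ntop == 1L
  out[take] <- al[best[take]]
  out[depth == 0L] <- "N"
  assembly_result(genome_sequence(paste0(reference$id, "_mc"), c2s(out),
                                  reference$circular),
                  depth, "mc")
}

#' 2/3-ratio consensus
#'
#' The alternative nucleotide replaces the reference base only when it
#' reaches a minimum fraction (default 2/3) of the position's depth;
#' coverage below 1 is masked to N. Stricter than majority count, and
#' the coverage-based baseline least sensitive to mapping stringency.
#'
#' @param pileup A `pileup`.
#' @param reference The `genome_sequence` the pileup was built on.
#' @param ratio Minimum alternative-allele fraction, in `(0.5, 1]`.
#' @return An `assembly_result`.
#' @export
consensus_two_thirds <- function(pileup, reference, ratio = 2 / 3) {
  if (ratio <= 0.5 || ratio > 1)
    stop("consensus_two_thirds: ratio must be in (0.5, 1]")
  cm <- consensus_counts(pileup, reference)
  depth <- colSums(cm)
  refv <- genome_chars(reference)
  out <- refv
  al <- rownames(cm)
  for (j in which(depth > 0L)) {
    cnt <- cm[, j]
    cnt[al == refv[j]] <- -1L   # only alternative alleles compete
    a <- which.max(cnt)
    if (cnt[a] >= 0L && cnt[a] / depth[j] >= ratio) out[j] <- al[a]
  }
  out[depth == 0L] <- "N"
  assembly_result(genome_sequence(paste0(reference$id, "_23"), c2s(out),
                                  reference$circular),
                  depth, "two_thirds")
}

#' Phasing-based consensus
#'
#' Inside each classified block the organellar haplotype sequence is
#' substituted (with its zero-coverage positions masked N); homozygous
#' alternative calls outside blocks take the alternative allele;
#' everywhere else the reference base is kept. Positions with depth
#' below `min_coverage` are masked to N. Odin regions are collected from
#' the origin calls.
#'
#' @param primary_ref The mapping reference.
#' @param snvs An `snv_calls` table.
#' @param blocks List of `phased_block`s (non-overlapping).
#' @param origin_calls List of `origin_call`s, one per block.
#' @param pileup The `pileup` the calls were made from.
#' @param min_coverage Mask threshold (default 1: coverage < 1 is masked).
#' @return An `assembly_result` with `odin_regions` populated.
#' @export
assemble_phased <- function(primary_ref, snvs, blocks, origin_calls,
                            pileup, min_coverage = 1L) {
  L <- genome_length(primary_ref)
  out <- genome_chars(primary_ref)
  depth <- pileup_depth_vector(pileup)

  ## classified blocks carry the organellar haplotype
  if (length(blocks)) {
    starts <- vapply(blocks, function(b) b$start, numeric(1))
    o <- order(starts)
    ends <- vapply(blocks, function(b) b$end, numeric(1))
    if (any(starts[o][-1L] < ends[o][-length(o)]))
      stop("assemble_phased: overlapping blocks (invariant violation)")
  }
  odin <- NULL
  if (length(origin_calls)) {
    odin <- data.frame(chrom = character(0), start = integer(0),
                       end = integer(0), stringsAsFactors = FALSE)
    for (oc in origin_calls) {
      seqv <- s2c(oc$haplotypes$hap_seqs[oc$organellar_hap + 1L])
      idx <- (oc$block$start + 1L):oc$block$end
      out[idx] <- seqv
      odin <- rbind(odin, data.frame(chrom = oc$block$ref_id,
                                     start = oc$block$start,
                                     end = oc$block$end,
                                     stringsAsFactors = FALSE))
    }
  }
  ## hom-alt substitutions: both haplotypes carry the alternative, so
  ## they apply everywhere except at a block's het sites (those are
  ## decided by the classified haplotype above)
  het_site <- logical(L)
  for (blk in blocks) het_site[blk$sites$pos + 1L] <- TRUE
  hom <- snvs[snvs$genotype == "hom_alt", , drop = FALSE]
  for (i in seq_len(nrow(hom))) {
    p <- hom$pos[i] + 1L
    if (!het_site[p]) out[p] <- hom$allele1[i]
  }

  out[depth < min_coverage] <- "N"
  assembly_result(genome_sequence(paste0(primary_ref$id, "_phased"),
                                  c2s(out), primary_ref$circular),
                  depth, "phased", odin_regions = odin)
}

#' Count non-N differences between two equal-length sequences
#'
#' The convergence metric of the iterative loop: positions where either
#' sequence is N are excluded, so masking changes do not count as
#' sequence changes.
#'
#' @param a,b `genome_sequence`s or strings of equal length.
#' @return Integer count.
#' @export
count_differences <- function(a, b) {
  va <- genome_chars(a); vb <- genome_chars(b)
  if (length(va) != length(vb))
    stop("count_differences: sequences have different lengths (",
         length(va), " vs ", length(vb), ")")
  sum(va != vb & va != "N" & vb != "N")
}

#' Translate two CDS sequences and list amino-acid differences
#'
#' Both sequences are translated with the bacterial/plastid genetic code
#' (NCBI translation table 11 by default) and compared codon by codon.
#' Used to check whether insertion-derived miscalls would change the
#' protein.
#'
#' @param cds_a,cds_b Equal-length nucleotide strings (or
#'   `genome_sequence`s), length divisible by 3, no internal N.
#' @param table Genetic code id as understood by
#'   [Biostrings::getGeneticCode()] (default `"11"`).
#' @return data.frame with columns `codon` (0-based codon index), `aa_a`,
#'   `aa_b`; zero rows when the proteins agree.
#' @export
translate_and_compare <- function(cds_a, cds_b, table = "11") {
  sa <- if (inherits(cds_a, "genome_sequence")) cds_a$bases else toupper(cds_a)
  sb <- if (inherits(cds_b, "genome_sequence")) cds_b$bases else toupper(cds_b)
  if (nchar(sa) != nchar(sb))
    stop("translate_and_compare: sequences have different lengths")
  if (nchar(sa) %% 3L != 0L)
    stop("translate_and_compare: length not divisible by 3")
  if (grepl("N", sa, fixed = TRUE) || grepl("N", sb, fixed = TRUE))
    stop("translate_and_compare: internal N in CDS")
  code <- Biostrings::getGeneticCode(as.character(table))
  aa_a <- s2c(as.character(Biostrings::translate(Biostrings::DNAString(sa),
                                                 genetic.code = code)))
  aa_b <- s2c(as.character(Biostrings::translate(Biostrings::DNAString(sb),
                                                 genetic.code = code)))
  d <- which(aa_a != aa_b)
  data.frame(codon = d - 1L, aa_a = aa_a[d], aa_b = aa_b[d],
             stringsAsFactors = FALSE)
}
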