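#' Caller configuration
#'
#' Parameters of the genotype-likelihood SNV caller. The confidence
#' thresholds follow the UnifiedGenotyper-style convention: calls with
#' phred quality at or above `emit_conf` are emitted, and additionally
#' marked `PASS` when at or above `call_conf` (else `LowQual`). The
#' per-read error probability `base_error` is fixed rather than taken
#' per-base, since low-quality bases are already removed at the pileup.
#'
#' @param base_error Per-read base error probability (0 < eps < 0.5).
#' @param call_conf Phred confidence for a `PASS` call (default 30.0).
#' @param emit_conf Phred confidence to emit at all (default 10.0).
#' @param multiallelic_min_fraction Minimum fraction of the depth for a
#'   third allele to flag the site multiallelic (default 0.10).
#' @return A list of class `caller_config`.
#' @export
caller_config <- function(base_error = 0.01, call_conf = 30.0,
                          emit_conf = 10.0, multiallelic_min_fraction = 0.10) {
  if (base_error <= 0 || base_error >= 0.5)
    stop("caller_config: base_error must be in (0, 0.5)")
  if (call_conf < emit_conf || emit_conf < 0)
    stop("caller_config: need call_conf >= emit_conf >= 0")
  structure(list(base_error = base_error, call_conf = call_conf,
                 emit_conf = emit_conf,
                 multiallelic_min_fraction = multiallelic_min_fraction),
            class = "caller_config")
}

#' Reduce a pileup column to its top two alleles
#'
#' Alleles are ranked by count (ties broken by quality sum, then
#' alphabetically). If a third allele reaches
#' `multiallelic_min_fraction` of the depth the site is flagged
#' multiallelic: diploid phasing can only carry two alleles, so the flag
#' propagates to the block and drives the allele-separation rescue.
#'
#' @param counts Named integer vector over `A,C,G,T`.
#' @param qual_sums Named numeric vector over `A,C,G,T`.
#' @param min_fraction Third-allele flag threshold.
#' @return List with `a1`, `a2` (allele characters, `NA` if absent) and
#'   `multiallelic`.
#' @export
reduce_to_biallelic <- function(counts, qual_sums = NULL, min_fraction = 0.10) {
  al <- c("A", "C", "G", "T")
  cnt <- stats::setNames(rep(0L, 4L), al)
  cnt[names(counts)] <- counts
  if (is.null(qual_sums)) qual_sums <- cnt
  qs <- stats::setNames(rep(0, 4L), al)
  qs[names(qual_sums)] <- qual_sums
  o <- order(-cnt, -qs, al)
  depth <- sum(cnt)
  present <- cnt[o] > 0L
  a1 <- if (present[1L]) al[o[1L]] else NA_character_
  a2 <- if (sum(present) >= 2L) al[o[2L]] else NA_character_
  ma <- sum(present) >= 3L && depth > 0L &&
    (cnt[o[3L]] / depth) >= min_fraction
  list(a1 = a1, a2 = a2, multiallelic = ma)
}

## Genotype log10-likelihoods for counts (n1, n2) over alleles (a1, a2):
## hom-a1, het, hom-a2. Per-read: (1 - eps) if the base matches a
## genotype allele, eps otherwise; 0.5 per read under the het genotype.
genotype_log10lik <- function(n1, n2, eps) {
  c(hom1 = n1 * log10(1 - eps) + n2 * log10(eps),
    het = (n1 + n2) * log10(0.5),
    hom2 = n1 * log10(eps) + n2 * log10(1 - eps))
}

## phred-scaled confidence of the best genotype under a flat prior:
## -10 log10(1 - posterior_best), computed in log space
genotype_qual <- function(ll) {
  best <- which.max(ll)
  rest <- ll[-best]
  m <- max(ll)
  lse_all <- m + log10(sum(10^(ll - m)))
  mr <- max(rest)
  lse_rest <- mr + log10(sum(10^(rest - mr)))
  -10 * (lse_rest - lse_all)
}

#' Call biallelic SNVs from a pileup
#'
#' Per column the top two alleles are taken and a three-genotype
#' likelihood model (hom/het/hom, flat prior) is evaluated; non-reference
#' calls with phred quality at or above `emit_conf` are emitted, and
#' marked `PASS` or `LowQual` against `call_conf`. Indels are never
#' produced: the model is substitution-only by construction, so every
#' call preserves the reference length.
#'
#' @param pileup A `pileup` from [build_pileup()].
#' @param reference The `genome_sequence` the pileup was built on.
#' @param config A [caller_config()].
#' @return A data.frame of class `snv_calls` with columns `pos` (0-based),
#'   `ref`, `allele1`, `allele2` (the two genotype alleles; for het calls
#'   containing the reference allele, `allele1` is the reference),
#'   `genotype` (`"het"` or `"hom_alt"`), `qual`, `filter`, `ad1`, `ad2`,
#'   `depth`, `multiallelic`.
#' @export
call_snvs <- function(pileup, reference, config = caller_config()) {
  empty <- data.frame(pos = integer(0), ref = character(0),
                      allele1 = character(0), allele2 = character(0),
                      genotype = character(0), qual = numeric(0),
                      filter = character(0), ad1 = integer(0),
                      ad2 = integer(0), ad_ref = integer(0),
                      depth = integer(0),
                      multiallelic = logical(0), stringsAsFactors = FALSE)
  class(empty) <- c("snv_calls", "data.frame")
  if (nrow(pileup) == 0L) return(empty)
  eps <- config$base_error
  rows <- vector("list", nrow(pileup))
  for (i in seq_len(nrow(pileup))) {
    if (pileup$depth[i] == 0L) next
    cnt <- c(A = pileup$A[i], C = pileup$C[i], G = pileup$G[i], T = pileup$T[i])
    qs <- c(A = pileup$qA[i], C = pileup$qC[i], G = pileup$qG[i], T = pileup$qT[i])
    tb <- reduce_to_biallelic(cnt, qs, config$multiallelic_min_fraction)
    a1 <- tb$a1; a2 <- tb$a2
    ref <- pileup$ref[i]
    if (is.na(a2)) {
      if (a1 == ref) next           # monomorphic reference column
      ## forced hom-alt comparison vs the reference base; against a
      ## masked (N) reference any other base serves as the null allele
      a2 <- if (ref %in% names(cnt)) ref else
        setdiff(c("A", "C", "G", "T"), a1)[1L]
    }
    n1 <- cnt[[a1]]; n2 <- cnt[[a2]]
    ll <- genotype_log10lik(n1, n2, eps)
    best <- which.max(ll)
    gt_alleles <- switch(best, c(a1, a1), c(a1, a2), c(a2, a2))
    if (gt_alleles[1L] == gt_alleles[2L] && gt_alleles[1L] == ref) next
    q <- genotype_qual(ll)
    if (q < config$emit_conf) next
    het <- best == 2L
    if (het && a2 == ref) { tmp <- a1; a1 <- a2; a2 <- tmp
                            n1 <- cnt[[a1]]; n2 <- cnt[[a2]] }
    rows[[i]] <- data.frame(
      pos = pileup$pos[i], ref = ref,
      allele1 = if (het) a1 else gt_alleles[1L],
      allele2 = if (het) a2 else gt_alleles[2L],
      genotype = if (het) "het" else "hom_alt",
      qual = q,
      filter = if (q >= config$call_conf) "PASS" else "LowQual",
      ad1 = if (het) n1 else cnt[[gt_alleles[1L]]],
      ad2 = if (het) n2 else cnt[[gt_alleles[1L]]],
      ad_ref = if (ref %in% names(cnt)) cnt[[ref]] else 0L,
      depth = pileup$depth[i], multiallelic = tb$multiallelic,
      stringsAsFactors = FALSE)
  }
  keep <- !vapply(rows, is.null, logical(1))
  out <- if (any(keep)) do.call(rbind, rows[keep]) else empty
  rownames(out) <- NULL
  class(out) <- c("snv_calls", "data.frame")
  out
}
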