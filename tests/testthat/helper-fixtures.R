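## Shared fixture builders. All fixtures are constructed in code.

chars <- function(s) strsplit(s, "", fixed = TRUE)[[1L]]
collapse <- function(v) paste0(v, collapse = "")

## a read_alignments table from terse per-read specs
fx_reads <- function(ids, starts, seqs, quals = NULL, cigars = NULL,
                     ref_id = "ref", strand = "+", frag_id = ids,
                     paired = FALSE, first_of_pair = TRUE) {
  if (is.null(quals)) quals <- strrep("I", nchar(seqs))  # phred 40
  if (is.null(cigars)) cigars <- sprintf("%dM", nchar(seqs))
  read_alignments(read_id = ids, ref_id = ref_id, start = starts,
                  cigar = cigars, seq = seqs, qual = quals,
                  strand = strand, frag_id = frag_id, paired = paired,
                  first_of_pair = first_of_pair, proper = paired)
}

## a pileup data.frame from a list pos -> named counts, e.g.
## fx_pileup(list(`50` = c(A = 6, G = 4)), reference)
fx_pileup <- function(cols, reference, qual_per_read = 30) {
  refv <- chars(reference$bases)
  pos <- as.integer(names(cols))
  m <- matrix(0L, length(cols), 4L,
              dimnames = list(NULL, c("A", "C", "G", "T")))
  for (i in seq_along(cols)) m[i, names(cols[[i]])] <- cols[[i]]
  pu <- data.frame(pos = pos, ref = refv[pos + 1L],
                   A = m[, "A"], C = m[, "C"], G = m[, "G"], T = m[, "T"],
                   qA = m[, "A"] * qual_per_read,
                   qC = m[, "C"] * qual_per_read,
                   qG = m[, "G"] * qual_per_read,
                   qT = m[, "T"] * qual_per_read,
                   stringsAsFactors = FALSE)
  pu$depth <- pu$A + pu$C + pu$G + pu$T
  class(pu) <- c("pileup", "data.frame")
  attr(pu, "ref_length") <- nchar(reference$bases)
  sc <- integer(nchar(reference$bases))
  sc[pos + 1L] <- pmax(pu$depth, 1L)
  attr(pu, "span_coverage") <- sc
  pu
}

## an snv_calls table for hand-built het sites
fx_hets <- function(pos, allele1, allele2, ref = allele1,
                    multiallelic = FALSE) {
  df <- data.frame(pos = as.integer(pos), ref = ref, allele1 = allele1,
                   allele2 = allele2, genotype = "het", qual = 50,
                   filter = "PASS", ad1 = 10L, ad2 = 10L, ad_ref = 10L,
                   depth = 20L, multiallelic = multiallelic,
                   stringsAsFactors = FALSE)
  class(df) <- c("snv_calls", "data.frame")
  df
}

## random phasing instance: k het sites on a random reference, two true
## haplotypes, n single-end reads covering windows of adjacent sites.
## Returns everything both the package path and the oracle need.
fx_phase_instance <- function(seed, k_max = 8L, n_max = 50L,
                              err = 0.01, spacing = 15L) {
  withr::with_seed(seed, {
    k <- sample(2:k_max, 1L)
    n <- sample(10:n_max, 1L)
    site_pos <- cumsum(c(20L, sample(5:spacing, k - 1L, replace = TRUE)))
    L <- max(site_pos) + 40L
    refv <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
    allele1 <- refv[site_pos + 1L]
    allele2 <- vapply(allele1, function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1L), character(1))
    true_side <- c(1L, sample(1:2, k - 1L, replace = TRUE))  # hap A sides
    starts <- integer(n); seqs <- character(n)
    hap_of <- sample(1:2, n, replace = TRUE)
    for (i in seq_len(n)) {
      first <- sample(seq_len(k), 1L)
      nsites <- sample(1:3, 1L)
      last <- min(k, first + nsites - 1L)
      s <- max(0L, site_pos[first] - sample(2:8, 1L))
      e <- min(L - 1L, site_pos[last] + sample(2:8, 1L))
      v <- refv[(s + 1L):(e + 1L)]
      for (j in seq_len(k)) {
        p <- site_pos[j]
        if (p < s || p > e) next
        side <- if (hap_of[i] == 1L) true_side[j] else 3L - true_side[j]
        base <- if (side == 1L) allele1[j] else allele2[j]
        if (stats::runif(1) < err)
          base <- sample(setdiff(c("A", "C", "G", "T"), base), 1L)
        v[p - s + 1L] <- base
      }
      starts[i] <- s
      seqs[i] <- collapse(v)
    }
    list(k = k, site_pos = site_pos, allele1 = allele1, allele2 = allele2,
         true_side = true_side,
         reads = fx_reads(sprintf("r%03d", seq_len(n)), starts, seqs),
         snvs = fx_hets(site_pos, allele1, allele2, ref = allele1))
  })
}
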