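## Phased VCF 4.2 writer/reader (SNV-only subset with GT/PS/AD/DP).
##
## Indels are rejected outright: the pipeline excludes them so that every
## consensus keeps the reference length. Phased genotypes are written
## "a|b" with a PS tag equal to the 1-based position of the block's first
## site; unphased het sites are written "a/b" with PS missing.

vcf_allele_index <- function(allele, ref, alts) {
  if (allele == ref) 0L else match(allele, alts)
}

#' Write SNV calls and phased blocks as VCF 4.2
#'
#' @param snvs An `snv_calls` table.
#' @param blocks List of `phased_block` objects over the same sites.
#' @param path Output path.
#' @param reference The `genome_sequence` (contig name and length).
#' @param sample Sample column name.
#' @return `path`, invisibly.
#' @export
write_phased_vcf <- function(snvs, blocks, path, reference,
                             sample = "SAMPLE") {
  if (any(nchar(snvs$ref) != 1L | nchar(snvs$allele1) != 1L |
          nchar(snvs$allele2) != 1L))
    stop("write_phased_vcf: indel alleles are not supported")
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##contig=<ID=%s,length=%d>", reference$id,
                   genome_length(reference)),
           "##INFO=<ID=MA,Number=0,Type=Flag,Description=\"Multiallelic site: substantial third allele observed\">",
           "##FILTER=<ID=LowQual,Description=\"Call confidence below the call threshold\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "##FORMAT=<ID=PS,Number=1,Type=Integer,Description=\"Phase set (1-based start of the phased block)\">",
           "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allele depths\">",
           "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
           paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                 "INFO", "FORMAT", sample, sep = "\t"))

  ## site -> phasing info from multi-site blocks
  ps <- rep(NA_integer_, nrow(snvs))
  hap0 <- rep(NA_character_, nrow(snvs))
  hap1 <- rep(NA_character_, nrow(snvs))
  for (blk in blocks) {
    if (!isTRUE(blk$phased)) next
    m <- match(blk$sites$pos, snvs$pos)
    ps[m] <- blk$start + 1L
    hap0[m] <- blk$hap0
    hap1[m] <- blk$hap1
  }

  o <- order(snvs$pos)
  rec <- character(nrow(snvs))
  for (r in seq_len(nrow(snvs))) {
    i <- o[r]
    ref <- snvs$ref[i]
    gt_al <- unique(c(snvs$allele1[i], snvs$allele2[i]))
    alts <- setdiff(gt_al, ref)
    ad_map <- stats::setNames(c(snvs$ad_ref[i], snvs$ad1[i], snvs$ad2[i]),
                              c(ref, snvs$allele1[i], snvs$allele2[i]))
    ad <- vapply(c(ref, alts), function(a)
      if (a %in% names(ad_map)) ad_map[[a]] else 0L, numeric(1))
    if (!is.na(ps[i])) {
      gt <- paste0(vcf_allele_index(hap0[i], ref, alts), "|",
                   vcf_allele_index(hap1[i], ref, alts))
      psf <- as.character(ps[i])
    } else if (snvs$genotype[i] == "het") {
      gt <- paste0(vcf_allele_index(snvs$allele1[i], ref, alts), "/",
                   vcf_allele_index(snvs$allele2[i], ref, alts))
      psf <- "."
    } else {
      gt <- sprintf("%d/%d", vcf_allele_index(snvs$allele1[i], ref, alts),
                    vcf_allele_index(snvs$allele2[i], ref, alts))
      psf <- "."
    }
    rec[r] <- paste(reference$id, snvs$pos[i] + 1L, ".", ref,
                    paste(alts, collapse = ","),
                    sprintf("%.2f", snvs$qual[i]), snvs$filter[i],
                    if (snvs$multiallelic[i]) "MA" else ".",
                    "GT:PS:AD:DP",
                    paste(gt, psf, paste(round(ad), collapse = ","),
                          snvs$depth[i], sep = ":"),
                    sep = "\t")
  }
  writeLines(c(hdr, rec), path)
  invisible(path)
}

#' Read a phased VCF written by [write_phased_vcf()]
#'
#' Reconstructs the retained fields: the SNV table and the phased-block
#' set (site positions, alleles, haplotype vectors, multiallelic flag).
#' Supporting-read sets and pair phase qualities are not stored in VCF
#' and come back empty/NA. Unphased het records become single-site
#' blocks, matching the phaser's convention.
#'
#' @param path VCF path.
#' @return List with elements `snvs` (an `snv_calls` table) and `blocks`
#'   (list of `phased_block` objects).
#' @export
read_phased_vcf <- function(path) {
  if (!file.exists(path)) stop("VCF file not found: ", path)
  ln <- readLines(path)
  body <- ln[!startsWith(ln, "#") & nzchar(ln)]
  n <- length(body)
  pos <- integer(n); ref <- character(n)
  allele1 <- character(n); allele2 <- character(n)
  genotype <- character(n); qual <- numeric(n); filter <- character(n)
  multiallelic <- logical(n); psv <- rep(NA_integer_, n)
  h0 <- character(n); h1 <- character(n); phased <- logical(n)
  ad1 <- integer(n); ad2 <- integer(n); adr <- integer(n); dp <- integer(n)
  chrom <- character(n)
  for (i in seq_len(n)) {
    f <- strsplit(body[i], "\t", fixed = TRUE)[[1L]]
    chrom[i] <- f[1L]
    pos[i] <- as.integer(f[2L]) - 1L
    ref[i] <- f[4L]
    alts <- strsplit(f[5L], ",", fixed = TRUE)[[1L]]
    if (any(nchar(c(ref[i], alts)) != 1L))
      stop("read_phased_vcf: indel record at POS ", f[2L])
    qual[i] <- as.numeric(f[6L]); filter[i] <- f[7L]
    multiallelic[i] <- grepl("(^|;)MA(;|$)", f[8L])
    fmt <- strsplit(f[9L], ":", fixed = TRUE)[[1L]]
    val <- strsplit(f[10L], ":", fixed = TRUE)[[1L]]
    gt <- val[match("GT", fmt)]
    psf <- val[match("PS", fmt)]
    adf <- val[match("AD", fmt)]
    dp[i] <- as.integer(val[match("DP", fmt)])
    phased[i] <- grepl("|", gt, fixed = TRUE)
    gti <- as.integer(strsplit(gt, "[/|]")[[1L]])
    alleles <- c(ref[i], alts)
    a <- alleles[gti[1L] + 1L]; b <- alleles[gti[2L] + 1L]
    h0[i] <- a; h1[i] <- b
    if (a == b) {
      genotype[i] <- "hom_alt"; allele1[i] <- a; allele2[i] <- b
    } else {
      genotype[i] <- "het"
      if (b == ref[i]) { allele1[i] <- b; allele2[i] <- a }
      else if (a == ref[i]) { allele1[i] <- a; allele2[i] <- b }
      else { allele1[i] <- a; allele2[i] <- b }
    }
    if (!is.na(psf) && psf != ".") psv[i] <- as.integer(psf)
    adv <- as.integer(strsplit(adf, ",", fixed = TRUE)[[1L]])
    adr[i] <- adv[1L]
    amap <- stats::setNames(adv, alleles[seq_along(adv)])
    ad1[i] <- if (allele1[i] %in% names(amap)) amap[[allele1[i]]] else 0L
    ad2[i] <- if (allele2[i] %in% names(amap)) amap[[allele2[i]]] else 0L
  }
  snvs <- data.frame(pos = pos, ref = ref, allele1 = allele1,
                     allele2 = allele2, genotype = genotype, qual = qual,
                     filter = filter, ad1 = ad1, ad2 = ad2, ad_ref = adr,
                     depth = dp, multiallelic = multiallelic,
                     stringsAsFactors = FALSE)
  o <- order(snvs$pos)
  snvs <- snvs[o, , drop = FALSE]
  rownames(snvs) <- NULL
  class(snvs) <- c("snv_calls", "data.frame")
  h0 <- h0[o]; h1 <- h1[o]; psv <- psv[o]; phased <- phased[o]
  chrom <- chrom[o]

  blocks <- list()
  het_rows <- which(snvs$genotype == "het")
  grp <- ifelse(phased & !is.na(psv), paste0("PS", psv), paste0("U", seq_len(nrow(snvs))))
  for (g in unique(grp[het_rows])) {
    idx <- het_rows[grp[het_rows] == g]
    idx <- idx[order(snvs$pos[idx])]
    blocks[[length(blocks) + 1L]] <- structure(list(
      ref_id = chrom[idx[1L]],
      start = snvs$pos[idx[1L]],
      end = snvs$pos[idx[length(idx)]] + 1L,
      sites = snvs[idx, , drop = FALSE],
      hap0 = h0[idx], hap1 = h1[idx],
      pair_pq = rep(NA_real_, max(0L, length(idx) - 1L)),
      phased = length(idx) > 1L,
      hap_read_ids = list(character(0), character(0)),
      chimeric_read_ids = character(0),
      uninformative_read_ids = character(0),
      chimeric_fraction = 0,
      multiallelic = any(snvs$multiallelic[idx])), class = "phased_block")
  }
  ord <- order(vapply(blocks, function(b) b$start, numeric(1)))
  list(snvs = snvs, blocks = blocks[ord])
}
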