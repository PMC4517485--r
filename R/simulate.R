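## Seeded simulator: organellar genome, diverged inserted copies (odins)
## and sequencing reads (modern or ancient-DNA models) with full ground
## truth. Odin reads are recorded at their homologous organellar
## coordinates, carrying their divergent alleles — the truth-placement
## model of cross-mapping that the internal mapper filters by mismatch
## fraction.

#' Specify an odin (inserted organellar copy)
#'
#' @param source_start,source_end 0-based half-open interval on the
#'   organellar genome the copy derives from.
#' @param divergence Per-site substitution probability of the copy
#'   relative to its template, in `[0, 0.25]`.
#' @param copies Number of independent copies with this spec.
#' @param relative_depth Expected read depth of each copy as a multiple
#'   of the organellar depth.
#' @param from_copy Optional index of a previously generated copy to use
#'   as the template instead of the organelle — a nested insertion
#'   family (copy of a copy), the common topology of real numt clusters.
#' @return An `odin_spec`.
#' @export
odin_spec <- function(source_start, source_end, divergence,
                      copies = 1L, relative_depth = 1,
                      from_copy = NA_integer_) {
  if (divergence < 0 || divergence > 0.25)
    stop("odin_spec: divergence must be in [0, 0.25]")
  if (copies < 1L) stop("odin_spec: copies must be >= 1")
  if (source_end <= source_start) stop("odin_spec: empty source interval")
  structure(list(source_start = as.integer(source_start),
                 source_end = as.integer(source_end),
                 divergence = divergence, copies = as.integer(copies),
                 relative_depth = relative_depth,
                 from_copy = from_copy), class = "odin_spec")
}

derive_seed <- function(seed, k) {
  (abs(as.integer(seed)) + 7919L * as.integer(k)) %% 2147483587L
}

#' Simulate an organellar genome with inserted copies and ground truth
#'
#' @param genome_length Organelle length in bp.
#' @param gc GC fraction of the organelle.
#' @param odins List of [odin_spec()]s.
#' @param seed Integer seed controlling every draw.
#' @param circular Circularity of the organelle.
#' @return A `sim_truth`: `organelle` (a `genome_sequence`), `copies`
#'   (list with `seq`, `start`, `end`, `relative_depth`, `positions` —
#'   0-based organellar coordinates of the copy's substitutions), and
#'   `seed`.
#' @export
simulate_truth <- function(genome_length = 20000L, gc = 0.4,
                           odins = list(), seed = 1L, circular = TRUE) {
  org <- simulate_genome(genome_length, gc, seed = derive_seed(seed, 1L),
                         circular = circular)
  copies <- list()
  k <- 0L
  for (sp in odins) {
    for (cc in seq_len(sp$copies)) {
      k <- k + 1L
      template <- if (is.na(sp$from_copy)) {
        substr(org$bases, sp$source_start + 1L, sp$source_end)
      } else {
        if (sp$from_copy > length(copies))
          stop("simulate_truth: from_copy refers to a copy not yet generated")
        copies[[sp$from_copy]]$seq
      }
      start <- if (is.na(sp$from_copy)) sp$source_start else
        copies[[sp$from_copy]]$start
      dv <- apply_divergence(template, sp$divergence,
                             seed = derive_seed(seed, 100L + k),
                             id = paste0("copy", k))
      prev_pos <- if (is.na(sp$from_copy)) integer(0) else
        copies[[sp$from_copy]]$positions
      copies[[k]] <- list(name = paste0("copy", k),
                          seq = dv$seq$bases,
                          start = start,
                          end = start + nchar(dv$seq$bases),
                          relative_depth = sp$relative_depth,
                          positions = sort(unique(c(prev_pos,
                                                    start + dv$positions))))
    }
  }
  structure(list(organelle = org, copies = copies, seed = seed),
            class = "sim_truth")
}

#' @export
print.sim_truth <- function(x, ...) {
  cat(sprintf("sim_truth: organelle %d bp, %d inserted cop%s\n",
              genome_length(x$organelle), length(x$copies),
              if (length(x$copies) == 1L) "y" else "ies"))
  invisible(x)
}

## truncated log-normal fragment lengths for the aDNA model
adna_fragment_lengths <- function(n, mode = 45, sdlog = 0.35,
                                  range = c(30, 80)) {
  meanlog <- log(mode) + sdlog^2
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rlnorm(2L * (n - length(out)) + 10L, meanlog, sdlog)
    out <- c(out, x[x >= range[1L] & x <= range[2L]])
  }
  as.integer(round(out[seq_len(n)]))
}

#' Simulate sequencing reads with ground truth
#'
#' Reads are drawn uniformly from the organelle and from each inserted
#' copy in proportion to its `relative_depth`. Sequencing errors are
#' i.i.d. substitutions at rate `error`. In aDNA mode fragment lengths
#' follow a truncated log-normal (mode ~45 bp, range 30-80 bp by
#' default) and C at 5'-terminal positions is deaminated to T at
#' `deamination` (halving with each position into the read). Every read
#' is recorded at its homologous organellar coordinate; odin reads carry
#' their copy's divergent alleles there, emulating cross-mapping.
#'
#' @param truth A `sim_truth`.
#' @param depth Organellar fold coverage (> 0).
#' @param read_len Read length in bp (modern model).
#' @param error Per-base sequencing error rate.
#' @param paired Simulate mate pairs (insert-size fragments, one mate at
#'   each end, reference-oriented).
#' @param insert Fragment length for paired mode.
#' @param adna Use the ancient-DNA model (single-end, variable length).
#' @param deamination 5'-terminal C-to-T rate in aDNA mode.
#' @param adna_len_mode,adna_len_range Fragment-length distribution of
#'   the aDNA model.
#' @param seed Integer seed.
#' @return A `sim_reads` data.frame: `read_id`, `frag_id`, `origin`,
#'   `truth_start` (0-based organellar), `len`, `strand`, `seq`, `qual`,
#'   `paired`, `first_of_pair`, with attribute `truth`.
#' @export
simulate_reads <- function(truth, depth = 50, read_len = 90L,
                           error = 0.002, paired = FALSE, insert = 300L,
                           adna = FALSE, deamination = 0,
                           adna_len_mode = 45, adna_len_range = c(30, 80),
                           seed = 1L) {
  if (depth <= 0) stop("simulate_reads: depth must be > 0")
  L <- genome_length(truth$organelle)
  if (read_len > L) stop("simulate_reads: read_len exceeds genome length")
  sources <- c(list(list(name = "organelle", seq = truth$organelle$bases,
                         start = 0L, end = L, relative_depth = 1)),
               truth$copies)
  rows <- list()
  withr::with_seed(derive_seed(seed, 31L), {
    for (src in sources) {
      slen <- nchar(src$seq)
      if (adna) {
        mean_len <- adna_len_mode + 2  # close enough for target depth
        nfrag <- max(1L, as.integer(round(depth * src$relative_depth *
                                            slen / mean_len)))
        flen <- adna_fragment_lengths(nfrag, adna_len_mode,
                                      range = adna_len_range)
        flen <- pmin(flen, slen)
        fstart <- vapply(flen, function(l)
          sample.int(slen - l + 1L, 1L) - 1L, integer(1))
        strand <- sample(c("+", "-"), nfrag, replace = TRUE)
        seqs <- substring(src$seq, fstart + 1L, fstart + flen)
        rows[[length(rows) + 1L]] <- data.frame(
          read_id = sprintf("%s_f%06d", src$name, seq_len(nfrag)),
          frag_id = sprintf("%s_f%06d", src$name, seq_len(nfrag)),
          origin = src$name,
          truth_start = src$start + fstart, len = flen, strand = strand,
          seq = seqs, paired = FALSE, first_of_pair = TRUE,
          stringsAsFactors = FALSE)
      } else if (paired) {
        nfrag <- max(1L, as.integer(round(depth * src$relative_depth *
                                            slen / (2 * read_len))))
        ## library insert sizes vary (~10% sd); also lets mate pairs link
        ## het sites at any separation up to the insert
        ins <- as.integer(round(stats::rnorm(nfrag, insert, 0.1 * insert)))
        ins <- pmin(pmax(ins, 2L * read_len + 10L), slen)
        fstart <- as.integer(floor(stats::runif(nfrag) * (slen - ins + 1L)))
        m1 <- data.frame(
          read_id = sprintf("%s_f%06d/1", src$name, seq_len(nfrag)),
          frag_id = sprintf("%s_f%06d", src$name, seq_len(nfrag)),
          origin = src$name, truth_start = src$start + fstart,
          len = read_len, strand = "+",
          seq = substring(src$seq, fstart + 1L, fstart + read_len),
          paired = TRUE, first_of_pair = TRUE, stringsAsFactors = FALSE)
        m2s <- fstart + ins - read_len
        m2 <- data.frame(
          read_id = sprintf("%s_f%06d/2", src$name, seq_len(nfrag)),
          frag_id = m1$frag_id, origin = src$name,
          truth_start = src$start + m2s, len = read_len, strand = "-",
          seq = substring(src$seq, m2s + 1L, m2s + read_len),
          paired = TRUE, first_of_pair = FALSE, stringsAsFactors = FALSE)
        rows[[length(rows) + 1L]] <- rbind(m1, m2)
      } else {
        rl <- min(read_len, slen)
        nfrag <- max(1L, as.integer(round(depth * src$relative_depth *
                                            slen / rl)))
        fstart <- sample.int(slen - rl + 1L, nfrag, replace = TRUE) - 1L
        rows[[length(rows) + 1L]] <- data.frame(
          read_id = sprintf("%s_f%06d", src$name, seq_len(nfrag)),
          frag_id = sprintf("%s_f%06d", src$name, seq_len(nfrag)),
          origin = src$name, truth_start = src$start + fstart,
          len = rl, strand = sample(c("+", "-"), nfrag, replace = TRUE),
          seq = substring(src$seq, fstart + 1L, fstart + rl),
          paired = FALSE, first_of_pair = TRUE, stringsAsFactors = FALSE)
      }
    }
    df <- do.call(rbind, rows)

    ## aDNA deamination: 5' C->T, halving per position into the read
    if (adna && deamination > 0) {
      for (i in seq_len(nrow(df))) {
        v <- s2c(df$seq[i])
        n <- length(v)
        idx5 <- if (df$strand[i] == "+") seq_len(min(8L, n)) else
          n + 1L - seq_len(min(8L, n))
        p <- deamination * 0.5^(seq_along(idx5) - 1L)
        hit <- v[idx5] == "C" & stats::runif(length(idx5)) < p
        v[idx5[hit]] <- "T"
        df$seq[i] <- c2s(v)
      }
    }

    ## i.i.d. sequencing errors
    if (error > 0) {
      for (i in seq_len(nrow(df))) {
        v <- s2c(df$seq[i])
        hit <- which(stats::runif(length(v)) < error)
        if (length(hit)) {
          v[hit] <- vapply(v[hit], function(b)
            sample(setdiff(c("A", "C", "G", "T"), b), 1L), character(1))
          df$seq[i] <- c2s(v)
        }
      }
    }

    ## per-base qualities jitter around phred 37 (33-40); ties in the
    ## duplicate-marking quality sums are thereby broken at random
    ## rather than by read order
    qchars <- intToUtf8(33L + 33:40, multiple = TRUE)
    df$qual <- vapply(df$len, function(l)
      c2s(qchars[sample.int(8L, l, replace = TRUE)]), character(1))
  })
  attr(df, "truth") <- truth
  class(df) <- c("sim_reads", "data.frame")
  df
}

#' Truth placements of simulated reads as alignments
#'
#' Places every simulated read (including odin reads) at its homologous
#' organellar coordinate with an all-M CIGAR.
#'
#' @param sim A `sim_reads` table.
#' @param ref_id Reference name to record.
#' @return A `read_alignments` table.
#' @export
truth_alignments <- function(sim, ref_id = NULL) {
  truth <- attr(sim, "truth")
  if (is.null(ref_id)) ref_id <- truth$organelle$id
  read_alignments(read_id = sim$read_id, ref_id = ref_id,
                  start = sim$truth_start,
                  cigar = sprintf("%dM", sim$len),
                  seq = sim$seq, qual = sim$qual, mapq = 60L,
                  strand = sim$strand, frag_id = sim$frag_id,
                  paired = sim$paired, first_of_pair = sim$first_of_pair,
                  proper = sim$paired)
}

#' Internal simulation mapper with a mismatch-fraction filter
#'
#' Implements the mapping contract without an external aligner: each
#' read is placed at its truth coordinate on the current reference and
#' kept only if its mismatch fraction (reference N positions excluded)
#' does not exceed `max_mismatch_frac`. As the consensus converges to
#' the organellar truth, insertion reads whose divergence exceeds the
#' cap stop mapping — reproducing the stringency-driven iteration
#' dynamics deterministically.
#'
#' @param sim A `sim_reads` table.
#' @param reference Current `genome_sequence` (same coordinates as the
#'   simulated organelle).
#' @param max_mismatch_frac Mismatch-fraction cap (default 0.04).
#' @return A `read_alignments` table of the retained reads.
#' @export
truth_map_reads <- function(sim, reference, max_mismatch_frac = 0.04) {
  refv <- genome_chars(reference)
  L <- length(refv)
  keep <- logical(nrow(sim))
  for (i in seq_len(nrow(sim))) {
    s <- sim$truth_start[i]
    idx <- (s + 1L):(s + sim$len[i])
    if (s + sim$len[i] > L) {
      if (!reference$circular) next
      idx <- ((idx - 1L) %% L) + 1L
    }
    rv <- refv[idx]
    v <- s2c(sim$seq[i])
    cmp <- rv != "N" & v != "N"
    mm <- sum(v[cmp] != rv[cmp])
    keep[i] <- sum(cmp) > 0L && (mm / sim$len[i]) <= max_mismatch_frac
  }
  out <- truth_alignments(sim[keep, , drop = FALSE], ref_id = reference$id)
  attr(out, "n_input") <- nrow(sim)
  out
}

#' Odin source intervals of a simulation as BED
#' @param truth A `sim_truth`.
#' @return data.frame with `chrom`, `start`, `end`, `name`.
#' @export
truth_odin_bed <- function(truth) {
  if (!length(truth$copies))
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), name = character(0),
                      stringsAsFactors = FALSE))
  data.frame(chrom = truth$organelle$id,
             start = vapply(truth$copies, function(cp) cp$start, integer(1)),
             end = vapply(truth$copies, function(cp) cp$end, integer(1)),
             name = vapply(truth$copies, function(cp) cp$name, character(1)),
             stringsAsFactors = FALSE)
}

#' Build a coverage-based starting reference contaminated by odin alleles
#'
#' Returns the organellar truth with the copy's divergent alleles
#' substituted at a given fraction of its substitution sites — the
#' situation of a published assembly produced by a coverage-based
#' consensus over a region with a high-depth insertion, which is the
#' natural starting reference for the iterative loop.
#'
#' @param truth A `sim_truth` with at least one copy.
#' @param copy Copy index.
#' @param fraction Fraction of the copy's divergent sites carrying the
#'   odin allele in the returned reference.
#' @param seed Integer seed for the site subset.
#' @return A `genome_sequence`.
#' @export
contaminated_reference <- function(truth, copy = 1L, fraction = 2 / 3,
                                   seed = 1L) {
  cp <- truth$copies[[copy]]
  v <- genome_chars(truth$organelle)
  pos <- cp$positions
  take <- withr::with_seed(derive_seed(seed, 77L), {
    sort(pos[sample.int(length(pos), size = round(fraction * length(pos)))])
  })
  cpv <- s2c(cp$seq)
  v[take + 1L] <- cpv[take - cp$start + 1L]
  genome_sequence(paste0(truth$organelle$id, "_contaminated"), c2s(v),
                  truth$organelle$circular)
}

#' Write a simulation to disk (FASTQ, truth SAM, BED, JSON manifest)
#'
#' @param sim A `sim_reads` table.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  truth <- attr(sim, "truth")
  paths <- c(fastq = file.path(dir, "reads.fastq"),
             truth_fasta = file.path(dir, "organelle.fasta"),
             truth_sam = file.path(dir, "truth_placements.sam"),
             odin_bed = file.path(dir, "odin_sources.bed"),
             truth_json = file.path(dir, "sim_truth.json"))
  write_fastq(sim$read_id, sim$seq, sim$qual, paths["fastq"])
  write_fasta(truth$organelle, paths["truth_fasta"])
  write_sam(truth_alignments(sim), truth$organelle, paths["truth_sam"])
  write_bed(truth_odin_bed(truth), paths["odin_bed"])
  js <- list(seed = truth$seed,
             organelle_length = genome_length(truth$organelle),
             copies = lapply(truth$copies, function(cp)
               list(name = cp$name, start = cp$start, end = cp$end,
                    relative_depth = cp$relative_depth,
                    n_divergent_sites = length(cp$positions))),
             read_origins = stats::setNames(as.list(sim$origin), sim$read_id))
  jsonlite::write_json(js, paths["truth_json"], auto_unbox = TRUE)
  invisible(paths)
}
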