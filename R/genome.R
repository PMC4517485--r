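#' Construct a genome sequence
#'
#' Lightweight container for a single reference or haplotype sequence:
#' an id, an upper-case nucleotide string and a circularity flag
#' (organellar genomes are usually circular).
#'
#' @param id Character scalar label.
#' @param bases Nucleotide string over the IUPAC alphabet (at least
#'   `A`,`C`,`G`,`T`,`N`; ambiguity codes are accepted but the pipeline
#'   only emits `ACGTN`).
#' @param circular Logical; treat coordinates modulo the length.
#' @return An object of class `genome_sequence` with fields `id`, `bases`,
#'   `circular`.
#' @examples
#' g <- genome_sequence("mt", "ACGTACGT")
#' genome_length(g)
#' @export
genome_sequence <- function(id, bases, circular = FALSE) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  stopifnot(is.character(bases), length(bases) == 1L)
  bases <- toupper(bases)
  if (nchar(bases) == 0L) stop("genome_sequence: empty sequence")
  if (grepl("[^ACGTNRYSWKMBDHV]", bases))
    stop("genome_sequence: non-IUPAC characters in sequence '", id, "'")
  structure(list(id = id, bases = bases, circular = isTRUE(circular)),
            class = "genome_sequence")
}

#' @export
print.genome_sequence <- function(x, ...) {
  cat(sprintf("genome_sequence '%s': %d bp%s\n", x$id, nchar(x$bases),
              if (x$circular) " (circular)" else ""))
  invisible(x)
}

#' Length of a genome sequence in bp
#' @param g A `genome_sequence`.
#' @return Integer length.
#' @export
genome_length <- function(g) nchar(g$bases)

## split a string into single characters (hot path helper)
s2c <- function(s) strsplit(s, "", fixed = TRUE)[[1L]]

c2s <- function(v) paste0(v, collapse = "")

#' Convert a genome sequence to a character vector of bases
#' @param g A `genome_sequence` or a plain string.
#' @return Character vector, one base per element.
#' @export
genome_chars <- function(g) {
  if (inherits(g, "genome_sequence")) s2c(g$bases) else s2c(g)
}

#' Simulate a random genome
#'
#' Draws i.i.d. bases at a given GC content. Used as the organellar
#' ground-truth sequence in simulations.
#'
#' @param length Length in bp (>= 1).
#' @param gc Target GC fraction in `[0, 1]`.
#' @param seed Integer seed; the draw is fully reproducible.
#' @param circular Logical circularity flag of the result.
#' @param id Sequence label.
#' @return A `genome_sequence`.
#' @export
simulate_genome <- function(length, gc = 0.4, seed = 1L, circular = TRUE,
                            id = "sim_organelle") {
  if (length < 1) stop("simulate_genome: length must be >= 1")
  if (gc < 0 || gc > 1) stop("simulate_genome: gc must be in [0, 1]")
  bases <- withr::with_seed(seed, {
    sample(c("A", "C", "G", "T"), length, replace = TRUE,
           prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
  })
  genome_sequence(id, c2s(bases), circular = circular)
}

#' Apply random substitutions to a sequence
#'
#' Independently substitutes each site with the given probability to a
#' uniformly chosen different base. Substitution-only by design: the
#' pipeline excludes indels, so inserted-copy divergence is modelled at
#' the nucleotide level.
#'
#' @param seq A `genome_sequence` or nucleotide string.
#' @param rate Per-site substitution probability in `[0, 0.25]`.
#' @param seed Integer seed.
#' @param id Label for the diverged copy.
#' @return List with `seq` (a `genome_sequence`) and `positions`
#'   (0-based substituted positions).
#' @export
apply_divergence <- function(seq, rate, seed = 1L, id = "diverged") {
  if (rate < 0 || rate > 0.25)
    stop("apply_divergence: rate must be in [0, 0.25]")
  v <- genome_chars(seq)
  pos <- integer(0)
  if (rate > 0) {
    withr::with_seed(seed, {
      hit <- which(stats::runif(length(v)) < rate)
      if (length(hit)) {
        alts <- vapply(v[hit], function(b) {
          sample(setdiff(c("A", "C", "G", "T"), b), 1L)
        }, character(1))
        v[hit] <- alts
      }
      pos <- hit - 1L
    })
  }
  list(seq = genome_sequence(id, c2s(v)), positions = pos)
}

#' Observed GC fraction of a sequence
#' @param g A `genome_sequence` or string.
#' @return Fraction of G/C among A,C,G,T bases.
#' @export
gc_content <- function(g) {
  v <- genome_chars(g)
  v <- v[v %in% c("A", "C", "G", "T")]
  mean(v %in% c("C", "G"))
}

#' Read a FASTA file
#' @param path FASTA file path.
#' @param circular Circularity flag applied to every record.
#' @return List of `genome_sequence` objects, named by record id.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  out <- lapply(seq_along(ss), function(i) {
    id <- sub("\\s.*$", "", names(ss)[i])
    genome_sequence(id, as.character(ss[[i]]))
  })
  names(out) <- vapply(out, function(g) g$id, character(1))
  out
}

#' Write genome sequences to FASTA
#' @param seqs A `genome_sequence` or list of them.
#' @param path Output path.
#' @param headers Optional character vector of record headers (defaults
#'   to the sequence ids).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, headers = NULL) {
  if (inherits(seqs, "genome_sequence")) seqs <- list(seqs)
  ss <- Biostrings::DNAStringSet(vapply(seqs, function(g) g$bases, character(1)))
  names(ss) <- if (is.null(headers))
    vapply(seqs, function(g) g$id, character(1)) else headers
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}
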