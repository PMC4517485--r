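#' Pipeline configuration
#'
#' Houses every numeric threshold of the pipeline: the caller thresholds
#' (phred 30 to pass, 10 to emit), the diploid phase-quality threshold
#' (phred 10), the 2/3 consensus ratio, the coverage-below-1 mask, the
#' iteration budget and convergence rule (0 non-N differences between
#' consecutive consensi), the stall patience before switching to
#' allele-separation mode, and the internal mapper's mismatch-fraction
#' cap.
#'
#' @param caller A [caller_config()].
#' @param phase_quality_thresh Phred threshold for linking het sites.
#' @param phase_eps Per-fragment error of the phase-quality form.
#' @param min_base_qual Phred cutoff for pileup/phasing base calls.
#' @param two_thirds_ratio Ratio of the 2/3 consensus baseline.
#' @param min_coverage Mask positions with depth below this.
#' @param max_iterations Iteration cap of the mapping/phasing loop.
#' @param convergence_diffs Maximum non-N differences between
#'   consecutive consensi to declare convergence.
#' @param stall_patience Consecutive converged-but-unresolved iterations
#'   tolerated in standard mode before switching to allele separation.
#' @param mapper_max_mismatch_frac Mismatch cap of the internal mapper.
#' @param chimeric_fraction_thresh,min_informative Block-level
#'   multiallelic detection (see [phase_blocks()]).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(caller = caller_config(),
                            phase_quality_thresh = 10.0,
                            phase_eps = 0.01,
                            min_base_qual = 13L,
                            two_thirds_ratio = 2 / 3,
                            min_coverage = 1L,
                            max_iterations = 40L,
                            convergence_diffs = 0L,
                            stall_patience = 3L,
                            mapper_max_mismatch_frac = 0.04,
                            chimeric_fraction_thresh = 0.10,
                            min_informative = 10L) {
  stopifnot(phase_quality_thresh >= 0, min_coverage >= 0,
            two_thirds_ratio > 0.5, two_thirds_ratio <= 1,
            max_iterations >= 1, convergence_diffs >= 0,
            stall_patience >= 1)
  structure(list(caller = caller,
                 phase_quality_thresh = phase_quality_thresh,
                 phase_eps = phase_eps,
                 min_base_qual = as.integer(min_base_qual),
                 two_thirds_ratio = two_thirds_ratio,
                 min_coverage = as.integer(min_coverage),
                 max_iterations = as.integer(max_iterations),
                 convergence_diffs = as.integer(convergence_diffs),
                 stall_patience = as.integer(stall_patience),
                 mapper_max_mismatch_frac = mapper_max_mismatch_frac,
                 chimeric_fraction_thresh = chimeric_fraction_thresh,
                 min_informative = as.integer(min_informative)),
            class = "pipeline_config")
}

#' One pass of the assembly pipeline on mapped reads
#'
#' dedup -> pileup -> SNV calling -> phasing -> haplotype reconstruction
#' and classification -> phased consensus. Blocks whose second haplotype
#' has no read support (hence a fully masked sequence) are classified by
#' default in favour of the supported haplotype.
#'
#' @param alignments A `read_alignments` table mapped to `primary_ref`.
#' @param primary_ref Mapping reference (`genome_sequence`).
#' @param secondary_ref Classification reference (may equal the primary).
#' @param config A [pipeline_config()].
#' @return List with `alignments`, `pileup`, `snvs`, `blocks`,
#'   `block_haplotypes`, `origin_calls`, `assembly` (an
#'   `assembly_result`).
#' @export
run_pipeline_once <- function(alignments, primary_ref, secondary_ref,
                              config = pipeline_config()) {
  aln <- mark_duplicates(alignments)
  pu <- build_pileup(aln, primary_ref, config$min_base_qual)
  snvs <- call_snvs(pu, primary_ref, config$caller)
  blocks <- phase_blocks(snvs, aln,
                         phase_quality_thresh = config$phase_quality_thresh,
                         eps = config$phase_eps,
                         min_base_qual = config$min_base_qual,
                         chimeric_fraction_thresh = config$chimeric_fraction_thresh,
                         min_informative = config$min_informative,
                         ref_id = primary_ref$id)
  bhs <- lapply(blocks, reconstruct_block_haplotypes, reads = aln,
                primary_ref = primary_ref)
  calls <- lapply(bhs, function(bh) {
    alignable <- vapply(bh$hap_seqs, function(s) any(s2c(s) != "N"),
                        logical(1))
    if (all(alignable)) return(classify_block(bh, secondary_ref))
    org <- if (alignable[1L]) 0L else 1L
    structure(list(block = bh$block, haplotypes = bh,
                   organellar_hap = org, odin_hap = 1L - org,
                   score_org = NA_real_, score_odin = NA_real_,
                   tie = FALSE), class = "origin_call")
  })
  asm <- assemble_phased(primary_ref, snvs, blocks, calls, pu,
                         min_coverage = config$min_coverage)
  list(alignments = aln, pileup = pu, snvs = snvs, blocks = blocks,
       block_haplotypes = bhs, origin_calls = calls, assembly = asm)
}

## Allele-separation rescue of one multiallelic block: re-run calling
## and phasing inside each allele-separated read set (hap0, hap1) and
## inside the chimeric set — a chimeric read may itself be an odin (or
## the organelle when two insertion haplotypes dominated the diploid
## split), so its set is a candidate pool too. Candidate sequences over
## the block interval are scored against the secondary reference; the
## best becomes the organellar sequence, the rest are odins.
rescue_block <- function(block, alignments, primary_ref, secondary_ref,
                         config, min_reads = 3L) {
  sets <- list(hap0 = block$hap_read_ids[[1L]],
               hap1 = block$hap_read_ids[[2L]],
               chimeric = block$chimeric_read_ids)
  width <- block$end - block$start
  candidates <- list()
  for (nm in names(sets)) {
    ids <- sets[[nm]]
    if (length(ids) < min_reads) next
    sub <- alignments[alignments$read_id %in% ids, , drop = FALSE]
    pu <- build_pileup(sub, primary_ref, config$min_base_qual)
    snvs <- call_snvs(pu, primary_ref, config$caller)
    snvs <- snvs[snvs$pos >= block$start & snvs$pos < block$end, ,
                 drop = FALSE]
    mc <- consensus_mc(pu, primary_ref)
    base <- genome_chars(mc$consensus)[(block$start + 1L):block$end]
    hets <- snvs[snvs$genotype == "het", , drop = FALSE]
    if (nrow(hets) == 0L) {
      candidates[[nm]] <- c2s(base)
    } else {
      ## residual het structure inside the set: phase it and classify
      ## every sub-block independently, so the organellar side is chosen
      ## per sub-block rather than by a global label pairing
      sblocks <- phase_blocks(snvs, sub,
                              phase_quality_thresh = config$phase_quality_thresh,
                              eps = config$phase_eps,
                              min_base_qual = config$min_base_qual,
                              chimeric_fraction_thresh = config$chimeric_fraction_thresh,
                              min_informative = config$min_informative,
                              ref_id = primary_ref$id)
      v_org <- base
      v_alt <- base
      for (sb in sblocks) {
        offs <- sb$sites$pos - block$start + 1L
        side <- 0L
        bh <- reconstruct_block_haplotypes(sb, sub, primary_ref)
        alignable <- vapply(bh$hap_seqs, function(s) any(s2c(s) != "N"),
                            logical(1))
        if (all(alignable)) {
          oc <- classify_block(bh, secondary_ref,
                               hint_interval = c(block$start, block$end))
          side <- oc$organellar_hap
        } else if (!alignable[1L]) side <- 1L
        v_org[offs] <- if (side == 0L) sb$hap0 else sb$hap1
        v_alt[offs] <- if (side == 0L) sb$hap1 else sb$hap0
      }
      candidates[[paste0(nm, "_org")]] <- c2s(v_org)
      candidates[[paste0(nm, "_alt")]] <- c2s(v_alt)
    }
  }
  scored <- vapply(candidates, function(s) {
    if (!any(s2c(s) != "N")) return(NA_real_)
    align_score(s, secondary_ref, hint_interval = c(block$start, block$end))
  }, numeric(1))
  ok <- which(!is.na(scored))
  if (!length(ok)) return(NULL)
  best <- ok[which.max(scored[ok])]
  org_seq <- candidates[[best]]

  ## site-level arbitration: inside a multiallelic block the diploid
  ## linkage is unreliable, so wherever the secondary reference (when
  ## coordinate-compatible) carries one of the two called alleles, that
  ## allele wins — the origin-by-alignment-score rule at one-site
  ## granularity. Sites where the secondary matches neither allele keep
  ## the phased candidate's base.
  if (genome_length(secondary_ref) == genome_length(primary_ref)) {
    v <- s2c(org_seq)
    secv <- genome_chars(secondary_ref)
    for (j in seq_len(nrow(block$sites))) {
      pos <- block$sites$pos[j]
      sb <- secv[pos + 1L]
      if (sb %in% c(block$sites$allele1[j], block$sites$allele2[j]))
        v[pos - block$start + 1L] <- sb
    }
    org_seq <- c2s(v)
  }
  list(org_seq = org_seq, org_set = names(candidates)[best],
       candidates = candidates, scores = scored,
       odin_seqs = candidates[setdiff(ok, best)])
}

#' Run the iterative mapping/phasing loop
#'
#' Repeats map -> dedup -> pileup -> call -> phase -> classify ->
#' assemble, feeding each consensus back as the next primary reference.
#' The loop stops when consecutive consensi agree within
#' `convergence_diffs` non-N differences and no multiallelic block
#' remains unresolved, or at `max_iterations`. If the consensus stops
#' changing for `stall_patience` iterations while multiallelic blocks
#' persist, the loop switches (irreversibly) to allele-separation mode,
#' in which each flagged block is re-phased per allele-separated read
#' set and the best-scoring candidate sequence replaces the block.
#'
#' @param read_source A `sim_reads` table (or anything the mapper
#'   understands).
#' @param initial_ref Starting primary reference.
#' @param secondary_ref Classification reference.
#' @param config A [pipeline_config()].
#' @param mapper Function `(read_source, reference) -> read_alignments`;
#'   defaults to the internal truth mapper with the configured mismatch
#'   cap.
#' @param profile_window Window of the per-iteration coverage profile.
#' @return List of class `iteration_run`: `states` (data.frame with one
#'   row per iteration: `iteration`, `n_diffs_vs_prev`, `mode`,
#'   `unresolved_blocks`, `n_mapped`, `stalled`, `converged`), `consensus` (final
#'   `genome_sequence`), `final` (the last pass result), `profiles`
#'   (per-iteration coverage profiles), `rescues` (allele-separation
#'   results, if any).
#' @export
run_iterations <- function(read_source, initial_ref, secondary_ref,
                           config = pipeline_config(), mapper = NULL,
                           profile_window = 100L) {
  if (is.null(mapper))
    mapper <- function(rs, ref)
      truth_map_reads(rs, ref, config$mapper_max_mismatch_frac)
  ref <- initial_ref
  prev <- initial_ref
  prev2 <- NULL
  mode <- "standard"
  stall <- 0L
  states <- list(); profiles <- list(); rescues <- list()
  final <- NULL
  for (it in seq_len(config$max_iterations)) {
    aln <- mapper(read_source, ref)
    if (is.null(aln) || !nrow(aln))
      stop("run_iterations: mapper returned no alignments at iteration ", it)
    res <- run_pipeline_once(aln, ref, secondary_ref, config)
    consensus <- res$assembly$consensus
    ma_blocks <- Filter(function(b) b$multiallelic, res$blocks)
    unresolved <- length(ma_blocks)

    if (mode == "allele_separation" && unresolved > 0L) {
      cv <- genome_chars(consensus)
      for (blk in ma_blocks) {
        rs <- rescue_block(blk, res$alignments, ref, secondary_ref, config)
        if (is.null(rs)) next
        cv[(blk$start + 1L):blk$end] <- s2c(rs$org_seq)
        unresolved <- unresolved - 1L
        rescues[[length(rescues) + 1L]] <-
          c(list(iteration = it, start = blk$start, end = blk$end,
                 block_sites = blk$sites$pos), rs)
      }
      consensus <- genome_sequence(consensus$id, c2s(cv),
                                   consensus$circular)
      res$assembly$consensus <- consensus
    }

    diffs <- count_differences(consensus, prev)
    diffs2 <- if (!is.null(prev2)) count_differences(consensus, prev2)
              else .Machine$integer.max
    converged <- diffs <= config$convergence_diffs && unresolved == 0L

    ## period-2 limit cycle with nothing left to rescue: classification
    ## keeps alternating at a few sites as the reference alternates.
    ## Arbitrate those sites by the secondary reference (the
    ## origin-by-score rule at single sites) and stop.
    if (!converged && unresolved == 0L && diffs > 0L &&
        diffs2 <= config$convergence_diffs) {
      cur <- genome_chars(consensus)
      pv <- genome_chars(prev)
      if (genome_length(secondary_ref) == length(cur)) {
        secv <- genome_chars(secondary_ref)
        dpos <- which(cur != pv & cur != "N" & pv != "N")
        take_prev <- secv[dpos] == pv[dpos]
        cur[dpos[take_prev]] <- pv[dpos[take_prev]]
        consensus <- genome_sequence(consensus$id, c2s(cur),
                                     consensus$circular)
        res$assembly$consensus <- consensus
        diffs <- count_differences(consensus, prev)
      }
      converged <- TRUE
    }
    stalled <- !converged && unresolved > 0L &&
      (diffs <= config$convergence_diffs ||
         diffs2 <= config$convergence_diffs)
    states[[it]] <- data.frame(iteration = it, n_diffs_vs_prev = diffs,
                               mode = mode, unresolved_blocks = unresolved,
                               n_mapped = nrow(aln), stalled = stalled,
                               converged = converged,
                               stringsAsFactors = FALSE)
    ## raw mapped coverage (duplicates included): the inflation over an
    ## insertion's source region and its flattening across iterations
    raw <- res$alignments
    raw$is_duplicate <- FALSE
    profiles[[it]] <- coverage_profile(raw, ref, window = profile_window)
    final <- res
    if (converged) break
    ## a stall is a consensus that stopped changing — including a
    ## period-2 oscillation (equal to the consensus two iterations back),
    ## the signature of a multiallelic region flipping between its alleles
    if (stalled) {
      stall <- stall + 1L
      if (mode == "standard" && stall >= config$stall_patience)
        mode <- "allele_separation"
    } else stall <- 0L
    prev2 <- prev
    prev <- consensus
    ref <- genome_sequence(initial_ref$id, consensus$bases,
                           initial_ref$circular)
  }
  structure(list(states = do.call(rbind, states),
                 consensus = final$assembly$consensus,
                 final = final, profiles = profiles, rescues = rescues,
                 config = config),
            class = "iteration_run")
}

#' @export
print.iteration_run <- function(x, ...) {
  n <- nrow(x$states)
  cat(sprintf("iteration_run: %d iteration(s), %s\n", n,
              if (x$states$converged[n]) "converged" else "stopped at cap"))
  print(x$states)
  invisible(x)
}
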