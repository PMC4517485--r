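test_that("majority-count consensus follows the exact rule", {
  ref <- genome_sequence("r", strrep("A", 30))
  pu <- fx_pileup(list(`5` = c(A = 4, G = 6),    # majority alt
                       `6` = c(A = 5, G = 5),    # tie -> reference base
                       `7` = c(G = 10)), ref)    # forced alt
  out <- consensus_mc(pu, ref)
  v <- chars(out$consensus$bases)
  expect_equal(v[6], "G")
  expect_equal(v[7], "A")
  expect_equal(v[8], "G")
  ## depth 0 -> N (coverage below 1 is masked)
  expect_equal(v[1], "N")
  expect_equal(genome_length(out$consensus), 30L)
})

test_that("2/3-ratio consensus keeps the alternative only at the threshold", {
  ref <- genome_sequence("r", strrep("A", 30))
  pu <- fx_pileup(list(`5` = c(A = 3, G = 7),    # 0.70 >= 2/3 -> G
                       `6` = c(A = 4, G = 6),    # 0.60 <  2/3 -> A
                       `7` = c(G = 10),          # 1.00 -> G
                       `8` = c(A = 1, G = 2)),   # exactly 2/3 -> G
                  ref)
  out <- consensus_two_thirds(pu, ref)
  v <- chars(out$consensus$bases)
  expect_equal(v[6:9], c("G", "A", "G", "G"))
  expect_equal(v[1], "N")
  expect_error(consensus_two_thirds(pu, ref, ratio = 0.4), "ratio")
})

test_that("difference counting excludes N and enforces equal length", {
  expect_equal(count_differences("ACGT", "ACGT"), 0L)
  expect_equal(count_differences("ACGT", "ACGA"), 1L)
  expect_equal(count_differences("ACGT", "NCGT"), 0L)
  expect_equal(count_differences("ANGT", "AAGT"), 0L)
  expect_error(count_differences("ACG", "ACGT"), "length")
})

test_that("translation comparison uses the plastid/bacterial code", {
  expect_equal(translate_and_compare("GCT", "GTT"),
               data.frame(codon = 0L, aa_a = "A", aa_b = "V",
                          stringsAsFactors = FALSE))
  expect_equal(nrow(translate_and_compare("GCTGCA", "GCTGCA")), 0L)
  expect_equal(nrow(translate_and_compare("GCT", "GCC")), 0L)  # synonymous
  expect_error(translate_and_compare("GCTA", "GCTA"), "divisible")
  expect_error(translate_and_compare("GCT", "GNT"), "internal N")
  ## table 11 translates ATA to I (unlike the vertebrate mito code)
  expect_equal(nrow(translate_and_compare("ATA", "ATT")), 0L)
})

test_that("phased assembly substitutes blocks, hom-alts and masks", {
  refv <- rep("C", 60)
  ref <- genome_sequence("r", collapse(refv))
  snvs <- rbind(fx_hets(c(20L, 25L), c("A", "A"), c("G", "T"),
                        ref = c("C", "C")),
                within(fx_hets(40L, "G", "G", ref = "C"),
                       genotype <- "hom_alt"))
  class(snvs) <- c("snv_calls", "data.frame")
  mk <- function(id, b1, b2) {
    v <- rep("C", 10); v[3] <- b1; v[8] <- b2
    fx_reads(id, 18L, collapse(v))
  }
  reads <- rbind(do.call(rbind, lapply(1:6, function(i) mk(paste0("x", i), "A", "A"))),
                 do.call(rbind, lapply(1:6, function(i) mk(paste0("y", i), "G", "T"))),
                 fx_reads("z", 36L, strrep("G", 8)))
  class(reads) <- c("read_alignments", "data.frame")
  pu <- build_pileup(reads, ref)
  blocks <- phase_blocks(snvs, reads, min_informative = 100L)
  blocks <- Filter(function(b) b$phased, blocks)
  bh <- reconstruct_block_haplotypes(blocks[[1]], reads, ref)
  sec <- genome_sequence("sec", collapse({
    v <- rep("C", 60); v[21] <- "A"; v[26] <- "A"; v
  }))
  oc <- classify_block(bh, sec)
  asm <- assemble_phased(ref, snvs, blocks, list(oc), pu)
  v <- chars(asm$consensus$bases)
  expect_equal(v[21], "A")            # organellar haplotype inside block
  expect_equal(v[26], "A")
  expect_equal(v[41], "G")            # hom-alt outside blocks
  expect_equal(v[1], "N")             # uncovered -> masked
  expect_equal(genome_length(asm$consensus), 60L)
  expect_equal(asm$odin_regions$start, blocks[[1]]$start)
})

test_that("every consensus preserves the reference length", {
  truth <- simulate_truth(1200, odins = list(odin_spec(300, 700, 0.04)),
                          seed = 21)
  sim <- simulate_reads(truth, depth = 30, read_len = 60, seed = 21)
  aln <- truth_map_reads(sim, truth$organelle, 0.1)
  res <- run_pipeline_once(aln, truth$organelle, truth$organelle)
  L <- genome_length(truth$organelle)
  expect_equal(genome_length(res$assembly$consensus), L)
  expect_equal(genome_length(consensus_mc(res$pileup, truth$organelle)$consensus), L)
  expect_equal(genome_length(consensus_two_thirds(res$pileup, truth$organelle)$consensus), L)
})

test_that("coverage profile reports per-window mean depth", {
  ref <- genome_sequence("r", strrep("A", 300), circular = FALSE)
  reads <- fx_reads(sprintf("r%d", 1:30),
                    rep(seq(0L, 270L, by = 30L), each = 3),
                    rep(strrep("A", 30), 30))
  prof <- coverage_profile(reads, ref, window = 50)
  expect_equal(nrow(prof), 6L)
  expect_true(all(abs(prof$mean_depth - 3) < 1e-9))
  ## no reads -> zeros
  prof0 <- coverage_profile(reads[0, ], ref, window = 50)
  expect_true(all(prof0$mean_depth == 0))
})
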