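test_that("pair phase quality has the stated closed form", {
  expect_equal(pair_phase_quality(8, 0, 0.01), 159.65, tolerance = 0.01)
  expect_equal(pair_phase_quality(3, 1, 0.01), 39.91, tolerance = 0.01)
  expect_equal(pair_phase_quality(5, 5, 0.01), 0)
  expect_equal(pair_phase_quality(0, 0, 0.01), 0)
  ## each net fragment contributes ~19.956 phred
  expect_equal(pair_phase_quality(1, 0, 0.01), 19.956, tolerance = 0.001)
})

test_that("informative fragments are counted per adjacent het pair", {
  ## ref AAAA... sites at 10 (A/G) and 20 (A/T), reads span both
  snvs <- fx_hets(c(10L, 20L), c("A", "A"), c("G", "T"))
  mk <- function(id, b1, b2) {
    v <- rep("C", 15)
    v[1] <- b1; v[11] <- b2
    fx_reads(id, 10L, collapse(v))
  }
  ## 8 cis fragments on the allele1 side, none trans
  reads <- do.call(rbind, lapply(1:8, function(i) mk(paste0("r", i), "A", "A")))
  class(reads) <- c("read_alignments", "data.frame")
  cnt <- collect_informative_reads(reads, snvs)
  expect_equal(cnt$cis, 8L)
  expect_equal(cnt$trans, 0L)

  ## no read spans both sites -> (0, 0)
  short <- fx_reads(c("s1", "s2"), c(8L, 18L), c("CCACC", "CCACC"))
  cnt2 <- collect_informative_reads(short, snvs)
  expect_equal(c(cnt2$cis, cnt2$trans), c(0L, 0L))

  ## mate pair observing alt at site1 and alt at site2: one cis fragment
  pair <- fx_reads(c("p/1", "p/2"), c(8L, 18L), c("CCGCC", "CCTCC"),
                   frag_id = "p", paired = TRUE,
                   first_of_pair = c(TRUE, FALSE), strand = c("+", "-"))
  cnt3 <- collect_informative_reads(pair, snvs)
  expect_equal(c(cnt3$cis, cnt3$trans), c(1L, 0L))

  ## fragment with a non-called allele at one site is ignored there
  odd <- mk("o1", "C", "A")
  cnt4 <- collect_informative_reads(odd, snvs)
  expect_equal(c(cnt4$cis, cnt4$trans), c(0L, 0L))
})

test_that("the sweep links strong pairs and splits at weak ones", {
  snvs <- fx_hets(c(10L, 20L, 30L), c("A", "A", "A"), c("G", "T", "C"))
  mk <- function(id, s, bases, at) {
    v <- rep("C", 25)
    v[at - s + 1L] <- bases
    fx_reads(id, s, collapse(v))
  }
  ## strong cis link 10-20 (8 fragments), conflicting 20-30 (1 cis, 1 trans)
  reads <- rbind(
    do.call(rbind, lapply(1:4, function(i) mk(paste0("a", i), 8L, c("A", "A"), c(10L, 20L)))),
    do.call(rbind, lapply(1:4, function(i) mk(paste0("b", i), 8L, c("G", "T"), c(10L, 20L)))),
    mk("c1", 18L, c("A", "A"), c(20L, 30L)),
    mk("c2", 18L, c("A", "C"), c(20L, 30L)))
  class(reads) <- c("read_alignments", "data.frame")
  blocks <- phase_blocks(snvs, reads, min_informative = 100L)
  expect_equal(length(blocks), 2L)
  expect_equal(blocks[[1]]$sites$pos, c(10L, 20L))
  expect_equal(blocks[[1]]$hap0, c("A", "A"))
  expect_equal(blocks[[1]]$hap1, c("G", "T"))
  expect_true(blocks[[1]]$phased)
  expect_false(blocks[[2]]$phased)   # singleton from the split
  expect_equal(blocks[[2]]$sites$pos, 30L)

  ## a trans-majority pair crosses the haplotypes
  reads2 <- rbind(
    do.call(rbind, lapply(1:6, function(i) mk(paste0("t", i), 8L, c("A", "T"), c(10L, 20L)))),
    do.call(rbind, lapply(1:6, function(i) mk(paste0("u", i), 8L, c("G", "A"), c(10L, 20L)))))
  class(reads2) <- c("read_alignments", "data.frame")
  b2 <- phase_blocks(fx_hets(c(10L, 20L), c("A", "A"), c("G", "T")), reads2,
                     min_informative = 100L)
  expect_equal(length(b2), 1L)
  expect_equal(b2[[1]]$hap0, c("A", "T"))
  expect_equal(b2[[1]]$hap1, c("G", "A"))
})

test_that("reads separate into hap0/hap1/chimeric/uninformative partitions", {
  snvs <- fx_hets(c(10L, 20L), c("A", "A"), c("G", "T"))
  mk <- function(id, b1, b2) {
    v <- rep("C", 15); v[1] <- b1; v[11] <- b2
    fx_reads(id, 10L, collapse(v))
  }
  reads <- rbind(
    do.call(rbind, lapply(1:5, function(i) mk(paste0("h0_", i), "A", "A"))),
    do.call(rbind, lapply(1:5, function(i) mk(paste0("h1_", i), "G", "T"))),
    mk("chim", "A", "T"),                      # hap0 at site1, hap1 at site2
    fx_reads("noinfo", 12L, "CCCCC"))          # overlaps block, no site
  class(reads) <- c("read_alignments", "data.frame")
  blocks <- phase_blocks(snvs, reads, min_informative = 100L)
  blk <- blocks[[1]]
  sep <- separate_reads_by_allele(blk, reads)
  expect_setequal(sep$hap0, paste0("h0_", 1:5))
  expect_setequal(sep$hap1, paste0("h1_", 1:5))
  expect_equal(sep$chimeric, "chim")
  expect_equal(sep$uninformative, "noinfo")
  ## the four sets partition the block-overlapping reads
  expect_setequal(c(sep$hap0, sep$hap1, sep$chimeric, sep$uninformative),
                  reads$read_id)
})

test_that("phasing agrees with the brute-force configuration search", {
  for (seed in 1:40) {
    inst <- fx_phase_instance(seed)
    blocks <- phase_blocks(inst$snvs, inst$reads, min_informative = 1000L)
    orc <- oracle_phase(inst$reads, inst$site_pos, inst$allele1,
                        inst$allele2)
    expect_equal(length(blocks), length(orc$blocks),
                 info = paste("seed", seed))
    a1 <- stats::setNames(inst$allele1, inst$site_pos)
    for (b in seq_along(blocks)) {
      expect_equal(match(blocks[[b]]$sites$pos, inst$site_pos),
                   orc$blocks[[b]]$sites, info = paste("seed", seed))
      side <- block_sides(blocks[[b]], a1)
      sc <- oracle_concordance(orc$obs, orc$blocks[[b]]$sites, side)
      expect_equal(sc, orc$blocks[[b]]$best_score,
                   info = paste("seed", seed, "block", b))
    }
  }
})

test_that("downstream calls are invariant to swapping haplotype labels", {
  inst <- fx_phase_instance(99)
  blocks <- phase_blocks(inst$snvs, inst$reads, min_informative = 1000L)
  blk <- Filter(function(b) b$phased, blocks)[[1]]
  ref <- genome_sequence("ref", strrep("A", max(inst$site_pos) + 50))
  swapped <- blk
  swapped$hap0 <- blk$hap1
  swapped$hap1 <- blk$hap0
  swapped$hap_read_ids <- rev(blk$hap_read_ids)
  sec <- genome_sequence("sec", collapse({
    v <- chars(ref$bases); v[blk$sites$pos + 1L] <- blk$hap0; v
  }))
  bh1 <- reconstruct_block_haplotypes(blk, inst$reads, ref)
  bh2 <- reconstruct_block_haplotypes(swapped, inst$reads, ref)
  c1 <- classify_block(bh1, sec)
  c2 <- classify_block(bh2, sec)
  expect_equal(bh1$hap_seqs[c1$organellar_hap + 1L],
               bh2$hap_seqs[c2$organellar_hap + 1L])
  expect_equal(c1$score_org, c2$score_org)
})
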