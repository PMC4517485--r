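test_that("alignment scoring follows the stated scheme", {
  sec <- genome_sequence("sec", "TTTTACGTTTTT")
  expect_equal(align_score("ACGT", sec), 4)          # perfect, free end gaps
  expect_equal(align_score("ACGA", genome_sequence("s", "ACGT")), 2)
  expect_error(align_score("NNNN", sec), "unalignable")
  ## N scores 0 against anything
  expect_equal(align_score("ANGT", sec), 3)
})

test_that("alignment scores match an independent dynamic-programming oracle", {
  withr::with_seed(42, {
    for (rep in 1:25) {
      n <- sample(8:20, 1)
      m <- sample(25:60, 1)
      subj <- collapse(sample(c("A", "C", "G", "T"), m, replace = TRUE))
      ## query: mutated substring of the subject (subs + occasional gapping)
      s0 <- sample(1:(m - n), 1)
      q <- chars(substr(subj, s0, s0 + n - 1))
      nm <- sample(0:2, 1)
      if (nm > 0) {
        at <- sample(seq_along(q), nm)
        q[at] <- sample(c("A", "C", "G", "T", "N"), nm, replace = TRUE)
      }
      if (stats::runif(1) < 0.3) q <- q[-sample(seq_along(q), 1)]
      query <- collapse(q)
      expect_equal(align_score(query, genome_sequence("s", subj)),
                   oracle_semiglobal(query, subj),
                   info = paste("rep", rep))
    }
  })
})

test_that("block haplotypes are rebuilt on the reference backbone with masking", {
  refv <- rep("C", 120)
  ref <- genome_sequence("ref", collapse(refv))
  snvs <- fx_hets(c(102L, 107L), c("A", "A"), c("G", "T"), ref = c("C", "C"))
  mk <- function(id, b1, b2, s = 100L, len = 10L) {
    v <- rep("C", len)
    v[103 - s] <- b1; v[108 - s] <- b2
    fx_reads(id, s, collapse(v))
  }
  reads <- rbind(do.call(rbind, lapply(1:6, function(i) mk(paste0("x", i), "A", "A"))),
                 do.call(rbind, lapply(1:6, function(i) mk(paste0("y", i), "G", "T"))))
  class(reads) <- c("read_alignments", "data.frame")
  blk <- phase_blocks(snvs, reads, min_informative = 100L)[[1]]
  bh <- reconstruct_block_haplotypes(blk, reads, ref)
  expect_equal(nchar(bh$hap_seqs[1]), blk$end - blk$start)
  expect_equal(substr(bh$hap_seqs[1], 1, 1), "A")
  expect_equal(substr(bh$hap_seqs[1], 6, 6), "A")
  expect_equal(substr(bh$hap_seqs[2], 1, 1), "G")
  ## backbone positions between sites keep the reference base
  expect_equal(substr(bh$hap_seqs[1], 3, 3), "C")

  ## zero-coverage positions of one haplotype are masked to N
  blk2 <- blk
  blk2$hap_read_ids <- list(blk$hap_read_ids[[1]], character(0))
  bh2 <- reconstruct_block_haplotypes(blk2, reads, ref)
  expect_equal(bh2$hap_seqs[2], strrep("N", blk$end - blk$start))
  expect_false(any(chars(bh2$hap_seqs[1]) == "N"))
})

test_that("classification picks the higher-scoring haplotype with tie review", {
  ref <- genome_sequence("ref", strrep("C", 60))
  blk <- structure(list(ref_id = "ref", start = 20L, end = 31L,
                        sites = fx_hets(c(20L, 30L), c("A", "A"), c("G", "T"),
                                        ref = c("C", "C")),
                        hap0 = c("A", "A"), hap1 = c("G", "T"),
                        pair_pq = 40, phased = TRUE,
                        hap_read_ids = list(paste0("a", 1:12), paste0("b", 1:5)),
                        chimeric_read_ids = character(0),
                        uninformative_read_ids = character(0),
                        chimeric_fraction = 0, multiallelic = FALSE),
                   class = "phased_block")
  hapA <- "ACCCCCCCCCA"; hapB <- "GCCCCCCCCCT"
  bh <- structure(list(block = blk, hap_seqs = c(hapA, hapB),
                       masks = list(rep(FALSE, 11), rep(FALSE, 11)),
                       hap_read_counts = c(12L, 5L)),
                  class = "block_haplotypes")
  sec_like_A <- genome_sequence("sec", collapse({
    v <- rep("C", 60); v[21] <- "A"; v[31] <- "A"; v
  }))
  oc <- classify_block(bh, sec_like_A)
  expect_equal(oc$organellar_hap, 0L)
  expect_equal(oc$odin_hap, 1L)
  expect_false(oc$tie)
  expect_gte(oc$score_org, oc$score_odin)

  ## label symmetry: swapping haplotypes flips the index, not the sequence
  bh_sw <- bh
  bh_sw$hap_seqs <- rev(bh$hap_seqs)
  bh_sw$hap_read_counts <- rev(bh$hap_read_counts)
  oc_sw <- classify_block(bh_sw, sec_like_A)
  expect_equal(oc_sw$organellar_hap, 1L)

  ## equal scores: read-count majority wins provisionally, tie flagged
  bh_tie <- bh
  bh_tie$hap_seqs <- c(hapA, hapA)
  oc_tie <- classify_block(bh_tie, sec_like_A)
  expect_true(oc_tie$tie)
  expect_equal(oc_tie$organellar_hap, 0L)
})

test_that("odin regions are emitted as BED plus FASTA and reject overlap", {
  mkcall <- function(s, e, seqs) {
    blk <- structure(list(ref_id = "ref", start = s, end = e,
                          sites = fx_hets(s, "A", "G"),
                          hap0 = "A", hap1 = "G", pair_pq = numeric(0),
                          phased = FALSE,
                          hap_read_ids = list("r1", "r2"),
                          chimeric_read_ids = character(0),
                          uninformative_read_ids = character(0),
                          chimeric_fraction = 0, multiallelic = FALSE),
                     class = "phased_block")
    structure(list(block = blk,
                   haplotypes = list(block = blk, hap_seqs = seqs,
                                     masks = NULL, hap_read_counts = c(1L, 1L)),
                   organellar_hap = 0L, odin_hap = 1L,
                   score_org = 10, score_odin = 6, tie = FALSE),
              class = "origin_call")
  }
  calls <- list(mkcall(10L, 20L, c("AAAAAAAAAA", "GGGGGGGGGG")),
                mkcall(30L, 40L, c("CCCCCCCCCC", "TTTTTTTTTT")),
                mkcall(50L, 60L, c("AAAAAAAAAA", "TTTTTTTTTT")))
  bed <- withr::local_tempfile(fileext = ".bed")
  fa <- withr::local_tempfile(fileext = ".fasta")
  df <- emit_odin_regions(calls, bed, fa)
  expect_equal(nrow(read_bed(bed)), 3L)
  expect_equal(sum(startsWith(readLines(fa), ">")), 3L)
  expect_equal(df$seq[1], "GGGGGGGGGG")   # the odin haplotype is exported

  ## zero calls -> empty but valid outputs
  emit_odin_regions(list(), bed, fa)
  expect_equal(nrow(read_bed(bed)), 0L)

  ## overlapping blocks violate a construction invariant
  bad <- list(mkcall(10L, 25L, c("A", "G")), mkcall(20L, 30L, c("A", "G")))
  expect_error(emit_odin_regions(bad, bed, fa), "overlap")
})
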