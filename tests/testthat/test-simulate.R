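test_that("simulated genomes are reproducible with the requested GC", {
  g1 <- simulate_genome(20000, gc = 0.4, seed = 7)
  g2 <- simulate_genome(20000, gc = 0.4, seed = 7)
  expect_identical(g1$bases, g2$bases)
  expect_lt(abs(gc_content(g1) - 0.4), 0.02)
  g3 <- simulate_genome(20000, gc = 0.4, seed = 8)
  expect_false(identical(g1$bases, g3$bases))
  expect_error(simulate_genome(0), "length")
  expect_error(simulate_genome(100, gc = 1.4), "gc")
})

test_that("divergence applies seeded substitutions at the requested rate", {
  g <- simulate_genome(1000, seed = 11)
  d0 <- apply_divergence(g, 0, seed = 11)
  expect_identical(d0$seq$bases, g$bases)
  expect_equal(length(d0$positions), 0L)

  d <- apply_divergence(g, 0.03, seed = 11)
  ## independent recount of mismatches equals the returned position list
  mism <- which(chars(d$seq$bases) != chars(g$bases)) - 1L
  expect_equal(sort(d$positions), mism)
  expect_gt(length(mism), 0L)
  expect_error(apply_divergence(g, 0.3), "rate")
  d25 <- apply_divergence(g, 0.25, seed = 3)   # upper bound accepted
  expect_gt(length(d25$positions), 150L)
})

test_that("read simulation respects depth, truth placements and origins", {
  truth <- simulate_truth(4000, odins = list(odin_spec(1000, 3000, 0.03,
                                                       relative_depth = 2)),
                          seed = 13)
  sim <- simulate_reads(truth, depth = 50, read_len = 90, error = 0,
                        seed = 13)
  expect_true(all(c("organelle", "copy1") %in% sim$origin))
  ## with zero error, organelle reads match the organelle exactly
  orgv <- chars(truth$organelle$bases)
  org_reads <- sim[sim$origin == "organelle", ][1:50, ]
  for (i in seq_len(nrow(org_reads))) {
    s <- org_reads$truth_start[i]
    expect_equal(org_reads$seq[i],
                 substr(truth$organelle$bases, s + 1, s + org_reads$len[i]))
  }
  ## truth-placement depth over the odin source is ~3x background
  aln <- truth_alignments(sim)
  prof <- coverage_profile(aln, truth$organelle, window = 200)
  inr <- prof$start >= 1000 & prof$end <= 3000
  bg <- prof$start < 800 | prof$start >= 3200
  ratio <- mean(prof$mean_depth[inr]) / mean(prof$mean_depth[bg])
  expect_gt(ratio, 2.5)
  expect_lt(ratio, 3.5)
  ## odin reads carry divergent alleles at their truth placements
  cp <- truth$copies[[1]]
  cp_reads <- sim[sim$origin == "copy1", ]
  i <- which(cp_reads$truth_start <= cp$positions[1] - 0 &
               cp_reads$truth_start + cp_reads$len > cp$positions[1])[1]
  expect_false(is.na(i))
  v <- chars(cp_reads$seq[i])
  off <- cp$positions[1] - cp_reads$truth_start[i] + 1L
  expect_equal(v[off], chars(cp$seq)[cp$positions[1] - cp$start + 1L])
})

test_that("the truth mapper filters by mismatch fraction against the reference", {
  truth <- simulate_truth(3000, odins = list(odin_spec(1000, 2000, 0.08)),
                          seed = 17)
  sim <- simulate_reads(truth, depth = 30, read_len = 90, error = 0, seed = 17)
  aln_strict <- truth_map_reads(sim, truth$organelle, 0.02)
  aln_loose <- truth_map_reads(sim, truth$organelle, 0.25)
  expect_equal(nrow(aln_loose), nrow(sim))
  kept <- table(factor(sim$origin[sim$read_id %in% aln_strict$read_id],
                       levels = c("organelle", "copy1")))
  expect_equal(unname(kept["organelle"]),
               sum(sim$origin == "organelle"))
  ## 8%-divergent copy reads nearly all fail a 2% mismatch cap
  expect_lt(kept["copy1"] / sum(sim$origin == "copy1"), 0.1)
})

test_that("the aDNA model produces short fragments with 5' deamination", {
  truth <- simulate_truth(3000, seed = 19)
  sim <- simulate_reads(truth, depth = 60, adna = TRUE, deamination = 0.3,
                        error = 0, adna_len_range = c(30, 80), seed = 19)
  expect_true(all(sim$len >= 30 & sim$len <= 80))
  expect_gt(mean(sim$len), 35)
  expect_lt(mean(sim$len), 60)
  ## observed C->T fraction at 5' position 1 is ~ the deamination rate
  plus <- sim[sim$strand == "+", ]
  ref1 <- substring(truth$organelle$bases, plus$truth_start + 1,
                    plus$truth_start + 1)
  obs1 <- substr(plus$seq, 1, 1)
  cs <- ref1 == "C"
  frac <- mean(obs1[cs] == "T")
  expect_lt(abs(frac - 0.3), 0.06)
  ## deep positions are unaffected
  refm <- substring(truth$organelle$bases, plus$truth_start + 20,
                    plus$truth_start + 20)
  obsm <- substr(plus$seq, 20, 20)
  expect_true(all(obsm[refm == "C" & nchar(plus$seq) >= 20] %in% c("C")))
})

test_that("simulations write a complete text bundle", {
  truth <- simulate_truth(800, odins = list(odin_spec(200, 500, 0.05)),
                          seed = 23)
  sim <- simulate_reads(truth, depth = 10, read_len = 50, seed = 23)
  dir <- withr::local_tempdir()
  paths <- write_simulation(sim, dir)
  expect_true(all(file.exists(paths)))
  fq <- read_fastq(paths["fastq"])
  expect_equal(nrow(fq), nrow(sim))
  back <- read_sam(paths["truth_sam"])
  expect_equal(nrow(back), nrow(sim))
  bed <- read_bed(paths["odin_bed"])
  expect_equal(bed$start, 200L)
  js <- jsonlite::read_json(paths["truth_json"])
  expect_equal(js$organelle_length, 800L)
  expect_equal(length(js$read_origins), nrow(sim))
})
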