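# Interval operations: replicate intersection, blacklist subtraction,
# chain projection with the minimum-matched-bases rule, permutation
# enrichment, and chromatin-state folds.

test_that("replicate intersection follows bedtools semantics", {
  a <- gr("chr1", c(100, 500, 900), c(200, 700, 950))
  expect_equal(merge_replicate_peaks(a, a), GenomicRanges::reduce(a))
  b <- gr("chr1", c(1000, 2000), c(1100, 2100))
  expect_length(merge_replicate_peaks(a, b), 0)
  # hand-computed toy: portions of a overlapping c
  cc <- gr("chr1", c(150, 650, 940), c(550, 660, 1000))
  got <- merge_replicate_peaks(a, cc)
  expect_equal(GenomicRanges::start(got), c(150, 500, 650, 940))
  expect_equal(GenomicRanges::end(got), c(200, 550, 660, 950))
  # base conservation: intersection never creates new bases
  expect_true(all(IRanges::overlapsAny(got, a)))
  expect_true(all(IRanges::overlapsAny(got, cc)))
})

test_that("blacklist subtraction removes whole peaks, never trims", {
  pk <- gr("chr1", c(100, 500, 900), c(200, 700, 950))
  expect_equal(subtract_blacklist(pk, GenomicRanges::GRanges()), pk)
  bl_all <- gr("chr1", 1, 1e6)
  expect_length(subtract_blacklist(pk, bl_all), 0)
  # partial overlap drops the whole peak
  bl <- gr("chr1", 690, 710)
  kept <- subtract_blacklist(pk, bl)
  expect_equal(GenomicRanges::start(kept), c(100, 900))
})

test_that("chain projection applies the matched-fraction rule", {
  # one chain covering 40% of a peak is rejected at min_match = 0.5
  blocks <- data.frame(chain_id = 1, score = 100, src_chrom = "chr1",
                       src_start = 1000, src_end = 1040,
                       tgt_chrom = "hchr1", tgt_start = 5000,
                       tgt_end = 5040)
  ch <- chain_map(blocks)
  pk <- gr("chr1", 1001, 1100)  # 100 bp peak, 40 mapped
  res <- map_intervals(ch, pk, min_match = 0.5)
  expect_length(res$mapped, 0)
  expect_equal(res$report$status, "below_min_match")
  expect_equal(res$report$mapped_fraction, 0.4)
  # accepted at a lower cutoff
  res2 <- map_intervals(ch, pk, min_match = 0.3)
  expect_equal(GenomicRanges::start(res2$mapped), 5001)
  expect_equal(GenomicRanges::end(res2$mapped), 5040)

  # one 10 bp alignment gap inside a 100 bp peak: fraction 0.9, and the
  # target span follows block arithmetic (gap widens the target span by
  # the target-side gap)
  blocks2 <- data.frame(chain_id = 1, score = 10, src_chrom = "chr1",
                        src_start = c(0, 60), src_end = c(50, 110),
                        tgt_chrom = "hchr1", tgt_start = c(1000, 1065),
                        tgt_end = c(1050, 1115))
  ch2 <- chain_map(blocks2)
  pk2 <- gr("chr1", 1, 100)  # 0-based [0, 100): 50 + 40 mapped
  res3 <- map_intervals(ch2, pk2, min_match = 0.5)
  expect_equal(res3$report$mapped_fraction, 0.9)
  expect_equal(GenomicRanges::start(res3$mapped), 1001)
  expect_equal(GenomicRanges::end(res3$mapped), 1105)

  # a peak spanning two chains maps via the best-scoring one
  blocks3 <- rbind(blocks2,
                   data.frame(chain_id = 2, score = 1000,
                              src_chrom = "chr1", src_start = 40,
                              src_end = 90, tgt_chrom = "hchr2",
                              tgt_start = 0, tgt_end = 50))
  ch3 <- chain_map(blocks3)
  res4 <- map_intervals(ch3, pk2, min_match = 0.4)
  expect_equal(as.character(GenomicRanges::seqnames(res4$mapped)), "hchr2")
  expect_equal(res4$report$n_chains, 2)
})

test_that("identity-chain projection is exact and idempotent", {
  cl <- c(chr1 = 2e6, chr2 = 1e6)
  ch <- identity_chain(cl)
  set.seed(5)
  pk <- GenomicRanges::GRanges(sample(names(cl), 50, TRUE),
                               IRanges::IRanges(sample.int(9e5, 50),
                                                width = sample(100:1000, 50,
                                                               TRUE)))
  res <- map_intervals(ch, pk)
  expect_equal(GenomicRanges::start(res$mapped), GenomicRanges::start(pk))
  expect_equal(GenomicRanges::width(res$mapped), GenomicRanges::width(pk))
  expect_true(all(res$mapped$mapped_fraction == 1))
  # projection is strictly order-preserving within a chain: sorted source
  # starts map to sorted target starts
  on1 <- as.character(GenomicRanges::seqnames(res$mapped)) == "chr1"
  src_ord <- order(GenomicRanges::start(pk)[res$mapped$src_index[on1]])
  expect_false(is.unsorted(GenomicRanges::start(res$mapped[on1])[src_ord]))
})

test_that("chain round-trips through the UCSC format against rtracklayer",
{
  skip_if_not_installed("rtracklayer")
  feats <- gen_genome_features(c(chr1 = 3e6), n_genes = 10,
                               peak_density = 10, loop_density = 1,
                               seed = 8)
  f <- tempfile(fileext = ".chain")
  write_chain(feats$chain, f)
  rt <- rtracklayer::import.chain(f)
  pk <- feats$peaks[[1]]$rep1
  ours <- map_intervals(feats$chain, pk, min_match = 1)
  # fully-mapped peaks must agree with rtracklayer::liftOver exactly
  lo <- rtracklayer::liftOver(pk, rt)
  full <- ours$report$status == "mapped"
  for (i in which(full)) {
    li <- GenomicRanges::reduce(lo[[i]])
    if (length(li) >= 1) {
      ours_i <- ours$mapped[ours$mapped$src_index == i]
      expect_equal(min(GenomicRanges::start(li)),
                   GenomicRanges::start(ours_i))
      expect_equal(max(GenomicRanges::end(li)), GenomicRanges::end(ours_i))
    }
  }
})

test_that("permutation enrichment: saturation, construction, null", {
  ws <- gr("chr1", 1, 1e6)
  # reference = workspace: fold exactly 1, p ~ 1
  q <- GenomicRanges::GRanges("chr1",
                              IRanges::IRanges(seq(1000, 9e5, by = 5e4),
                                               width = 500))
  r_sat <- permutation_enrichment(q, ws, ws, n_permutations = 99, seed = 1)
  expect_equal(r_sat$fold, 1)
  expect_equal(r_sat$p, 1)

  # query inside a reference covering 10% of the workspace
  ref <- GenomicRanges::GRanges("chr1",
                                IRanges::IRanges(seq(1, 1e6, by = 1e4),
                                                 width = 1000))
  qin <- GenomicRanges::GRanges("chr1",
                                IRanges::IRanges(seq(101, 9.9e5, by = 2e4),
                                                 width = 300))
  stopifnot(all(IRanges::overlapsAny(qin, ref)))
  r_in <- permutation_enrichment(qin, ref, ws, n_permutations = 999,
                                 seed = 2)
  expect_lt(abs(r_in$fold - 10) / 10, 0.1)
  expect_equal(r_in$p, 1 / 1000)

  # random query: fold within 2 null SDs of 1
  set.seed(9)
  qr <- GenomicRanges::GRanges("chr1",
                               IRanges::IRanges(sample.int(9.9e5, 40),
                                                width = 200))
  r_null <- permutation_enrichment(qr, ref, ws, n_permutations = 499,
                                   seed = 3)
  expect_lt(abs(r_null$observed - r_null$null_mean), 2 * r_null$null_sd)

  # errors: query outside the workspace / workspace too small
  expect_error(permutation_enrichment(gr("chr1", 2e6, 2e6 + 100), ref, ws),
               "within the workspace")
  expect_error(permutation_enrichment(q, ref, gr("chr1", 1, 100)),
               "within the workspace")
})

test_that("state enrichment matches hand computation on a 3-state toy", {
  seg <- gr("chr1", c(1, 1001, 3001), c(1000, 3000, 6000),
            name = c("A", "B", "C"))
  q <- gr("chr1", c(1, 1001), c(500, 1500))  # 500 in A, 500 in B
  res <- state_enrichment(q, seg)
  # W = 6000; A: (500/1000)/(1000/6000) = 3; B: (500/1000)/(2000/6000)=1.5
  expect_equal(res$fold[res$state == "A"], 3)
  expect_equal(res$fold[res$state == "B"], 1.5)
  expect_equal(res$fold[res$state == "C"], 0)

  # query = all of state C: fold_C = 1/coverage_C, others 0
  qc <- gr("chr1", 3001, 6000)
  resc <- state_enrichment(qc, seg)
  expect_equal(resc$fold[resc$state == "C"], 6000 / 3000)
  expect_equal(resc$fold[resc$state == "A"], 0)

  # uniform random query: folds near 1
  set.seed(4)
  seg2 <- gr("chr1", seq(1, 1e6, by = 1e4),
             seq(1e4, 1e6 + 9999, by = 1e4),
             name = sample(c("A", "B"), 100, TRUE))
  qu <- GenomicRanges::GRanges("chr1",
                               IRanges::IRanges(sample.int(9.9e5, 300),
                                                width = 500))
  resu <- state_enrichment(qu, seg2)
  expect_true(all(abs(resu$fold - 1) < 0.25))
})
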