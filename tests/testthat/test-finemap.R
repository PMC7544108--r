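# Fine-mapping: coding classification, regulatory tagging, proximal/distal
# target assignment, and the tier rule against an independent oracle.

test_that("coding classification filters by consequence and CADD", {
  cand <- data.frame(id = c("v1", "v2", "v3", "v4"),
                     locus_id = c(1, 1, 2, 2),
                     chrom = "1", pos = c(100, 200, 300, 400))
  eff <- data.frame(id = c("v1", "v2", "v3"),
                    consequence = c("missense", "missense", "synonymous"),
                    gene_id = c("KLHDC7B", "GX", "GY"),
                    cadd_phred = c(16.21, 9.9, 30),
                    aa_change = c("Val504Met", NA, NA))
  res <- classify_coding(cand, eff)
  # deleterious missense retained; low-CADD missense and synonymous are
  # not; unannotated candidates default to noncoding
  expect_equal(res$id, "v1")
  expect_equal(res$gene_id, "KLHDC7B")
  expect_equal(res$aa_change, "Val504Met")
  # boundary: CADD exactly at the threshold is retained
  eff$cadd_phred[2] <- 10
  expect_equal(classify_coding(cand, eff)$id, c("v1", "v2"))
})

test_that("regulatory tagging respects the inclusive 500 bp flank", {
  # OCR at 0-based [10000, 10500)
  ocr <- gr("1", 10001, 10500, cell_class = "epithelial")
  mk <- function(pos) data.frame(id = "s", locus_id = 1, chrom = "1",
                                 pos = pos)
  # exactly 500 bp left of the region start (0-based 9500) -> retained
  expect_equal(nrow(regulatory_candidates(mk(9501), ocr)), 1)
  # 501 bp away -> excluded
  expect_equal(nrow(regulatory_candidates(mk(9500), ocr)), 0)
  # right boundary: last included 0-based position is end + 499
  expect_equal(nrow(regulatory_candidates(mk(11000), ocr)), 1)
  expect_equal(nrow(regulatory_candidates(mk(11001), ocr)), 0)
  expect_equal(regulatory_candidates(mk(10100), ocr)$cell_class,
               "epithelial")
})

test_that("regulatory tagging equals a brute-force distance check", {
  set.seed(17)
  ocr <- GenomicRanges::GRanges("1",
                                IRanges::IRanges(sort(sample.int(1e6, 60)),
                                                 width = sample(100:600, 60,
                                                                TRUE)))
  cand <- data.frame(id = sprintf("s%03d", 1:613), locus_id = 1,
                     chrom = "1", pos = sample.int(1.1e6, 613))
  got <- regulatory_candidates(cand, ocr, flank_bp = 500)
  s0 <- GenomicRanges::start(ocr) - 1
  e0 <- GenomicRanges::end(ocr)
  keep <- vapply(cand$pos, function(p)
    any(p - 1 >= s0 - 500 & p - 1 < e0 + 500), logical(1))
  expect_setequal(got$id, cand$id[keep])
})

test_that("proximal assignment matches a brute-force TSS scan", {
  genes <- data.frame(gene_id = c("A", "B", "C"), chrom = "1",
                      tss = c(10000, 24000, 100000))
  snps <- data.frame(id = c("s1", "s2"), locus_id = 1, chrom = "1",
                     pos = c(5000, 99000))
  res <- assign_proximal(snps, genes, max_tss_distance = 20000)
  expect_setequal(paste(res$id, res$gene_id),
                  c("s1 A", "s1 B", "s2 C"))
  expect_equal(res$tss_distance[res$id == "s1" & res$gene_id == "A"], 5000)
  # SNP at a TSS: distance 0
  res0 <- assign_proximal(data.frame(id = "x", locus_id = 1, chrom = "1",
                                     pos = 10000), genes)
  expect_true(any(res0$tss_distance == 0))
  # random instance against the naive double loop
  set.seed(23)
  g2 <- data.frame(gene_id = sprintf("G%02d", 1:40), chrom = "1",
                   tss = sample.int(2e6, 40))
  s2 <- data.frame(id = sprintf("s%02d", 1:60), locus_id = 1, chrom = "1",
                   pos = sample.int(2e6, 60))
  got <- assign_proximal(s2, g2)
  naive <- NULL
  for (i in 1:60) for (j in 1:40)
    if (abs(s2$pos[i] - g2$tss[j]) <= 20000)
      naive <- rbind(naive, data.frame(id = s2$id[i],
                                       gene_id = g2$gene_id[j]))
  expect_setequal(paste(got$id, got$gene_id),
                  paste(naive$id, naive$gene_id))
})

test_that("distal assignment follows bin arithmetic and the loop p rule", {
  genes <- data.frame(gene_id = c("A", "B"), chrom = "1",
                      tss = c(2.05e6, 2.85e6))
  snps <- data.frame(id = "s1", locus_id = 3, chrom = "1", pos = 50000)
  loops <- data.frame(chrom_a = "1", start_a = 40000, chrom_b = "1",
                      start_b = c(2.04e6, 2.84e6), bin_size = 40000,
                      p = c(1e-30, 1e-20))
  res <- assign_distal(snps, loops, genes, loop_p_max = 1e-25)
  # only the strong loop passes; its partner bin holds gene A
  expect_equal(res$gene_id, "A")
  expect_equal(res$loop_p, 1e-30)
  # multi-tissue duplicates collapse to the minimum p
  loops2 <- rbind(loops,
                  data.frame(chrom_a = "1", start_a = 40000, chrom_b = "1",
                             start_b = 2.84e6, bin_size = 40000, p = 1e-40))
  res2 <- assign_distal(snps, loops2, genes, loop_p_max = 1e-25)
  expect_setequal(res2$gene_id, c("A", "B"))
  # SNP and TSS in the same bin never yield a distal call
  same_bin <- data.frame(chrom_a = "1", start_a = 40000, chrom_b = "1",
                         start_b = 40000, bin_size = 40000, p = 1e-50)
  g_same <- data.frame(gene_id = "S", chrom = "1", tss = 41000)
  expect_equal(nrow(assign_distal(snps, same_bin, g_same)), 0)
  # a loop touching the SNP bin from its B side also assigns
  loops3 <- data.frame(chrom_a = "1", start_a = 2.04e6, chrom_b = "1",
                       start_b = 40000, bin_size = 40000, p = 1e-30)
  expect_equal(assign_distal(snps, loops3, genes)$gene_id, "A")
})

test_that("tier rule matches the oracle on randomized instances and
           recovers planted genes", {
  # hand case: coding beats three distal genes at the same locus
  coding <- data.frame(id = "c1", locus_id = 1, gene_id = "CG",
                       consequence = "missense", cadd_phred = 20)
  distal <- data.frame(id = c("d1", "d2", "d3"), locus_id = 1,
                       gene_id = c("X", "Y", "Z"), loop_p = 1e-30)
  res <- prioritize(coding, NULL, distal)
  expect_equal(res$prioritized$gene_id, "CG")
  expect_equal(res$prioritized$tier, "coding")
  # union list keeps all evidence genes
  expect_setequal(res$union_genes$gene_id, c("CG", "X", "Y", "Z"))
  # empty locus emits nothing
  expect_equal(nrow(prioritize(NULL, NULL, NULL)$prioritized), 0)

  # randomized multi-locus instances vs the independent oracle
  set.seed(41)
  for (rep in 1:20) {
    n_loci <- 10
    mk <- function(p_has, genes) {
      rows <- NULL
      for (l in 1:n_loci) if (runif(1) < p_has) {
        k <- sample(1:3, 1)
        rows <- rbind(rows, data.frame(
          id = sprintf("s%d_%d", l, 1:k), locus_id = l,
          gene_id = sample(genes, k, TRUE)))
      }
      rows
    }
    coding <- mk(0.3, c("C1", "C2"))
    proximal <- mk(0.5, c("P1", "P2", "P3"))
    distal <- mk(0.6, c("D1", "D2"))
    got <- prioritize(coding, proximal, distal)$prioritized
    want <- oracle_prioritize(coding, proximal, distal)
    if (is.null(want)) {
      expect_equal(nrow(got), 0)
    } else {
      expect_equal(got[, c("locus_id", "gene_id", "tier")], want)
    }
    # tier exclusivity per locus
    if (nrow(got))
      expect_true(all(tapply(got$tier, got$locus_id,
                             function(x) length(unique(x))) == 1))
  }
})

test_that("relaxing distance or loop thresholds never removes a
           prioritized gene at the same tier", {
  set.seed(47)
  genes <- data.frame(gene_id = sprintf("G%02d", 1:30), chrom = "1",
                      tss = sort(sample.int(4e6, 30)))
  snps <- data.frame(id = sprintf("s%02d", 1:15), locus_id = 1:15,
                     chrom = "1", pos = sample.int(4e6, 15))
  loops <- data.frame(chrom_a = "1",
                      start_a = sample(seq(0, 3.9e6, 4e4), 40, TRUE),
                      chrom_b = "1",
                      start_b = sample(seq(0, 3.9e6, 4e4), 40, TRUE),
                      bin_size = 4e4, p = 10^-runif(40, 20, 35))
  p1 <- assign_proximal(snps, genes, 10000)
  p2 <- assign_proximal(snps, genes, 20000)
  expect_true(all(paste(p1$id, p1$gene_id) %in% paste(p2$id, p2$gene_id)))
  d1 <- assign_distal(snps, loops, genes, loop_p_max = 1e-28)
  d2 <- assign_distal(snps, loops, genes, loop_p_max = 1e-22)
  expect_true(all(paste(d1$id, d1$gene_id) %in% paste(d2$id, d2$gene_id)))
})
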