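# Generators: determinism, planted-structure invariants, and the
# statistical properties the downstream stages rely on.

test_that("seed splitting is deterministic and collision-free across
           stage labels", {
  labs <- c(paste0("rep", 1:200), paste0("null", 1:100), "panel",
            "sumstats", "cohort_phenotype")
  for (master in c(1, 42, 123456)) {
    s <- vapply(labs, child_seed, integer(1), master = master)
    expect_equal(anyDuplicated(s), 0)
    expect_true(all(s >= 1 & s < 2^31 - 1))
  }
  expect_identical(child_seed(7, "stage"), child_seed(7, "stage"))
  expect_false(child_seed(7, "stage") == child_seed(8, "stage"))
})

test_that("reference panel is deterministic and respects its invariants", {
  p1 <- gen_reference_panel(200, 100, 20, 0.7, seed = 5)
  p2 <- gen_reference_panel(200, 100, 20, 0.7, seed = 5)
  expect_identical(p1$genotypes, p2$genotypes)
  expect_identical(p1$variants, p2$variants)

  # stored maf equals the empirical effect-allele frequency
  expect_equal(colMeans(p1$genotypes) / 2, p1$variants$maf, tolerance = 1e-12)
  expect_true(all(p1$variants$maf > 0 & p1$variants$maf <= 0.5))
  # no monomorphic variants
  expect_true(all(apply(p1$genotypes, 2, function(x) length(unique(x))) > 1))
  # positions strictly increasing
  expect_true(all(diff(p1$variants$pos) > 0))
  expect_error(gen_reference_panel(0, 100), "positive")
  expect_error(gen_reference_panel(100, 101, 20), "divisible")
})

test_that("within-block dosage correlation matches the calibrated target", {
  # 120 blocks of 50 at corr 0.9: mean adjacent r2 within 0.1 of 0.81
  p <- gen_reference_panel(2000, 6000, 50, 0.9, seed = 9)
  G <- p$genotypes
  starts <- seq(1, 6000, by = 50)
  r2 <- vapply(starts, function(j) stats::cor(G[, j], G[, j + 1])^2,
               numeric(1))
  expect_lt(abs(mean(r2) - 0.81), 0.1)
})

test_that("zero within-block correlation yields independent variants", {
  p <- gen_reference_panel(2000, 1000, 50, 0, seed = 2)
  G <- p$genotypes
  r <- vapply(seq(1, 999, by = 50), function(j)
    abs(stats::cor(G[, j], G[, j + 1])), numeric(1))
  expect_lt(mean(r), 3 / sqrt(2000))
})

test_that("planted truth is self-consistent and enrichment recomputes", {
  p <- tiny_panel()
  ann <- make_annotations(p, list(cat = 1:10))
  tr <- make_simulation_truth(p, 0.25, ann, enrichment = c(cat = 5),
                              seed = 3)
  expect_equal(sum(tr$h2_snp), 0.25, tolerance = 1e-8)
  expect_equal(truth_enrichment(tr, ann, "cat"), 5, tolerance = 1e-6)
  # per-allele effects recompute the per-SNP h2
  sd_g <- sqrt(2 * p$variants$maf * (1 - p$variants$maf))
  expect_equal(unname((tr$causal_effects * sd_g)^2), tr$h2_snp,
               tolerance = 1e-10)
})

test_that("null summary statistics have mean chi-square 1", {
  p <- gen_reference_panel(500, 2000, 20, c(0.2, 0.8), seed = 4)
  tr <- make_simulation_truth(p, 0, seed = 1)
  ss <- gen_sumstats(p, tr, 20000, seed = 6)[[1]]
  chi2 <- sumstats_chi2(ss)
  # mean of ~correlated chi2; 3 SEs with a generous effective-n estimate
  expect_lt(abs(mean(chi2) - 1), 3 * stats::sd(chi2) / sqrt(2000 / 10))
  expect_true(all(ss$p > 0 & ss$p <= 1))
})

test_that("mean chi-square matches the closed-form expectation", {
  # independent variants so E[chi2] = 1 + N h2 / M exactly
  p <- gen_reference_panel(800, 2000, 20, 0, seed = 8)
  tr <- make_simulation_truth(p, 0.3, seed = 2)
  m <- replicate(20, {
    s <- gen_sumstats(p, tr, 50000,
                      seed = sample.int(1e6, 1))[[1]]
    mean(sumstats_chi2(s))
  })
  expected <- 1 + 50000 * 0.3 / 2000
  expect_lt(abs(mean(m) - expected) / expected, 0.05)
})

test_that("rg = 1 with shared effects gives near-identical z ranks", {
  p <- gen_reference_panel(500, 1000, 20, c(0.2, 0.8), seed = 4)
  tr <- make_simulation_truth(p, 0.4, rg = 1, seed = 3)
  sl <- gen_sumstats(p, tr, 50000, n_traits = 2, seed = 9)
  za <- sl[[1]]$beta / sl[[1]]$se
  zb <- sl[[2]]$beta / sl[[2]]$se
  expect_gt(stats::cor(za, zb, method = "spearman"), 0.95)
})

test_that("z-only and genotype modes agree in expectation", {
  # independent variants make the expectation free of the planted effect
  # signs (the genotype mode conditions on one sign realization)
  p <- gen_reference_panel(600, 1000, 20, 0, seed = 12)
  tr <- make_simulation_truth(p, 0.3, seed = 5)
  mz <- replicate(8, mean(sumstats_chi2(
    gen_sumstats(p, tr, 5000, seed = sample.int(1e6, 1))[[1]])))
  mg <- replicate(8, mean(sumstats_chi2(
    gen_sumstats(p, tr, 5000, mode = "genotype",
                 seed = sample.int(1e6, 1))[[1]])))
  expect_lt(abs(mean(mz) - mean(mg)) / mean(mz), 0.1)
  expect_error(gen_sumstats(p, tr, 100, n_traits = 2, mode = "genotype"),
               "single trait")
})

test_that("sumstats generation is deterministic and validates alignment", {
  p <- tiny_panel()
  tr <- make_simulation_truth(p, 0.1, seed = 1)
  s1 <- gen_sumstats(p, tr, 1e4, seed = 3)[[1]]
  s2 <- gen_sumstats(p, tr, 1e4, seed = 3)[[1]]
  expect_identical(s1, s2)
  p2 <- tiny_panel(m = 40)
  expect_error(gen_sumstats(p2, tr, 1e4, seed = 1), "alignment")
  expect_error(gen_sumstats(p, tr, 1e4, confounding_intercept = 0.5),
               "confounding")
})

test_that("genome features respect interval conventions and densities", {
  cl <- c(chr1 = 50e6, chr2 = 30e6)
  feats <- gen_genome_features(cl, n_genes = 100, peak_density = 20,
                               loop_density = 1.25, seed = 21)
  for (cc in names(feats$peaks)) for (rr in c("rep1", "rep2")) {
    pk <- feats$peaks[[cc]][[rr]]
    expect_true(all(GenomicRanges::width(pk) > 0))
    expect_false(is.unsorted(GenomicRanges::start(
      pk[GenomicRanges::seqnames(pk) == "mmchr1"])))
  }
  g <- feats$genes
  expect_true(all(g$start < g$end))
  expect_true(all(ifelse(g$strand == "+", g$tss == g$start,
                         g$tss == g$end)))
  # loop bins are multiples of the bin size
  expect_true(all(feats$loops$start_a %% 40000 == 0))
  expect_true(all(feats$loops$start_b %% 40000 == 0))
  # ~100 expected loops on 80 Mb at 1.25/Mb: Poisson 99% interval
  expect_gt(nrow(feats$loops), stats::qpois(0.005, 100))
  expect_lt(nrow(feats$loops), stats::qpois(0.995, 100))
  # replicates share most peaks (>= 1bp-overlap reproducible portion)
  ov <- merge_replicate_peaks(feats$peaks$epithelial$rep1,
                              feats$peaks$epithelial$rep2)
  expect_gt(sum(GenomicRanges::width(ov)) /
              sum(GenomicRanges::width(feats$peaks$epithelial$rep1)), 0.4)
  w <- testthat::capture_warnings(
    empty <- gen_genome_features(c(chr1 = 1e6), peak_density = 0,
                                 loop_density = 0, seed = 1))
  expect_true(any(grepl("zero", w)))
  expect_length(empty$peaks$epithelial$rep1, 0)
  expect_equal(nrow(empty$loops), 0)
})

test_that("identity chain maps intervals to themselves", {
  cl <- c(chr1 = 1e6)
  ch <- identity_chain(cl)
  pk <- gr("chr1", c(100, 5000), c(400, 6000))
  res <- map_intervals(ch, pk)
  expect_equal(GenomicRanges::start(res$mapped), c(100, 5000))
  expect_equal(GenomicRanges::end(res$mapped), c(400, 6000))
  expect_equal(res$mapped$mapped_fraction, c(1, 1))
})

test_that("single-cell generator plants violators and markers", {
  expect_error(gen_sc_counts(c(a = 10), depth_mean = 0), "positive")
  expect_error(gen_sc_counts(
    c(a = 10, b = 10), n_genes = 50,
    marker_spec = list(a = list(genes = 1:3, fold = 8),
                       b = list(genes = 3:5, fold = 2)),
    seed = 1), "contradictory")
  sim <- gen_sc_counts(c(a = 50, b = 50), n_genes = 100,
                       marker_spec = list(a = list(genes = 1:5, fold = 8)),
                       violator_frac = 0.1, seed = 33)
  expect_s3_class(sim$sc, "sc_counts")
  expect_equal(ncol(sim$sc$counts), 100)
  expect_equal(sum(sim$truth$qc_violation != "none"), 10)
  # planted low-depth violators are far below the QC bound
  tot <- Matrix::colSums(sim$sc$counts)
  expect_true(all(tot[sim$truth$qc_violation == "low_umi"] < 50))
  expect_true(all(tot[sim$truth$qc_violation == "high_umi"] > 20000))
})

test_that("target cohort phenotypes carry the genetic signal in PC1", {
  p <- tiny_panel(n = 200, m = 100)
  tr <- make_simulation_truth(p, 0.5, seed = 2)
  co <- gen_target_cohort(300, p, tr, n_frequencies = 3, h2_score = 0.3,
                          noise_sd = 1e-8, seed = 5)
  pc <- phenotype_pca(co$thresholds)
  expect_gt(pc$var_explained[1], 0.99)
  expect_error(gen_target_cohort(100, p, tr, n_frequencies = 1, seed = 1),
               "frequencies")
})

test_that("generated artifacts round-trip through their file formats", {
  dir <- withr::local_tempdir()
  p <- tiny_panel(m = 40)
  tr <- make_simulation_truth(p, 0.2, seed = 1)
  ss <- gen_sumstats(p, tr, 5000, seed = 2)[[1]]
  f <- file.path(dir, "ss.tsv")
  write_sumstats(ss, f, seed = 2)
  ss2 <- read_sumstats(f)
  expect_equal(ss2$beta, ss$beta, tolerance = 1e-12)
  expect_equal(ss2$id, ss$id)
  expect_true(startsWith(readLines(f, n = 1), "# seed="))

  feats <- gen_genome_features(c(chr1 = 5e6), n_genes = 20,
                               peak_density = 10, loop_density = 2,
                               seed = 3)
  bedf <- file.path(dir, "pk.bed")
  write_bed(feats$peaks[[1]]$rep1, bedf)
  pk2 <- read_bed(bedf)
  expect_equal(GenomicRanges::start(pk2),
               GenomicRanges::start(feats$peaks[[1]]$rep1))

  chf <- file.path(dir, "map.chain")
  write_chain(feats$chain, chf)
  ch2 <- read_chain(chf)
  expect_equal(ch2$blocks$src_start, feats$chain$blocks$src_start)
  expect_equal(ch2$blocks$tgt_end, feats$chain$blocks$tgt_end)

  lpf <- file.path(dir, "loops.tsv")
  write_loops(feats$loops, lpf)
  expect_equal(read_loops(lpf)$p, feats$loops$p, tolerance = 1e-12)

  gnf <- file.path(dir, "genes.tsv")
  write_genes(feats$genes, gnf)
  expect_equal(read_genes(gnf)$tss, feats$genes$tss)

  sim <- gen_sc_counts(c(a = 20, b = 20), n_genes = 50, seed = 4)
  pref <- file.path(dir, "counts")
  write_counts_mtx(sim$sc, pref)
  sc2 <- read_counts_mtx(pref)
  expect_equal(as.matrix(sc2$counts), as.matrix(sim$sc$counts))
  expect_setequal(sc2$mito_genes, sim$sc$mito_genes)

  co <- gen_target_cohort(30, p, tr, seed = 6, miss_rate = 0.05)
  dgf <- file.path(dir, "dosages.tsv")
  write_dosages(co$genotypes, dgf)
  g2 <- read_dosages(dgf)
  expect_equal(unname(g2), unname(co$genotypes))
})
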