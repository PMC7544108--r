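# Polygenic scoring: threshold PCA, cohort QC with the exact HWE test,
# score computation and harmonization, variance-explained evaluation.

test_that("phenotype PCA handles rank-1, signs and toy loadings", {
  # rank-1 matrix: PC1 explains everything
  v <- rnorm(50)
  m <- cbind(v, 2 * v, -v)
  pc <- phenotype_pca(m)
  expect_gt(pc$var_explained[1], 1 - 1e-10)
  # PC1 correlates positively with the mean threshold
  expect_gt(cor(pc$scores[, 1], rowMeans(m)), 0)
  # negating the data negates scores, not explained variance
  pc2 <- phenotype_pca(-m)
  expect_equal(pc2$var_explained, pc$var_explained, tolerance = 1e-12)
  expect_equal(abs(cor(pc2$scores[, 1], pc$scores[, 1])), 1,
               tolerance = 1e-10)

  # toy 4x3: loadings match eigenvectors of the covariance
  toy <- matrix(c(1, 2, 3, 4,
                  2, 1, 4, 3,
                  5, 5, 6, 7), 4, 3)
  pt <- phenotype_pca(toy)
  ev <- eigen(cov(toy))$vectors
  for (j in 1:3)
    expect_equal(abs(sum(pt$loadings[, j] * ev[, j])), 1, tolerance = 1e-8)
  expect_equal(pt$var_explained,
               eigen(cov(toy))$values / sum(eigen(cov(toy))$values),
               tolerance = 1e-10)
  # explained variance non-increasing; PCs orthogonal
  expect_true(all(diff(pt$var_explained) <= 1e-12))
  expect_equal(crossprod(pt$scores)[1, 2], 0, tolerance = 1e-8)

  expect_error(phenotype_pca(cbind(v)), "at least 2")
  expect_warning(phenotype_pca(cbind(v, v * 0 + 3, -v)), "constant")
})

test_that("exact HWE test matches the enumeration oracle", {
  cases <- list(c(10, 50, 40), c(30, 10, 60), c(0, 5, 95), c(25, 50, 25),
                c(3, 0, 97), c(40, 20, 40), c(1, 1, 1), c(0, 2, 0))
  for (cs in cases)
    expect_equal(hwe_exact_p(cs[1], cs[2], cs[3]),
                 oracle_hwe(cs[1], cs[2], cs[3]), tolerance = 1e-9)
  # equilibrium counts give a large p; gross het deficit a tiny one
  expect_gt(hwe_exact_p(25, 50, 25), 0.5)
  expect_lt(hwe_exact_p(50, 0, 50), 1e-20)
})

test_that("cohort QC applies the filters in order", {
  set.seed(3)
  n <- 200
  G <- matrix(rbinom(n * 20, 2, 0.3), n, 20,
              dimnames = list(NULL, sprintf("v%02d", 1:20)))
  # individual with 11% missing genotypes is removed
  G[1, 1:3] <- NA  # 15% missing
  # SNP missing in 15% of individuals
  G[sample(2:n, 30), 5] <- NA
  # SNP with MAF 4%
  G[, 7] <- rbinom(n, 2, 0.04)
  # SNP violating HWE: all homozygotes
  G[, 9] <- 2 * rbinom(n, 1, 0.5)
  qc <- qc_cohort(G)
  expect_equal(qc$report$n_individuals_removed, 1)
  expect_false("v05" %in% colnames(qc$genotypes))
  expect_false("v07" %in% colnames(qc$genotypes))
  expect_false("v09" %in% colnames(qc$genotypes))
  expect_true("v02" %in% colnames(qc$genotypes))
  expect_error(qc_cohort(matrix(NA_real_, 5, 2)), "removed all")
})

test_that("injected cohort artifacts are caught by QC", {
  p <- tiny_panel(n = 300, m = 100)
  tr <- make_simulation_truth(p, 0.4, seed = 1)
  co <- gen_target_cohort(400, p, tr, n_lowmaf = 2, n_hwe_violating = 2,
                          miss_rate = 0.01, seed = 9)
  qc <- qc_cohort(co$genotypes)
  expect_true(all(!co$injected$hwe %in% colnames(qc$genotypes)))
  expect_true(all(!co$injected$lowmaf %in% colnames(qc$genotypes)))
})

test_that("scores equal the centered dot product and survive allele flips",
{
  set.seed(5)
  G <- matrix(rbinom(200, 2, 0.4), 20, 10,
              dimnames = list(NULL, paste0("v", 1:10)))
  info <- data.frame(id = paste0("v", 1:10),
                     effect_allele = "A", other_allele = "G")
  disc <- manual_sumstats(paste0("v", 1:10), runif(10, 1e-6, 0.9))
  disc$beta <- rnorm(10, 0, 0.05)
  prs <- compute_prs(G, info, disc, thresholds = 1)
  manual <- sweep(G, 2, colMeans(G)) %*% disc$beta
  expect_equal(unname(prs$scores[, 1]), as.numeric(manual),
               tolerance = 1e-12)
  expect_equal(prs$n_snps_used, 10L)

  # flipped target alleles leave the scores identical
  info_fl <- info
  info_fl$effect_allele[3] <- "G"; info_fl$other_allele[3] <- "A"
  G_fl <- G; G_fl[, 3] <- 2 - G[, 3]
  prs_fl <- compute_prs(G_fl, info_fl, disc, thresholds = 1)
  expect_equal(prs_fl$scores, prs$scores, tolerance = 1e-12)

  # ambiguous A/T SNPs are dropped and counted
  disc_amb <- disc
  disc_amb$effect_allele[5] <- "A"; disc_amb$other_allele[5] <- "T"
  info_amb <- info
  info_amb$effect_allele[5] <- "A"; info_amb$other_allele[5] <- "T"
  prs_amb <- compute_prs(G, info_amb, disc_amb, thresholds = 1)
  expect_equal(prs_amb$n_dropped_ambiguous, 1)
  expect_equal(prs_amb$n_snps_used, 9L)

  # all-zero betas give identically zero scores
  disc0 <- disc; disc0$beta <- 0
  prs0 <- compute_prs(G, info, disc0, thresholds = 1)
  expect_true(all(prs0$scores == 0))

  # n_snps_used is monotone in the threshold (empty strata warn)
  suppressWarnings(prs_t <- compute_prs(G, info, disc))
  expect_true(all(diff(prs_t$n_snps_used) >= 0))
})

test_that("evaluation reports incremental R2 over covariates", {
  set.seed(7)
  n <- 400
  s <- rnorm(n)
  covar <- data.frame(age = rnorm(n))
  y <- 0.3 * s + 0.5 * covar$age + rnorm(n)
  prs <- structure(list(scores = cbind(`1` = s), n_snps_used = 5L,
                        thresholds = 1), class = "prs_result")
  ev <- evaluate_prs(prs, y, covar)
  m0 <- lm(y ~ age, data = covar)
  m1 <- lm(y ~ age + s, data = cbind(covar, s = s))
  expect_equal(ev$r2, summary(m1)$r.squared - summary(m0)$r.squared,
               tolerance = 1e-12)
  expect_equal(ev$p, anova(m0, m1)$`Pr(>F)`[2], tolerance = 1e-12)
  # the phenotype itself as covariate kills the incremental R2
  suppressWarnings(ev2 <- evaluate_prs(prs, y, data.frame(y2 = y)))
  expect_lt(ev2$r2, 1e-10)
  # orthogonal score: near-zero R2, non-significant
  ev3 <- evaluate_prs(prs, rnorm(n))
  expect_lt(ev3$r2, 0.03)
})

test_that("with dense causal effects the all-SNP threshold is near-best",
{
  p <- gen_reference_panel(500, 1000, 20, c(0.1, 0.4), seed = 61)
  tr <- make_simulation_truth(p, 0.5, seed = 2)
  disc <- gen_sumstats(p, tr, 1e5, mode = "conditional", seed = 3)[[1]]
  co <- gen_target_cohort(800, p, tr, h2_score = 0.08, noise_sd = 0.3,
                          seed = 4)
  pc1 <- phenotype_pca(co$thresholds)$scores[, 1]
  prs <- compute_prs(co$genotypes, co$target_info, disc,
                     thresholds = c(0.01, 0.1, 0.5, 1))
  ev <- evaluate_prs(prs, pc1)
  expect_gte(ev$r2[ev$threshold == 1], 0.8 * max(ev$r2, na.rm = TRUE))
  expect_gt(ev$r2[ev$threshold == 1], 0)
})

test_that("clumping inside compute_prs thins correlated SNPs", {
  p <- tiny_panel(n = 400, m = 100, block = 20, corr = 0.9, seed = 31)
  tr <- make_simulation_truth(p, 0.5, seed = 1)
  disc <- gen_sumstats(p, tr, 5e4, seed = 2)[[1]]
  co <- gen_target_cohort(150, p, tr, seed = 3)
  ld <- ld_from_panel(p)
  prs_all <- compute_prs(co$genotypes, co$target_info, disc,
                         thresholds = 1)
  prs_cl <- compute_prs(co$genotypes, co$target_info, disc,
                        thresholds = 1, ld = ld, clump_r2 = 0.1)
  expect_lt(prs_cl$n_snps_used, prs_all$n_snps_used)
})
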