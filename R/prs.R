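# Polygenic-score replication: phenotype PCA of multi-frequency hearing
# thresholds, cohort QC (missingness, MAF, exact HWE), threshold-based
# scoring from discovery summary statistics, and variance-explained
# evaluation.

#' PCA summary of multi-frequency hearing thresholds
#'
#' Column-centered PCA of an individuals x frequencies threshold matrix.
#' PC1's sign is fixed so it correlates positively with the mean threshold
#' (an overall hearing-loss severity axis); other PCs are signed so their
#' largest-magnitude loading is positive. Constant columns are dropped with
#' a warning; missing values are mean-imputed when `impute = TRUE`.
#'
#' @param thresholds numeric matrix (dB), individuals x frequencies.
#' @param impute mean-impute missing entries (flagged in the result).
#' @return list with `scores`, `loadings`, `var_explained` (non-increasing
#'   shares), `imputed` (count of imputed entries).
#' @export
phenotype_pca <- function(thresholds, impute = TRUE) {
  thresholds <- as.matrix(thresholds)
  if (ncol(thresholds) < 2) stop("need at least 2 frequencies")
  n_imp <- sum(is.na(thresholds))
  if (n_imp > 0) {
    if (!impute) stop("missing thresholds; set impute = TRUE or complete cases")
    for (j in seq_len(ncol(thresholds))) {
      mi <- is.na(thresholds[, j])
      thresholds[mi, j] <- mean(thresholds[, j], na.rm = TRUE)
    }
  }
  const <- apply(thresholds, 2, stats::var) < 1e-12
  if (any(const)) {
    warning("dropping constant threshold column(s): ",
            paste(colnames(thresholds)[const], collapse = ", "))
    thresholds <- thresholds[, !const, drop = FALSE]
    if (ncol(thresholds) < 2) stop("fewer than 2 informative frequencies")
  }
  pc <- stats::prcomp(thresholds, center = TRUE, scale. = FALSE)
  mt <- rowMeans(thresholds)
  if (stats::sd(mt) > 1e-12 && stats::cor(pc$x[, 1], mt) < 0) {
    pc$x[, 1] <- -pc$x[, 1]
    pc$rotation[, 1] <- -pc$rotation[, 1]
  }
  for (j in seq_len(ncol(pc$x))[-1]) {
    if (pc$rotation[which.max(abs(pc$rotation[, j])), j] < 0) {
      pc$x[, j] <- -pc$x[, j]
      pc$rotation[, j] <- -pc$rotation[, j]
    }
  }
  list(scores = pc$x, loadings = pc$rotation,
       var_explained = pc$sdev^2 / sum(pc$sdev^2), imputed = n_imp)
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Two-sided exact test: the p-value is the total probability of
#' heterozygote counts at most as likely as the observed one under the
#' conditional distribution given the allele counts.
#'
#' @param n_aa,n_ab,n_bb genotype counts (AA homozygote, heterozygote, BB
#'   homozygote).
#' @return the exact p-value.
#' @export
hwe_exact_p <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  if (n == 0) return(1)
  n_a <- 2 * n_aa + n_ab          # rarer-allele count below
  n_b <- 2 * n_bb + n_ab
  if (n_a > n_b) { tmp <- n_a; n_a <- n_b; n_b <- tmp }
  hets <- seq(n_a %% 2, n_a, by = 2)
  # probabilities by the stable recurrence in the heterozygote count
  lp <- numeric(length(hets))
  mid_i <- which.min(abs(hets - n_a * n_b / (2 * n)))  # start near the mode
  lp[mid_i] <- 0
  if (mid_i < length(hets)) for (i in (mid_i + 1):length(hets)) {
    h <- hets[i - 1]
    lp[i] <- lp[i - 1] +
      log((4 * ((n_a - h) / 2) * ((n_b - h) / 2)) / ((h + 2) * (h + 1)))
  }
  if (mid_i > 1) for (i in (mid_i - 1):1) {
    h <- hets[i + 1]
    lp[i] <- lp[i + 1] +
      log((h * (h - 1)) / (4 * ((n_a - h) / 2 + 1) * ((n_b - h) / 2 + 1)))
  }
  pr <- exp(lp - max(lp))
  pr <- pr / sum(pr)
  obs <- pr[hets == n_ab]
  min(sum(pr[pr <= obs * (1 + 1e-12)]), 1)
}

#' Cohort genotype quality control
#'
#' Filters applied in order: individuals with a missing-genotype fraction
#' strictly above `miss_ind`; then SNPs missing in strictly more than
#' `miss_snp` of the remaining individuals; then SNPs with minor allele
#' frequency strictly below `maf_min`; then SNPs failing the exact
#' Hardy-Weinberg test at `p < hwe_p`.
#'
#' @param genotypes individuals x SNPs dosage matrix in {0,1,2,NA}, with
#'   SNP ids as colnames.
#' @param miss_ind,miss_snp,maf_min,hwe_p filter thresholds.
#' @return list with `genotypes` (filtered) and `report` (counts removed
#'   per filter).
#' @export
qc_cohort <- function(genotypes, miss_ind = 0.10, miss_snp = 0.10,
                      maf_min = 0.05, hwe_p = 1e-6) {
  G <- as.matrix(genotypes)
  ind_miss <- rowMeans(is.na(G))
  keep_ind <- ind_miss <= miss_ind
  n_ind_rm <- sum(!keep_ind)
  G <- G[keep_ind, , drop = FALSE]

  snp_miss <- colMeans(is.na(G))
  rm_miss <- snp_miss > miss_snp
  G <- G[, !rm_miss, drop = FALSE]

  f <- colMeans(G, na.rm = TRUE) / 2
  maf <- pmin(f, 1 - f)
  rm_maf <- maf < maf_min
  G <- G[, !rm_maf, drop = FALSE]

  hwe <- vapply(seq_len(ncol(G)), function(j) {
    x <- G[, j]
    hwe_exact_p(sum(x == 0, na.rm = TRUE), sum(x == 1, na.rm = TRUE),
                sum(x == 2, na.rm = TRUE))
  }, numeric(1))
  rm_hwe <- hwe < hwe_p
  G <- G[, !rm_hwe, drop = FALSE]
  if (!nrow(G) || !ncol(G)) stop("QC removed all individuals or all SNPs")
  list(genotypes = G,
       report = list(n_individuals_removed = n_ind_rm,
                     n_snp_missing = sum(rm_miss),
                     n_snp_maf = sum(rm_maf), n_snp_hwe = sum(rm_hwe),
                     n_individuals = nrow(G), n_snps = ncol(G)))
}

#' Polygenic risk scores at p-value thresholds
#'
#' Harmonizes target SNPs with the discovery summary statistics (flipped
#' allele orientations reverse the weight sign; strand-ambiguous A/T and
#' C/G SNPs and allele mismatches are dropped), optionally LD-clumps the
#' discovery statistics in the target panel, then for each threshold
#' computes `score_i = sum_j beta_j (dosage_ij - mean_j)` over SNPs with
#' discovery `p <= threshold`. Centering makes scores invariant to allele
#' flips and mean-imputes missing dosages.
#'
#' @param genotypes individuals x SNPs dosage matrix (colnames = SNP ids).
#' @param target_info data frame `id`, `effect_allele`, `other_allele` for
#'   the target SNPs.
#' @param discovery discovery summary-statistics data frame.
#' @param thresholds p-value cutoffs.
#' @param ld optional `ld_provider` in the target panel; when given, the
#'   discovery statistics are clumped at `clump_r2` within `clump_kb`.
#' @param clump_r2,clump_kb clumping parameters.
#' @return object of class `prs_result`: list with `scores` (individuals x
#'   thresholds matrix), `n_snps_used` per threshold, `n_dropped_ambiguous`,
#'   `n_dropped_mismatch`, `thresholds`.
#' @export
compute_prs <- function(genotypes, target_info, discovery,
                        thresholds = c(0.001, 0.005, 0.01, 0.05, 0.1, 0.5, 1),
                        ld = NULL, clump_r2 = 0.1, clump_kb = 250) {
  .check_sumstats(discovery)
  G <- as.matrix(genotypes)
  shared <- intersect(colnames(G), discovery$id)
  ti <- target_info[match(shared, target_info$id), , drop = FALSE]
  di <- discovery[match(shared, discovery$id), , drop = FALSE]
  cls <- classify_alleles(di$effect_allele, di$other_allele,
                          ti$effect_allele, ti$other_allele)
  n_amb <- sum(cls == "ambiguous")
  n_mis <- sum(cls == "mismatch")
  keep <- cls %in% c("same", "flip")
  shared <- shared[keep]; di <- di[keep, , drop = FALSE]
  beta <- ifelse(cls[keep] == "flip", -di$beta, di$beta)
  pvals <- di$p
  if (!is.null(ld)) {
    ld$window_bp <- clump_kb * 1000  # clumping window
    di2 <- di
    di2$beta <- beta
    leads <- clump_lead_snps(di2, ld, p_threshold = 1 + 1e-9,
                             r2_independence = clump_r2)
    sel <- shared %in% leads
    shared <- shared[sel]; beta <- beta[sel]; pvals <- pvals[sel]
  }
  Gs <- G[, shared, drop = FALSE]
  mu <- colMeans(Gs, na.rm = TRUE)
  Gc <- sweep(Gs, 2, mu)
  Gc[is.na(Gc)] <- 0  # mean imputation after centering
  scores <- matrix(0, nrow(G), length(thresholds),
                   dimnames = list(rownames(G), as.character(thresholds)))
  n_used <- integer(length(thresholds))
  for (t in seq_along(thresholds)) {
    sel <- pvals <= thresholds[t]
    n_used[t] <- sum(sel)
    if (n_used[t] == 0) {
      warning("no SNPs at threshold ", thresholds[t])
      next
    }
    scores[, t] <- Gc[, sel, drop = FALSE] %*% beta[sel]
  }
  structure(list(scores = scores, n_snps_used = n_used,
                 thresholds = thresholds, n_dropped_ambiguous = n_amb,
                 n_dropped_mismatch = n_mis),
            class = "prs_result")
}

#' Variance in a phenotype explained by polygenic scores
#'
#' For each threshold, the incremental R-squared of the score over the
#' covariates from nested linear models, with the F-test p-value; the
#' marginal (covariate-free) R-squared is also reported. The best threshold
#' maximizes the incremental R-squared.
#'
#' @param prs a `prs_result`.
#' @param phenotype numeric outcome (e.g. threshold PC1), aligned to the
#'   score rows.
#' @param covariates optional data frame of nuisance covariates.
#' @return data frame of class `prs_eval`: `threshold`, `n_snps`, `r2`
#'   (incremental), `r2_marginal`, `p`; attribute `best` holds the best
#'   threshold row.
#' @export
evaluate_prs <- function(prs, phenotype, covariates = NULL) {
  stopifnot(inherits(prs, "prs_result"))
  if (length(phenotype) != nrow(prs$scores))
    stop("phenotype not aligned to scores")
  if (length(phenotype) < 30) warning("n < 30: unstable R2 estimates")
  base_df <- if (is.null(covariates)) data.frame(y = phenotype) else
    cbind(data.frame(y = phenotype), covariates)
  m0 <- stats::lm(y ~ ., data = base_df)
  r2_0 <- summary(m0)$r.squared
  rows <- lapply(seq_along(prs$thresholds), function(t) {
    s <- prs$scores[, t]
    if (prs$n_snps_used[t] == 0 || stats::var(s) < 1e-16)
      return(data.frame(threshold = prs$thresholds[t],
                        n_snps = prs$n_snps_used[t], r2 = NA_real_,
                        r2_marginal = NA_real_, p = NA_real_))
    m1 <- stats::lm(y ~ . + s, data = cbind(base_df, s = s))
    an <- stats::anova(m0, m1)
    data.frame(threshold = prs$thresholds[t], n_snps = prs$n_snps_used[t],
               r2 = summary(m1)$r.squared - r2_0,
               r2_marginal = stats::cor(phenotype, s)^2,
               p = an$`Pr(>F)`[2])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  best <- out[which.max(out$r2), , drop = FALSE]
  attr(out, "best") <- best
  class(out) <- c("prs_eval", "data.frame")
  out
}
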