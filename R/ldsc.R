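# Desk-scale LD score regression: univariate heritability, stratified
# enrichment, and cross-trait genetic correlation, all with delete-one
# block-jackknife uncertainty computed from per-block sufficient statistics.

# Weighted least squares with a delete-one contiguous-block jackknife.
# `fun(coef)` maps a coefficient vector to the functional(s) of interest;
# returns the full-sample estimate, jackknife SEs and the replicate matrix.
.jackknife_wls <- function(X, Y, w, n_blocks, fun) {
  M <- nrow(X)
  p <- ncol(X)
  Y <- as.matrix(Y)
  n_blocks <- min(n_blocks, M)
  blk <- ceiling(seq_len(M) / (M / n_blocks))
  Xw <- X * w
  XtX <- crossprod(Xw, X)
  XtY <- crossprod(Xw, Y)
  coef_full <- solve(XtX, XtY)
  est <- fun(coef_full)
  reps <- matrix(NA_real_, n_blocks, length(est))
  for (b in seq_len(n_blocks)) {
    ii <- which(blk == b)
    Xb <- X[ii, , drop = FALSE]
    XtXb <- XtX - crossprod(Xb * w[ii], Xb)
    XtYb <- XtY - crossprod(Xb * w[ii], Y[ii, , drop = FALSE])
    reps[b, ] <- fun(solve(XtXb, XtYb))
  }
  m <- colMeans(reps)
  se <- sqrt((n_blocks - 1) / n_blocks * colSums(sweep(reps, 2, m)^2))
  list(est = est, se = se, reps = reps, coef = coef_full, n_blocks = n_blocks)
}

# align a sumstats table to an ldscore table by variant id
.align_ldsc <- function(ss, ldscores) {
  .check_sumstats(ss)
  idx <- match(ldscores$id, ss$id)
  keep <- !is.na(idx)
  list(ss = ss[idx[keep], , drop = FALSE],
       scores = ldscores$scores[keep, , drop = FALSE],
       keep = keep)
}

# standard LDSC chi-square winsorization
.cap_chi2 <- function(chi2, n, chi2_max = NULL) {
  cap <- if (is.null(chi2_max)) max(80, 0.001 * n) else chi2_max
  pmin(chi2, cap)
}

# heteroskedasticity + overcounting weights given a preliminary fit
.ldsc_weights <- function(l, n, M, h2_0, a0) {
  lc <- pmax(l, 1)
  1 / (lc * 2 * (n * h2_0 * lc / M + a0)^2)
}

# second (IRLS) weighting pass: expected chi-square from a first weighted
# fit, per SNP; substantially more efficient when per-SNP signal varies
# across annotation categories
.ldsc_weights2 <- function(X, l, w1, y) {
  b1 <- solve(crossprod(X * w1, X), crossprod(X * w1, y))
  mu <- pmax(as.numeric(X %*% b1), 0.5)
  1 / (pmax(l, 1) * 2 * mu^2)
}

#' Univariate LD score regression
#'
#' Regresses per-variant chi-square statistics on base LD scores with the
#' standard heteroskedasticity/overcounting weights (one reweighting pass
#' from a preliminary unweighted fit). The slope times `M/N` estimates SNP
#' heritability; the intercept estimates confounding inflation. Standard
#' errors come from a delete-one jackknife over `block_count` contiguous
#' SNP blocks. When the mean chi-square exceeds 1, the share of its excess
#' ascribed to polygenicity, `(mean chi2 - intercept) / (mean chi2 - 1)`,
#' is reported.
#'
#' @param sumstats summary-statistics data frame.
#' @param ldscores an `ldscore_table` (base category is used).
#' @param n GWAS sample size; defaults to the median of the `n` column.
#' @param M number of SNPs the heritability refers to; defaults to the
#'   number of regression SNPs.
#' @param block_count jackknife blocks (contiguous SNPs).
#' @param chi2_max winsorization cap; default `max(80, 0.001 N)`.
#' @return object of class `ldsc_fit`: list with `h2`, `h2_se`, `intercept`,
#'   `intercept_se`, `mean_chi2`, `attribution` (NA, flagged, when mean
#'   chi-square <= 1), `n_snps`, `jackknife`.
#' @export
fit_ldsc <- function(sumstats, ldscores, n = NULL, M = NULL,
                     block_count = 200, chi2_max = NULL) {
  al <- .align_ldsc(sumstats, ldscores)
  if (nrow(al$ss) < block_count)
    stop("need at least block_count SNPs shared with the LD scores")
  n <- if (is.null(n)) stats::median(al$ss$n) else n
  Msnp <- nrow(al$ss)
  M <- if (is.null(M)) Msnp else M
  l <- al$scores[, 1]
  chi2 <- .cap_chi2(sumstats_chi2(al$ss), n, chi2_max)

  pre <- stats::lm.fit(cbind(1, l), chi2)$coefficients
  h2_0 <- min(max(pre[2] * M / n, 0), 1)
  a0_0 <- max(pre[1], 1)
  X <- cbind(intercept = 1, l = l)
  w <- .ldsc_weights2(X, l, .ldsc_weights(l, n, M, h2_0, a0_0), chi2)
  jk <- .jackknife_wls(X, chi2, w, block_count,
                       function(b) c(b[1, 1], b[2, 1] * M / n))
  mean_chi2 <- mean(chi2)
  attribution <- if (mean_chi2 > 1)
    (mean_chi2 - jk$est[1]) / (mean_chi2 - 1) else NA_real_
  structure(list(h2 = unname(jk$est[2]), h2_se = unname(jk$se[2]),
                 intercept = unname(jk$est[1]),
                 intercept_se = unname(jk$se[1]),
                 mean_chi2 = mean_chi2, attribution = attribution,
                 n = n, M = M, n_snps = Msnp, jackknife = jk),
            class = "ldsc_fit")
}

#' @export
print.ldsc_fit <- function(x, ...) {
  cat(sprintf("LDSC: h2 = %.4f (SE %.4f), intercept = %.4f (SE %.4f), mean chi2 = %.3f\n",
              x$h2, x$h2_se, x$intercept, x$intercept_se, x$mean_chi2))
  if (!is.na(x$attribution))
    cat(sprintf("  share of inflation ascribed to polygenicity: %.1f%%\n",
                100 * x$attribution))
  invisible(x)
}

#' Stratified LD score regression
#'
#' Multiple regression of chi-square statistics on all per-category LD
#' scores. Per-category coefficients divided by N give tau_c; per-SNP
#' heritability is `sum_c a_jc tau_c` over the annotation membership, from
#' which the share of heritability, the enrichment
#' `prop_h2_c / prop_snps_c`, and a jackknife z-test of
#' `prop_h2_c - prop_snps_c = 0` (the enrichment p-value) are derived.
#' Collinear LD score columns are dropped with a warning.
#'
#' @param sumstats summary-statistics data frame.
#' @param ldscores an `ldscore_table` with all categories (base included).
#' @param annotations the `annotation_matrix` the scores were computed from.
#' @param n GWAS sample size; defaults to the median `n`.
#' @param block_count jackknife blocks.
#' @param chi2_max winsorization cap.
#' @return object of class `sldsc_fit`: list with `table` (one row per
#'   category: m_c, prop_snps, prop_h2, prop_h2_se, enrichment,
#'   enrichment_se, enrichment_p, tau, tau_se), `h2`, `h2_se`, `intercept`,
#'   `intercept_se`, `rank`, `dropped`.
#' @export
fit_stratified_ldsc <- function(sumstats, ldscores, annotations, n = NULL,
                                block_count = 200, chi2_max = NULL) {
  al <- .align_ldsc(sumstats, ldscores)
  n <- if (is.null(n)) stats::median(al$ss$n) else n
  memb <- annotations$membership
  storage.mode(memb) <- "double"
  M <- nrow(memb)
  cats <- colnames(memb)
  L <- al$scores
  chi2 <- .cap_chi2(sumstats_chi2(al$ss), n, chi2_max)

  X <- cbind(intercept = 1, L)
  qrX <- qr(X)
  dropped <- character(0)
  if (qrX$rank < ncol(X)) {
    keep_cols <- sort(qrX$pivot[seq_len(qrX$rank)])
    dropped <- colnames(X)[-keep_cols]
    warning("dropping collinear LD score columns: ",
            paste(dropped, collapse = ", "))
    X <- X[, keep_cols, drop = FALSE]
  }
  used_cats <- setdiff(colnames(X), "intercept")
  A <- memb[, used_cats, drop = FALSE]

  pre <- stats::lm.fit(cbind(1, L[, 1]), chi2)$coefficients
  h2_0 <- min(max(pre[2] * M / n, 0), 1)
  w1 <- .ldsc_weights(L[, 1], n, M, h2_0, max(pre[1], 1))
  w <- .ldsc_weights2(X, L[, 1], w1, chi2)

  # per-SNP h2 is identified from the reduced-rank fit, so heritability
  # shares and enrichments are reported for every original category,
  # including dropped (aliased) ones
  prop_snps <- annotations$m_c / M
  fun <- function(b) {
    a0 <- b[1, 1]
    tau <- b[-1, 1] / n
    h2j <- as.numeric(A %*% tau)
    h2t <- sum(h2j)
    prop <- as.numeric(crossprod(memb, h2j)) / h2t
    enr <- prop / prop_snps
    c(a0, h2t, tau, prop, enr, prop - prop_snps)
  }
  jk <- .jackknife_wls(X, chi2, w, block_count, fun)
  k <- length(used_cats)
  kk <- length(cats)
  i_tau <- 2 + seq_len(k)
  i_prop <- 2 + k + seq_len(kk)
  i_enr <- 2 + k + kk + seq_len(kk)
  i_diff <- 2 + k + 2 * kk + seq_len(kk)
  diff_z <- jk$est[i_diff] / jk$se[i_diff]
  tau_full <- tau_se_full <- rep(NA_real_, kk)
  tau_full[match(used_cats, cats)] <- jk$est[i_tau]
  tau_se_full[match(used_cats, cats)] <- jk$se[i_tau]
  tab <- data.frame(
    category = cats,
    m_c = annotations$m_c[cats],
    prop_snps = prop_snps,
    prop_h2 = jk$est[i_prop], prop_h2_se = jk$se[i_prop],
    enrichment = jk$est[i_enr], enrichment_se = jk$se[i_enr],
    enrichment_p = 2 * stats::pnorm(-abs(diff_z)),
    tau = tau_full, tau_se = tau_se_full,
    row.names = NULL, stringsAsFactors = FALSE
  )
  # the base category covers all SNPs: enrichment identically 1, no test
  tab$enrichment_p[tab$category == "base"] <- NA_real_
  structure(list(table = tab, h2 = unname(jk$est[2]),
                 h2_se = unname(jk$se[2]), intercept = unname(jk$est[1]),
                 intercept_se = unname(jk$se[1]),
                 rank = ncol(X), dropped = dropped, n = n, M = M,
                 jackknife = jk),
            class = "sldsc_fit")
}

#' @export
print.sldsc_fit <- function(x, ...) {
  cat(sprintf("stratified LDSC: h2 = %.4f (SE %.4f), intercept = %.4f\n",
              x$h2, x$h2_se, x$intercept))
  print(x$table, digits = 3)
  invisible(x)
}

#' Cross-trait LD score regression (genetic correlation)
#'
#' Harmonizes alleles between the two summary-statistics tables (flipped
#' orientations change the z sign; mismatches are dropped), regresses the
#' product `z_a * z_b` on base LD scores, and normalizes the genetic
#' covariance by the two univariate heritabilities fitted with the same
#' shared weights, so that identical inputs give rg = 1 exactly. Sample
#' overlap is absorbed by the cross-trait intercept. The jackknife refits
#' all three regressions per deleted block.
#'
#' @param sumstats_a,sumstats_b summary-statistics data frames.
#' @param ldscores an `ldscore_table`.
#' @param n_a,n_b sample sizes; default to the median `n` columns.
#' @param n_overlap overlapping individuals (informational; the overlap is
#'   estimated through the cross intercept either way).
#' @param block_count jackknife blocks.
#' @return object of class `rg_fit`: list with `rg`, `rg_se`, `p`,
#'   `gencov`, `cross_intercept`, `h2_a`, `h2_b`, `n_snps`. `rg` is NA
#'   (flagged) when either heritability estimate is non-positive.
#' @export
fit_genetic_correlation <- function(sumstats_a, sumstats_b, ldscores,
                                    n_a = NULL, n_b = NULL, n_overlap = 0,
                                    block_count = 200) {
  .check_sumstats(sumstats_a); .check_sumstats(sumstats_b)
  idx <- match(sumstats_a$id, sumstats_b$id)
  keep <- !is.na(idx)
  a <- sumstats_a[keep, , drop = FALSE]
  b <- sumstats_b[idx[keep], , drop = FALSE]
  cls <- classify_alleles(a$effect_allele, a$other_allele,
                          b$effect_allele, b$other_allele)
  ok <- cls %in% c("same", "flip", "ambiguous")
  a <- a[ok, ]; b <- b[ok, ]
  sgn <- ifelse(cls[ok] == "flip", -1, 1)
  sidx <- match(ldscores$id, a$id)
  skeep <- !is.na(sidx)
  a <- a[sidx[skeep], ]; b <- b[sidx[skeep], ]; sgn <- sgn[sidx[skeep]]
  l <- ldscores$scores[skeep, 1]
  n_a <- if (is.null(n_a)) stats::median(a$n) else n_a
  n_b <- if (is.null(n_b)) stats::median(b$n) else n_b
  M <- length(l)
  za <- a$beta / a$se
  zb <- sgn * b$beta / b$se
  capz <- function(z, n) sign(z) * sqrt(.cap_chi2(z^2, n))
  za <- capz(za, n_a); zb <- capz(zb, n_b)

  # shared weights from preliminary unweighted fits of the three regressions
  pa <- stats::lm.fit(cbind(1, l), za^2)$coefficients
  pb <- stats::lm.fit(cbind(1, l), zb^2)$coefficients
  pab <- stats::lm.fit(cbind(1, l), za * zb)$coefficients
  lc <- pmax(l, 1)
  va <- pmax(pa[1], 1) + max(pa[2], 0) * lc
  vb <- pmax(pb[1], 1) + max(pb[2], 0) * lc
  cab <- pab[1] + pab[2] * lc
  w <- 1 / (lc * (va * vb + cab^2))

  X <- cbind(intercept = 1, l = l)
  Y <- cbind(a = za^2, b = zb^2, ab = za * zb)
  fun <- function(bm) {
    h2a <- bm[2, "a"] * M / n_a
    h2b <- bm[2, "b"] * M / n_b
    gencov <- bm[2, "ab"] * M / sqrt(n_a * n_b)
    rg <- if (h2a > 0 && h2b > 0) gencov / sqrt(h2a * h2b) else NA_real_
    c(rg, gencov, bm[1, "ab"], h2a, h2b)
  }
  jk <- .jackknife_wls(X, Y, w, block_count, fun)
  rg <- jk$est[1]
  rg_se <- jk$se[1]
  p <- if (is.finite(rg) && is.finite(rg_se) && rg_se > 0)
    2 * stats::pnorm(-abs(rg / rg_se)) else NA_real_
  structure(list(rg = rg, rg_se = rg_se, p = p, gencov = jk$est[2],
                 cross_intercept = jk$est[3], h2_a = jk$est[4],
                 h2_b = jk$est[5], n_snps = M, n_overlap = n_overlap),
            class = "rg_fit")
}

#' @export
print.rg_fit <- function(x, ...) {
  cat(sprintf("cross-trait LDSC: rg = %.3f (SE %.3f, p = %.2g); h2_a = %.4f, h2_b = %.4f\n",
              x$rg, x$rg_se, x$p, x$h2_a, x$h2_b))
  invisible(x)
}
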