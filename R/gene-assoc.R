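# Gene-level association from SNP summary statistics: mean-chi-square gene
# statistic with a weighted-chi-square null, competitive gene-set test, and
# gene-property regression against cell-type expression.

#' Upper tail of a positively weighted sum of 1-df chi-squares
#'
#' Computes `P(sum_i lambda_i X_i > x)` with `X_i ~ chi2_1` independent, by
#' Imhof's numeric inversion of the characteristic function, with exact
#' closed forms when all weights are equal and a Monte-Carlo fallback
#' (1e6 draws) if the quadrature fails.
#'
#' @param x quantile (a single nonnegative value).
#' @param lambda positive weights.
#' @param tol integration tolerance.
#' @return the upper tail probability, clamped to `[0, 1]`.
#' @export
pweightchisq_upper <- function(x, lambda, tol = 1e-8) {
  lambda <- lambda[lambda > 1e-12]
  k <- length(lambda)
  if (k == 0) return(NA_real_)
  if (max(abs(lambda - lambda[1])) < 1e-12)
    return(stats::pchisq(x / lambda[1], df = k, lower.tail = FALSE))
  imhof <- function(u) {
    theta <- 0.5 * colSums(atan(outer(lambda, u))) - 0.5 * x * u
    rho <- exp(0.25 * colSums(log1p(outer(lambda^2, u^2))))
    sin(theta) / (u * rho)
  }
  envelope <- function(u)
    1 / (u * exp(0.25 * sum(log1p(lambda^2 * u^2))))
  # truncation point: beyond U the integrand oscillates with period
  # <= 4 pi / x inside a decaying envelope, so the tail is bounded by
  # (2 / x) * envelope(U); double U until that bound is below tol
  U <- 30
  while (envelope(U) * 2 / max(x, 0.5) > tol && U < 1e7) U <- U * 2
  # composite Simpson on a grid resolving the fastest oscillation
  period <- 2 * pi / (0.5 * (sum(lambda) + x))
  h <- period / 20
  n_int <- min(ceiling(U / (2 * h)), 1.5e6)
  h <- U / (2 * n_int)
  u <- seq(0, U, by = h)[-1]  # u = 0 handled by the analytic limit
  fu <- imhof(u)
  f0 <- 0.5 * (sum(lambda) - x)  # limit of the integrand at u -> 0
  fall <- c(f0, fu)
  wts <- rep(c(4, 2), length.out = length(u)); wts[length(u)] <- 1
  val <- 0.5 + (h / 3) * sum(c(1, wts) * fall) / pi
  if (is.na(val) || val < -1e-4 || val > 1 + 1e-4) {
    # deterministic Monte-Carlo fallback that leaves the caller's RNG intact
    has_seed <- exists(".Random.seed", envir = globalenv())
    if (has_seed) old <- get(".Random.seed", envir = globalenv())
    set.seed(1L)
    draws <- colSums(lambda * matrix(stats::rchisq(1e6 * k, df = 1), k))
    val <- mean(draws > x)
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
  }
  min(max(val, 0), 1)
}

#' Map SNPs to gene bodies
#'
#' A SNP is assigned to every gene whose body (closed interval
#' `[start, end]`, no flanking window) contains its position; SNPs inside
#' exclusion regions (e.g. the MHC) are dropped from all genes.
#'
#' @param sumstats summary-statistics data frame.
#' @param genes gene-model data frame with columns `gene_id`, `chrom`,
#'   `start`, `end` (1-based, closed) and optionally `strand`, `tss`.
#' @param exclusion_regions optional data frame with `chrom`, `start`,
#'   `end` (1-based, closed).
#' @return data frame with columns `gene_id`, `id` (SNP).
#' @export
map_snps_to_genes <- function(sumstats, genes, exclusion_regions = NULL) {
  .check_sumstats(sumstats)
  snps <- GenomicRanges::GRanges(sumstats$chrom,
                                 IRanges::IRanges(sumstats$pos, sumstats$pos))
  keep <- rep(TRUE, nrow(sumstats))
  if (!is.null(exclusion_regions) && nrow(exclusion_regions)) {
    ex <- GenomicRanges::GRanges(exclusion_regions$chrom,
                                 IRanges::IRanges(exclusion_regions$start,
                                                  exclusion_regions$end))
    keep <- !IRanges::overlapsAny(snps, ex, ignore.strand = TRUE)
  }
  gr <- GenomicRanges::GRanges(genes$chrom,
                               IRanges::IRanges(genes$start, genes$end))
  hits <- GenomicRanges::findOverlaps(snps[keep], gr, ignore.strand = TRUE)
  data.frame(gene_id = genes$gene_id[S4Vectors::subjectHits(hits)],
             id = sumstats$id[keep][S4Vectors::queryHits(hits)],
             stringsAsFactors = FALSE)
}

#' Gene-level association test
#'
#' The gene statistic is the mean chi-square of its member SNPs. Under the
#' null the statistic is distributed as `(1/k) sum_i lambda_i chi2_1`, with
#' `lambda_i` the eigenvalues of the member-SNP LD correlation matrix; the
#' p-value is the numeric weighted-chi-square tail and the gene z is
#' `qnorm(1 - p)`. A single-SNP gene returns the SNP p exactly. Genes with
#' no tested SNPs are skipped.
#'
#' @param gene_snp_map output of [map_snps_to_genes()].
#' @param sumstats summary-statistics data frame.
#' @param ld a panel-backed `ld_provider` (signed correlations are needed
#'   for the eigenvalues).
#' @return data frame with columns `gene_id`, `n_snps`, `stat`, `p`, `z`,
#'   `ld_density` (mean off-diagonal r2 among member SNPs).
#' @export
gene_test <- function(gene_snp_map, sumstats, ld) {
  stopifnot(ld$type == "panel")
  chi2 <- stats::setNames(sumstats_chi2(sumstats), sumstats$id)
  G <- ld$panel$genotypes
  res <- lapply(split(gene_snp_map$id, gene_snp_map$gene_id), function(ids) {
    ids <- intersect(unique(ids), names(chi2))
    k <- length(ids)
    if (k == 0) return(NULL)
    stat <- mean(chi2[ids])
    if (k == 1) {
      p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
      ldd <- 0
    } else {
      R <- stats::cor(G[, ld$col[ids], drop = FALSE])
      lam <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
      p <- pweightchisq_upper(k * stat, pmax(lam, 0))
      ldd <- mean(R[upper.tri(R)]^2)
    }
    p <- min(max(p, 1e-300), 1)  # keep the probit transform finite
    data.frame(n_snps = k, stat = stat, p = p,
               z = stats::qnorm(p, lower.tail = FALSE), ld_density = ldd)
  })
  res <- res[!vapply(res, is.null, logical(1))]
  out <- do.call(rbind, res)
  out <- cbind(gene_id = names(res), out)
  rownames(out) <- NULL
  out
}

# covariate frame for the competitive tests: log gene length, log SNP
# count, LD density
.gene_covariates <- function(gene_results, genes) {
  glen <- genes$end[match(gene_results$gene_id, genes$gene_id)] -
    genes$start[match(gene_results$gene_id, genes$gene_id)] + 1
  data.frame(log_len = log(pmax(glen, 1)),
             log_nsnp = log(gene_results$n_snps),
             ld_density = gene_results$ld_density)
}

#' Competitive gene-set enrichment test
#'
#' Linear regression of gene z-scores on set membership with the standard
#' confounder covariates (log gene length, log SNP count, LD density);
#' one-sided p for a positive membership effect.
#'
#' @param gene_results output of [gene_test()].
#' @param set_genes character vector of gene ids in the set.
#' @param genes gene-model data frame (for gene length).
#' @return list with `beta`, `se`, `p` (one-sided), `n_in`, `n_out`.
#' @export
gene_set_test <- function(gene_results, set_genes, genes) {
  m <- as.integer(gene_results$gene_id %in% set_genes)
  if (all(m == 1) || all(m == 0))
    stop("gene set must contain some but not all scored genes")
  if (sum(m) < 2 || sum(1 - m) < 2)
    stop("need at least 2 genes inside and outside the set")
  cv <- .gene_covariates(gene_results, genes)
  fit <- stats::lm(gene_results$z ~ m + ., data = cv)
  sm <- summary(fit)$coefficients["m", ]
  list(beta = unname(sm[1]), se = unname(sm[2]),
       p = stats::pt(sm[3], df = fit$df.residual, lower.tail = FALSE),
       n_in = sum(m), n_out = sum(1 - m))
}

#' Normalize an expression matrix across cell types
#'
#' Log-transforms TPM values (`log(TPM + 1)`) and quantile-normalizes
#' columns to the common quantile profile (the mean of the sorted columns;
#' ties averaged). The per-gene average across cell types is returned as
#' the conditioning covariate of [gene_property_test()].
#'
#' @param tpm nonnegative genes x cell-types matrix.
#' @return list with `norm` (normalized matrix), `avg` (row means) and
#'   `med` (row medians).
#' @export
normalize_expression <- function(tpm) {
  if (any(tpm < 0)) stop("TPM values must be nonnegative")
  lg <- log(tpm + 1)
  norm <- limma::normalizeQuantiles(lg, ties = TRUE)
  dimnames(norm) <- dimnames(tpm)
  list(norm = norm, avg = rowMeans(norm),
       med = apply(norm, 1, stats::median))
}

#' Gene-property test of cell-type expression
#'
#' Regresses gene z-scores on one cell type's (normalized) expression
#' column, conditioning on the per-gene average expression across all cell
#' types (or the median, by flag) and the standard covariates; one-sided p
#' for a positive coefficient. If the cell-type column is collinear with
#' the conditioning covariate its coefficient is dropped with a warning and
#' the p-value is NA (flagged).
#'
#' @param gene_results output of [gene_test()].
#' @param expression result of [normalize_expression()].
#' @param celltype column label in the expression matrix.
#' @param genes gene-model data frame.
#' @param center `"mean"` (default) or `"median"`: the across-type profile
#'   conditioned on.
#' @return list with `coef`, `se`, `p` (one-sided), `n_genes`.
#' @export
gene_property_test <- function(gene_results, expression, celltype, genes,
                               center = c("mean", "median")) {
  center <- match.arg(center)
  norm <- expression$norm
  common <- intersect(gene_results$gene_id, rownames(norm))
  if (length(common) < 5) stop("too few genes shared with the expression matrix")
  gr <- gene_results[match(common, gene_results$gene_id), , drop = FALSE]
  x <- norm[common, celltype]
  if (stats::var(x) < 1e-12) {
    warning("zero-variance expression column; property test undefined")
    return(list(coef = NA_real_, se = NA_real_, p = NA_real_,
                n_genes = length(common)))
  }
  ctr <- if (center == "mean") expression$avg[common] else expression$med[common]
  cv <- .gene_covariates(gr, genes)
  dat <- cbind(data.frame(z = gr$z, x = x, ctr = ctr), cv)
  # conditioning covariates enter first so an aliased cell-type column is
  # the term that gets dropped
  fit <- stats::lm(z ~ ctr + log_len + log_nsnp + ld_density + x, data = dat)
  co <- summary(fit)$coefficients
  if (!"x" %in% rownames(co) || is.na(stats::coef(fit)["x"])) {
    warning("cell-type column collinear with conditioning covariate; dropped")
    return(list(coef = NA_real_, se = NA_real_, p = NA_real_,
                n_genes = length(common)))
  }
  list(coef = unname(co["x", 1]), se = unname(co["x", 2]),
       p = stats::pt(co["x", 3], df = fit$df.residual, lower.tail = FALSE),
       n_genes = length(common))
}
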