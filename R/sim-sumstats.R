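# Planted heritability model and the generative twin of LD score regression.

#' Build a binary annotation matrix over a panel's variants
#'
#' The first category is always `base` and covers every variant; further
#' categories are given as index vectors (or logical masks) over the panel's
#' variants.
#'
#' @param n_variants number of variants (or a `reference_panel`).
#' @param categories named list of integer index vectors or logical masks.
#' @return an object of class `annotation_matrix`: list with `categories`
#'   (labels), `membership` (variants x categories 0/1 matrix, base first)
#'   and `m_c` (per-category SNP counts).
#' @export
make_annotations <- function(n_variants, categories = list()) {
  if (inherits(n_variants, "reference_panel"))
    n_variants <- nrow(n_variants$variants)
  M <- as.integer(n_variants)
  if (length(categories) && is.null(names(categories)))
    stop("categories must be named")
  memb <- matrix(1L, M, 1L, dimnames = list(NULL, "base"))
  for (nm in names(categories)) {
    v <- categories[[nm]]
    col <- integer(M)
    if (is.logical(v)) col[v] <- 1L else col[as.integer(v)] <- 1L
    memb <- cbind(memb, col)
    colnames(memb)[ncol(memb)] <- nm
  }
  structure(list(categories = colnames(memb), membership = memb,
                 m_c = colSums(memb)),
            class = "annotation_matrix")
}

#' Annotate panel variants by positional overlap with interval sets
#'
#' Builds an [make_annotations()] object whose non-base categories mark the
#' panel variants falling inside the given genomic intervals (e.g. BED peaks
#' read with [read_bed()]).
#'
#' @param panel a `reference_panel`.
#' @param interval_sets named list of `GRanges` (1-based, closed).
#' @return an `annotation_matrix`.
#' @export
annotations_from_intervals <- function(panel, interval_sets) {
  v <- panel$variants
  snps <- GenomicRanges::GRanges(v$chrom, IRanges::IRanges(v$pos, v$pos))
  cats <- lapply(interval_sets, function(gr)
    IRanges::overlapsAny(snps, gr, ignore.strand = TRUE))
  make_annotations(nrow(v), cats)
}

#' Plant the heritability truth of a simulation
#'
#' Fixes the per-variant heritability contributions used by all downstream
#' generators. With no enrichment, heritability is spread uniformly over
#' variants; with `enrichment`, each named (non-base, mutually disjoint)
#' annotation category receives a share of heritability equal to
#' `enrichment x (its share of SNPs)`, spread uniformly within the category.
#' Per-allele causal effects are the standardized effects divided by the
#' genotype standard deviation, with independent random signs.
#'
#' @param panel a `reference_panel`.
#' @param h2_total total SNP heritability in `[0, 1]`.
#' @param annotations optional `annotation_matrix` aligned to the panel.
#' @param enrichment named numeric vector of target enrichments for non-base
#'   categories (disjoint). Categories not named get the leftover share.
#' @param rg genetic correlation between trait pairs (scalar, used when
#'   several traits are generated), in `[-1, 1]`.
#' @param seed integer seed (controls effect signs).
#' @return object of class `simulation_truth` with fields `h2_total`,
#'   `per_annotation_enrichment`, `h2_snp` (per-variant standardized
#'   heritability), `causal_effects` (named per-allele effects), `rg`, `seed`.
#' @export
make_simulation_truth <- function(panel, h2_total, annotations = NULL,
                                  enrichment = NULL, rg = NULL, seed = 1) {
  stopifnot(inherits(panel, "reference_panel"),
            h2_total >= 0, h2_total <= 1)
  M <- nrow(panel$variants)
  h2_snp <- rep(h2_total / M, M)
  if (!is.null(enrichment) && length(enrichment)) {
    if (is.null(annotations)) stop("enrichment requires annotations")
    memb <- annotations$membership
    if (nrow(memb) != M) stop("annotations not aligned to panel")
    cats <- names(enrichment)
    if (!all(cats %in% colnames(memb))) stop("unknown enrichment category")
    sub <- memb[, cats, drop = FALSE]
    if (any(rowSums(sub) > 1))
      stop("enrichment categories must be disjoint")
    shares <- vapply(cats, function(cc) {
      m_c <- sum(memb[, cc])
      enrichment[[cc]] * m_c / M
    }, numeric(1))
    rest_share <- 1 - sum(shares)
    in_any <- rowSums(sub) > 0
    m_rest <- sum(!in_any)
    if (rest_share < 0) stop("requested enrichments exceed total heritability")
    if (m_rest > 0) h2_snp[!in_any] <- h2_total * rest_share / m_rest
    for (cc in cats) {
      idx <- memb[, cc] == 1
      h2_snp[idx] <- h2_total * enrichment[[cc]] / M
    }
  }
  set.seed(seed)
  sgn <- sample(c(-1, 1), M, replace = TRUE)
  sd_g <- sqrt(2 * panel$variants$maf * (1 - panel$variants$maf))
  beta <- sgn * sqrt(h2_snp) / sd_g
  names(beta) <- panel$variants$id
  structure(list(h2_total = h2_total,
                 per_annotation_enrichment = enrichment,
                 h2_snp = h2_snp, causal_effects = beta,
                 rg = rg, seed = seed),
            class = "simulation_truth")
}

#' Recompute planted enrichment from the causal effects
#'
#' Self-consistency check for [make_simulation_truth()]: the enrichment of a
#' category is (share of heritability in it) / (share of SNPs in it),
#' recomputed from the stored per-variant contributions.
#'
#' @param truth a `simulation_truth`.
#' @param annotations the `annotation_matrix` used to plant it.
#' @param category category label.
#' @return the realized enrichment.
#' @export
truth_enrichment <- function(truth, annotations, category) {
  memb <- annotations$membership[, category]
  (sum(truth$h2_snp[memb == 1]) / sum(truth$h2_snp)) / (mean(memb))
}

#' Generate GWAS summary statistics under the LD score regression model
#'
#' Default `"z"` mode draws marginal association z-scores blockwise from a
#' multivariate normal with covariance `a0 * R + N * R D R`, where `R` is the
#' panel's empirical per-block LD correlation matrix, `D` the diagonal of
#' planted per-SNP (standardized) heritabilities, `N` the GWAS sample size
#' and `a0` the confounding intercept. For several traits the genetic parts
#' share correlation `truth$rg` and the noise parts share the sample-overlap
#' correlation `n_overlap / sqrt(N_a N_b) * rho_pheno`, with
#' `rho_pheno = rg * h2 + env_corr * (1 - h2)`.
#'
#' `"conditional"` mode draws z-scores conditional on the realized planted
#' effects: `z ~ N(sqrt(N) R alpha, a0 R)` blockwise, with `alpha` the
#' standardized causal effects stored in the truth. The marginal (`"z"`)
#' mode integrates the effect signs out and is the right null model for
#' heritability regressions; the conditional mode preserves effect-level
#' alignment and is required when downstream stages reuse the effect
#' directions (e.g. polygenic scoring against a cohort simulated from the
#' same truth). Single trait only.
#'
#' `"genotype"` mode instead draws `sample_size` fresh individuals from the
#' panel's generating population, simulates phenotypes from the planted
#' per-allele effects and computes marginal regressions; it agrees with
#' `"z"` mode in expectation and is intended for small `sample_size`
#' (single trait only).
#'
#' @param panel a `reference_panel`.
#' @param truth a `simulation_truth` for the same panel.
#' @param sample_size GWAS sample size N.
#' @param n_traits number of traits to generate.
#' @param confounding_intercept a0 >= 1; 1 means no confounding.
#' @param mode `"z"` (default) or `"genotype"`.
#' @param env_corr residual (environmental) correlation between traits for
#'   overlapping samples.
#' @param n_overlap number of individuals shared between the trait GWAS.
#' @param seed integer seed.
#' @return a list of `n_traits` summary-statistics data frames with columns
#'   chrom, pos, id, effect_allele, other_allele, beta, se, p, n.
#' @export
gen_sumstats <- function(panel, truth, sample_size, n_traits = 1,
                         confounding_intercept = 1,
                         mode = c("z", "conditional", "genotype"),
                         env_corr = 0, n_overlap = 0, seed = 1) {
  mode <- match.arg(mode)
  stopifnot(inherits(panel, "reference_panel"),
            inherits(truth, "simulation_truth"))
  M <- nrow(panel$variants)
  if (length(truth$h2_snp) != M)
    stop("truth not aligned to panel (alignment error)")
  if (confounding_intercept < 1) stop("confounding_intercept must be >= 1")
  N <- sample_size
  if (mode == "genotype") {
    if (n_traits != 1) stop("genotype mode generates a single trait")
    return(list(trait1 = .gen_sumstats_genotype(panel, truth, N, seed)))
  }
  if (mode == "conditional") {
    if (n_traits != 1) stop("conditional mode generates a single trait")
    return(list(trait1 = .gen_sumstats_conditional(
      panel, truth, N, confounding_intercept, seed)))
  }
  set.seed(seed)
  Rb <- .panel_block_cor(panel)
  h2j <- truth$h2_snp
  rg <- if (is.null(truth$rg)) 0 else truth$rg
  h2 <- truth$h2_total
  rho_pheno <- rg * h2 + env_corr * (1 - h2)
  c_e <- if (N > 0) n_overlap / N * rho_pheno else 0
  Tg <- matrix(rg, n_traits, n_traits); diag(Tg) <- 1
  Te <- matrix(c_e, n_traits, n_traits); diag(Te) <- 1

  z <- matrix(0, M, n_traits)
  idx0 <- 0L
  for (b in seq_along(Rb)) {
    R <- Rb[[b]]
    L <- nrow(R)
    jj <- idx0 + seq_len(L)
    D <- diag(h2j[jj], L)
    Sg <- N * R %*% D %*% R
    Se <- confounding_intercept * R
    if (n_traits == 1) {
      S <- Sg + Se
    } else {
      S <- kronecker(Tg, Sg) + kronecker(Te, Se)
    }
    U <- chol(S + diag(1e-10, nrow(S)))
    draw <- as.numeric(crossprod(U, stats::rnorm(nrow(S))))
    z[jj, ] <- matrix(draw, L, n_traits)
    idx0 <- idx0 + L
  }
  sd_g <- sqrt(2 * panel$variants$maf * (1 - panel$variants$maf))
  se <- 1 / (sqrt(N) * sd_g)
  out <- lapply(seq_len(n_traits), function(t) {
    v <- panel$variants
    data.frame(chrom = v$chrom, pos = v$pos, id = v$id,
               effect_allele = v$effect_allele, other_allele = v$other_allele,
               beta = z[, t] * se, se = se, p = .z_to_p(z[, t]),
               n = N, stringsAsFactors = FALSE)
  })
  names(out) <- paste0("trait", seq_len(n_traits))
  out
}

# conditional mode: z centered on sqrt(N) R alpha for the realized
# standardized effects alpha, noise covariance a0 R blockwise
.gen_sumstats_conditional <- function(panel, truth, N, a0, seed) {
  set.seed(seed)
  Rb <- .panel_block_cor(panel)
  sd_g <- sqrt(2 * panel$variants$maf * (1 - panel$variants$maf))
  alpha <- truth$causal_effects * sd_g
  M <- nrow(panel$variants)
  z <- numeric(M)
  idx0 <- 0L
  for (b in seq_along(Rb)) {
    R <- Rb[[b]]
    L <- nrow(R)
    jj <- idx0 + seq_len(L)
    mu <- sqrt(N) * as.numeric(R %*% alpha[jj])
    U <- chol(a0 * R + diag(1e-10, L))
    z[jj] <- mu + as.numeric(crossprod(U, stats::rnorm(L)))
    idx0 <- idx0 + L
  }
  se <- 1 / (sqrt(N) * sd_g)
  v <- panel$variants
  data.frame(chrom = v$chrom, pos = v$pos, id = v$id,
             effect_allele = v$effect_allele, other_allele = v$other_allele,
             beta = z * se, se = se, p = .z_to_p(z), n = N,
             stringsAsFactors = FALSE)
}

# genotype mode: draw fresh individuals from the panel's generating
# population, simulate a phenotype from the planted per-allele effects,
# run per-SNP marginal regressions
.gen_sumstats_genotype <- function(panel, truth, N, seed) {
  X <- draw_panel_individuals(panel, N, seed = seed)
  storage.mode(X) <- "double"
  set.seed(child_seed(seed, "genotype_phenotype"))
  g <- as.numeric(X %*% truth$causal_effects)
  vg <- truth$h2_total
  y <- g + stats::rnorm(N, sd = sqrt(max(1 - vg, 1e-8)))
  xm <- colMeans(X)
  xv <- colMeans(X^2) - xm^2
  xv[xv < 1e-12] <- NA_real_
  ym <- mean(y)
  cxy <- as.numeric(crossprod(X, y)) / N - xm * ym
  beta <- cxy / xv
  yv <- mean(y^2) - ym^2
  resid_var <- pmax(yv - beta^2 * xv, 1e-12)
  se <- sqrt(resid_var / (N * xv))
  v <- panel$variants
  data.frame(chrom = v$chrom, pos = v$pos, id = v$id,
             effect_allele = v$effect_allele, other_allele = v$other_allele,
             beta = beta, se = se, p = .z_to_p(beta / se),
             n = N, stringsAsFactors = FALSE)
}
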