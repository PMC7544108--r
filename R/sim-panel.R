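# Synthetic LD reference panel: latent-Gaussian AR(1) haplotype blocks,
# thresholded to allele indicators and summed to dosages.

# Bivariate standard normal CDF P(X < t1, Y < t2) with correlation rho,
# by one-dimensional quadrature (no external dependency needed).
.pbinorm <- function(t1, t2, rho) {
  if (abs(rho) < 1e-12) return(stats::pnorm(t1) * stats::pnorm(t2))
  if (rho > 0.999999) return(stats::pnorm(min(t1, t2)))
  f <- function(x) stats::dnorm(x) * stats::pnorm((t2 - rho * x) / sqrt(1 - rho^2))
  stats::integrate(f, -8.5, t1, rel.tol = 1e-10, abs.tol = 1e-12)$value
}

# Latent correlation that yields a target correlation between two allele
# indicators thresholded at the same MAF (tetrachoric inversion). The
# correlation between dosages (sums of two independent haplotypes) equals the
# haplotype-level indicator correlation, so calibrating the indicators
# calibrates the dosages.
.latent_rho <- function(target_r, maf) {
  if (target_r <= 0) return(0)
  t <- stats::qnorm(maf)
  p11_target <- maf^2 + target_r * maf * (1 - maf)
  f <- function(r) .pbinorm(t, t, r) - p11_target
  stats::uniroot(f, c(0, 0.999999), tol = 1e-10)$root
}

#' Generate a synthetic LD reference panel
#'
#' Simulates diploid dosages for `n_individuals` at `n_variants` biallelic
#' variants arranged in independent LD blocks of `block_length` variants.
#' Within a block, haplotypes follow a latent Gaussian AR(1) process
#' thresholded to allele indicators, so pairwise dosage correlation decays
#' geometrically with variant distance. The latent AR(1) coefficient is
#' calibrated (tetrachoric inversion) so that the *dosage* correlation between
#' adjacent variants equals `within_block_corr`; a naive latent coefficient
#' would be attenuated by the thresholding. One minor-allele frequency is
#' drawn per block (shared threshold), which keeps any target correlation
#' below 1 attainable.
#'
#' @param n_individuals number of diploid individuals.
#' @param n_variants total number of variants; must be divisible by
#'   `block_length`.
#' @param block_length variants per LD block.
#' @param within_block_corr target dosage correlation between adjacent
#'   in-block variants, in `[0, 1)`; a length-2 vector draws one value per
#'   block uniformly from that interval (heterogeneous LD, so LD scores
#'   vary across the genome as they do in real panels).
#' @param maf_range length-2 interval inside `(0.01, 0.5]` from which the
#'   per-block minor-allele frequency is drawn.
#' @param chrom chromosome label for all variants.
#' @param pos_start,pos_step base-pair position of the first variant and
#'   spacing between consecutive variants.
#' @param seed integer seed; the generator is a pure function of it.
#' @return an object of class `reference_panel`: a list with `individuals`,
#'   `variants` (data frame: chrom, pos, id, effect_allele, other_allele,
#'   maf), `genotypes` (individuals x variants integer dosage matrix of the
#'   effect = minor allele), `block` (block index per variant), and `params`
#'   (block MAFs/thresholds/latent coefficients, for drawing further
#'   individuals from the same population).
#' @export
gen_reference_panel <- function(n_individuals, n_variants, block_length = 50,
                                within_block_corr = 0.9,
                                maf_range = c(0.05, 0.5),
                                chrom = "1", pos_start = 1e6, pos_step = 1000,
                                seed = 1) {
  if (n_individuals <= 0 || n_variants <= 0 || block_length <= 0)
    stop("panel dimensions must be positive")
  if (n_variants %% block_length != 0)
    stop("n_variants must be divisible by block_length")
  if (any(within_block_corr < 0) || any(within_block_corr >= 1))
    stop("within_block_corr must be in [0, 1)")
  if (maf_range[1] <= 0.01 || maf_range[2] > 0.5 || maf_range[1] > maf_range[2])
    stop("maf_range must lie within (0.01, 0.5]")

  n_blocks <- n_variants %/% block_length
  set.seed(seed)
  block_maf <- stats::runif(n_blocks, maf_range[1], maf_range[2])
  block_thr <- stats::qnorm(block_maf)
  block_target <- if (length(within_block_corr) == 2)
    stats::runif(n_blocks, within_block_corr[1], within_block_corr[2])
  else rep(within_block_corr[1], n_blocks)
  block_rho <- vapply(seq_len(n_blocks), function(b)
    .latent_rho(block_target[b], block_maf[b]), numeric(1))

  G <- matrix(0L, n_individuals, n_variants)
  for (b in seq_len(n_blocks)) {
    cols <- ((b - 1L) * block_length + 1L):(b * block_length)
    G[, cols] <- .draw_block_dosages(n_individuals, block_length,
                                     block_rho[b], block_thr[b])
  }

  # guard against monomorphic columns (possible at small n): inject one het
  mono <- which(apply(G, 2, function(x) length(unique(x)) == 1L))
  for (j in mono) G[1L, j] <- if (G[1L, j] == 0L) 1L else G[1L, j] - 1L

  # orient so the effect allele is the minor one; maf is the empirical
  # effect-allele frequency computed from the genotypes
  f <- colMeans(G) / 2
  flip <- f > 0.5
  if (any(flip)) {
    G[, flip] <- 2L - G[, flip]
    f[flip] <- 1 - f[flip]
  }

  variants <- data.frame(
    chrom = chrom,
    pos = pos_start + (seq_len(n_variants) - 1L) * pos_step,
    id = sprintf("s%06d", seq_len(n_variants)),
    effect_allele = ifelse(flip, "G", "A"),
    other_allele = ifelse(flip, "A", "G"),
    maf = f,
    stringsAsFactors = FALSE
  )
  structure(list(
    individuals = n_individuals,
    variants = variants,
    genotypes = G,
    block = rep(seq_len(n_blocks), each = block_length),
    params = list(block_maf = block_maf, block_thr = block_thr,
                  block_rho = block_rho, block_target = block_target,
                  block_length = block_length,
                  within_block_corr = within_block_corr),
    cache = new.env(parent = emptyenv()),
    seed = seed
  ), class = "reference_panel")
}

# draw n x L dosages for one block: two independent latent AR(1) haplotype
# chains thresholded at `thr`
.draw_block_dosages <- function(n, L, rho, thr) {
  hap <- function() {
    Z <- matrix(0, n, L)
    Z[, 1L] <- stats::rnorm(n)
    if (L > 1L) {
      s <- sqrt(1 - rho^2)
      for (t in 2:L) Z[, t] <- rho * Z[, t - 1L] + s * stats::rnorm(n)
    }
    Z < thr
  }
  m <- hap() + hap()
  storage.mode(m) <- "integer"
  m
}

#' @export
print.reference_panel <- function(x, ...) {
  cat(sprintf("reference_panel: %d individuals x %d variants (%d blocks of %d)\n",
              x$individuals, nrow(x$variants), max(x$block),
              x$params$block_length))
  invisible(x)
}

#' Draw additional individuals from a panel's generating population
#'
#' Uses the block MAFs, thresholds and latent AR(1) coefficients stored in a
#' [gen_reference_panel()] object to simulate new diploid individuals from
#' the same population (used by the target-cohort generator).
#'
#' @param panel a `reference_panel`.
#' @param n number of new individuals.
#' @param seed integer seed.
#' @return integer dosage matrix, `n` x `n_variants`, oriented to the panel's
#'   effect alleles.
#' @export
draw_panel_individuals <- function(panel, n, seed = 1) {
  stopifnot(inherits(panel, "reference_panel"))
  set.seed(seed)
  p <- panel$params
  L <- p$block_length
  n_blocks <- length(p$block_maf)
  G <- matrix(0L, n, n_blocks * L)
  for (b in seq_len(n_blocks)) {
    cols <- ((b - 1L) * L + 1L):(b * L)
    G[, cols] <- .draw_block_dosages(n, L, p$block_rho[b], p$block_thr[b])
  }
  # match the panel's allele orientation (panel columns were flipped to minor)
  flip <- panel$variants$effect_allele != "A"
  if (any(flip)) G[, flip] <- 2L - G[, flip]
  G
}

# per-block empirical correlation matrices of the panel dosages, cached in
# an environment carried by the panel object
.panel_block_cor <- function(panel) {
  cache <- panel$cache
  if (!is.null(cache) && !is.null(cache$block_cor)) return(cache$block_cor)
  bc <- lapply(seq_len(max(panel$block)), function(b) {
    stats::cor(panel$genotypes[, panel$block == b, drop = FALSE])
  })
  if (!is.null(cache)) cache$block_cor <- bc
  bc
}

#' Per-block empirical LD correlation matrices of a panel
#' @param panel a `reference_panel`.
#' @return list of per-block correlation matrices, in block order.
#' @export
panel_block_cor <- function(panel) .panel_block_cor(panel)
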