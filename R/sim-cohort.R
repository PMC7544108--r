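# Synthetic replication cohort: genotypes drawn from the panel's generating
# population plus per-frequency hearing thresholds whose first principal
# component carries the genetic signal.

#' Generate a target cohort with multi-frequency hearing thresholds
#'
#' New individuals are drawn from the reference panel's generating
#' population. Each individual's true genetic score is the standardized
#' weighted dosage sum under the planted causal effects. Thresholds at
#' each frequency share a common component
#' `z = sqrt(h2_score) g + sqrt(1 - h2_score) u` (with `u` a shared
#' non-genetic factor) plus independent frequency noise:
#' `y_f = z + noise_sd e_f`, so the first principal component of the
#' thresholds captures the genetic signal and the score-explained share of
#' its variance is close to `h2_score`. Missing genotypes, low-MAF
#' variants and Hardy-Weinberg-violating variants can be injected to
#' exercise cohort QC.
#'
#' @param n_individuals cohort size.
#' @param panel the `reference_panel` the discovery GWAS used.
#' @param truth the `simulation_truth` with planted causal effects.
#' @param n_frequencies number of threshold frequencies (>= 2).
#' @param h2_score share of the common component's variance explained by
#'   the genetic score.
#' @param noise_sd SD of the frequency-specific noise (common component
#'   has unit variance).
#' @param miss_rate rate of missing genotype entries.
#' @param n_lowmaf number of variants whose dosages are rarefied below a
#'   5 percent MAF.
#' @param n_hwe_violating number of variants overwritten with a grossly
#'   heterozygote-depleted genotype distribution (exact-test p far below
#'   1e-6).
#' @param seed integer seed.
#' @return list with `genotypes` (matrix, rownames individuals, colnames
#'   variant ids), `target_info` (id/allele data frame), `thresholds`
#'   (individuals x frequencies matrix, dB-like scale), `genetic_score`
#'   (true standardized score), `injected` (ids of low-MAF and HWE
#'   violators).
#' @export
gen_target_cohort <- function(n_individuals, panel, truth,
                              n_frequencies = 3, h2_score = 0.05,
                              noise_sd = 0.3, miss_rate = 0,
                              n_lowmaf = 0, n_hwe_violating = 0, seed = 1) {
  if (n_frequencies < 2)
    stop("need at least 2 frequencies (PCA summary undefined otherwise)")
  stopifnot(inherits(panel, "reference_panel"),
            inherits(truth, "simulation_truth"))
  G <- draw_panel_individuals(panel, n_individuals, seed = seed)
  colnames(G) <- panel$variants$id
  rownames(G) <- sprintf("ind%05d", seq_len(n_individuals))
  set.seed(child_seed(seed, "cohort_phenotype"))

  g_raw <- as.numeric(G %*% truth$causal_effects)
  g <- if (stats::sd(g_raw) > 0) as.numeric(scale(g_raw)) else g_raw
  u <- stats::rnorm(n_individuals)
  z <- sqrt(h2_score) * g + sqrt(1 - h2_score) * u
  thr <- vapply(seq_len(n_frequencies), function(f)
    z + noise_sd * stats::rnorm(n_individuals), numeric(n_individuals))
  thr <- 25 + 10 * thr  # dB-like location/scale
  colnames(thr) <- sprintf("freq%d", seq_len(n_frequencies))

  injected <- list(lowmaf = character(0), hwe = character(0))
  M <- ncol(G)
  if (n_lowmaf > 0) {
    jj <- sample.int(M, n_lowmaf)
    injected$lowmaf <- colnames(G)[jj]
    for (j in jj) {
      x <- integer(n_individuals)
      x[sample.int(n_individuals, max(1, round(0.02 * n_individuals)))] <- 1L
      G[, j] <- x
    }
  }
  if (n_hwe_violating > 0) {
    jj <- sample(setdiff(seq_len(M), match(injected$lowmaf, colnames(G))),
                 n_hwe_violating)
    injected$hwe <- colnames(G)[jj]
    for (j in jj) {
      # all homozygotes at intermediate frequency: maximal het deficit
      G[, j] <- 2L * stats::rbinom(n_individuals, 1, 0.5)
    }
  }
  if (miss_rate > 0) {
    nm <- round(miss_rate * length(G))
    G[sample.int(length(G), nm)] <- NA_integer_
  }
  list(genotypes = G,
       target_info = panel$variants[, c("id", "effect_allele",
                                        "other_allele", "chrom", "pos")],
       thresholds = thr, genetic_score = g, injected = injected)
}
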