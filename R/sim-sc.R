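# Synthetic droplet scRNA-seq counts: negative-binomial UMIs with
# cell-type-structured marker fold changes, a mitochondrial gene subset
# contributing a target UMI share, and planted QC violators.

#' Generate synthetic single-cell UMI counts with known cell types
#'
#' Counts are negative binomial with gene base rates drawn from a gamma
#' distribution; marker genes have their rate multiplied by the requested
#' fold change in their cell type. A `mito_n`-gene subset named `mt-*`
#' contributes approximately `mito_fraction` of each normal cell's UMIs.
#' A fraction of cells is planted as QC violators (depth far below /
#' above the filter bounds, or mitochondrial share far above it) to
#' exercise the filter.
#'
#' @param celltype_sizes named vector: cells per cell type.
#' @param n_genes gene count (excluding the mitochondrial genes).
#' @param marker_spec named list per cell type: list(genes = indices into
#'   the gene universe, fold = fold change). A gene may only be a marker of
#'   one type (contradictory assignments are an error).
#' @param depth_mean expected UMIs per normal cell (must be positive).
#' @param dispersion NB size parameter (smaller = noisier).
#' @param mito_fraction target mitochondrial UMI share of normal cells.
#' @param mito_n number of mitochondrial genes.
#' @param violator_frac fraction of cells planted as QC violators.
#' @param seed integer seed.
#' @return list with `sc` (an [sc_counts()]), `truth` (data frame:
#'   barcode, celltype, qc_violation in {none, low_umi, high_umi,
#'   high_mito}), `marker_spec`.
#' @export
gen_sc_counts <- function(celltype_sizes, n_genes = 800, marker_spec = list(),
                          depth_mean = 2000, dispersion = 2,
                          mito_fraction = 0.05, mito_n = 10,
                          violator_frac = 0.05, seed = 1) {
  if (depth_mean <= 0) stop("depth_mean must be positive")
  if (mito_fraction < 0 || mito_fraction >= 1)
    stop("mito_fraction must be in [0, 1)")
  types <- names(celltype_sizes)
  if (is.null(types)) stop("celltype_sizes must be named")
  seen <- character(0)
  for (tt in names(marker_spec)) {
    for (g in as.character(marker_spec[[tt]]$genes)) {
      if (!is.na(seen[g]) && seen[g] != tt)
        stop("contradictory marker assignment: gene ", g,
             " is a marker of two cell types")
      seen[g] <- tt
    }
  }
  set.seed(seed)
  n_cells <- sum(celltype_sizes)
  celltype <- rep(types, celltype_sizes)

  base_rate <- stats::rgamma(n_genes, shape = 0.6, rate = 1)
  base_rate <- base_rate / sum(base_rate) * (1 - mito_fraction)
  mito_rate <- rep(mito_fraction / mito_n, mito_n)

  # per-type expected gene shares with marker folds applied, renormalized
  rate_by_type <- vapply(types, function(tt) {
    r <- base_rate
    ms <- marker_spec[[tt]]
    if (!is.null(ms)) r[ms$genes] <- r[ms$genes] * ms$fold
    r / sum(r) * (1 - mito_fraction)
  }, numeric(n_genes))

  depth <- stats::rlnorm(n_cells, log(depth_mean), 0.25)
  mito_target <- rep(mito_fraction, n_cells)
  viol <- rep("none", n_cells)
  n_viol <- round(violator_frac * n_cells)
  if (n_viol > 0) {
    idx <- sample.int(n_cells, n_viol)
    kind <- sample(c("low_umi", "high_umi", "high_mito"), n_viol,
                   replace = TRUE)
    viol[idx] <- kind
    depth[idx[kind == "low_umi"]] <- 20
    depth[idx[kind == "high_umi"]] <- 30000
    mito_target[idx[kind == "high_mito"]] <- 0.5
  }

  counts <- matrix(0L, n_genes + mito_n, n_cells)
  tt_idx <- match(celltype, types)
  for (i in seq_len(n_cells)) {
    mr <- mito_target[i]
    r <- c(rate_by_type[, tt_idx[i]] / (1 - mito_fraction) * (1 - mr),
           mito_rate / mito_fraction * mr)
    counts[, i] <- stats::rnbinom(n_genes + mito_n, mu = depth[i] * r,
                                  size = dispersion)
  }
  rownames(counts) <- c(sprintf("g%04d", seq_len(n_genes)),
                        sprintf("mt-%d", seq_len(mito_n)))
  colnames(counts) <- sprintf("cell%05d", seq_len(n_cells))
  list(sc = sc_counts(counts),
       truth = data.frame(barcode = colnames(counts), celltype = celltype,
                          qc_violation = viol, stringsAsFactors = FALSE),
       marker_spec = marker_spec)
}

#' Generate bulk-style hair-cell expression datasets for meta-analysis
#'
#' Each dataset is a genes x samples matrix of log expression with a
#' hair-cell / other-cell design and an age covariate; listed hair-cell
#' genes get `log(fold)` added in hair-cell samples.
#'
#' @param n_datasets number of datasets.
#' @param genes gene symbols.
#' @param haircell_genes symbols with planted hair-cell enrichment.
#' @param fold planted fold change.
#' @param n_per_group samples per group per dataset.
#' @param noise_sd residual SD of log expression.
#' @param seed integer seed.
#' @return list of datasets in the [haircell_meta()] input format.
#' @export
gen_haircell_datasets <- function(n_datasets = 3, genes,
                                  haircell_genes = character(0), fold = 4,
                                  n_per_group = 10, noise_sd = 1, seed = 1) {
  set.seed(seed)
  lapply(seq_len(n_datasets), function(d) {
    n <- 2 * n_per_group
    hair <- rep(c(TRUE, FALSE), each = n_per_group)
    age <- stats::runif(n, 0, 4)
    mu <- stats::runif(length(genes), 1, 6)
    expr <- matrix(stats::rnorm(length(genes) * n, mu, noise_sd),
                   length(genes), n, dimnames = list(genes, NULL))
    expr <- expr + outer(rep(0.2, length(genes)), age)  # mild age effect
    expr[haircell_genes, hair] <- expr[haircell_genes, hair] + log(fold)
    list(expr = expr, hair = hair, age = age)
  })
}
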