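# Minimal droplet scRNA-seq pipeline: QC, log normalization, variable-gene
# selection (mean.var.plot convention), covariate regression + PCA + SNN
# Louvain clustering, Wilcoxon marker detection, risk-gene specificity, and
# the cross-dataset hair-cell Stouffer meta-analysis.

#' Construct a UMI count container
#'
#' @param counts genes x cells nonnegative integer matrix (dense or
#'   `dgCMatrix`), with gene symbols as rownames and barcodes as colnames.
#' @param mito_genes character vector of mitochondrial gene symbols;
#'   defaults to symbols starting with `mt-` (case-insensitive).
#' @return object of class `sc_counts`.
#' @export
sc_counts <- function(counts, mito_genes = NULL) {
  counts <- if (methods::is(counts, "sparseMatrix"))
    methods::as(counts, "CsparseMatrix")
  else Matrix::Matrix(as.matrix(counts) * 1.0, sparse = TRUE)
  if (any(counts@x < 0)) stop("counts must be nonnegative")
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("g%04d", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- sprintf("cell%05d", seq_len(ncol(counts)))
  if (is.null(mito_genes))
    mito_genes <- grep("^mt-", rownames(counts), ignore.case = TRUE,
                       value = TRUE)
  structure(list(counts = counts, mito_genes = mito_genes),
            class = "sc_counts")
}

#' @export
print.sc_counts <- function(x, ...) {
  cat(sprintf("sc_counts: %d genes x %d cells (%d mitochondrial genes)\n",
              nrow(x$counts), ncol(x$counts), length(x$mito_genes)))
  invisible(x)
}

#' Cell quality-control filter
#'
#' Removes cells with total UMIs strictly below `min_umi`, strictly above
#' `max_umi`, or with a mitochondrial UMI fraction strictly above
#' `max_mito`. The filter is idempotent.
#'
#' @param sc an `sc_counts`.
#' @param min_umi,max_umi inclusive UMI bounds for retention.
#' @param max_mito maximum mitochondrial fraction for retention.
#' @return list with `sc` (filtered `sc_counts`) and `report` (removed-cell
#'   counts per reason, plus the retained barcode vector).
#' @export
qc_filter <- function(sc, min_umi = 50, max_umi = 20000, max_mito = 0.20) {
  stopifnot(inherits(sc, "sc_counts"))
  tot <- Matrix::colSums(sc$counts)
  mito <- Matrix::colSums(sc$counts[rownames(sc$counts) %in% sc$mito_genes, ,
                                    drop = FALSE])
  mito_frac <- ifelse(tot > 0, mito / tot, 1)
  low <- tot < min_umi
  high <- tot > max_umi
  mt <- mito_frac > max_mito
  keep <- !(low | high | mt)
  if (!any(keep)) stop("all cells removed by QC")
  list(sc = sc_counts(sc$counts[, keep, drop = FALSE], sc$mito_genes),
       report = list(n_low_umi = sum(low), n_high_umi = sum(high),
                     n_high_mito = sum(mt), n_removed = sum(!keep),
                     n_kept = sum(keep),
                     kept_barcodes = colnames(sc$counts)[keep],
                     total_umi = tot, mito_fraction = mito_frac))
}

#' Library-size normalization and variable-gene selection
#'
#' Per-cell counts are scaled to `scale_factor` total and log1p-transformed.
#' Variable genes follow the mean.var.plot convention: per gene the mean of
#' the de-logged expression (log of mean + 1) and the log variance-to-mean
#' ratio (LogVMR dispersion) are computed; dispersions are z-standardized
#' within `n_bins` bins of the mean; genes are kept iff their mean lies in
#' `[mean_min, mean_max]` and their standardized dispersion is at least
#' `dispersion_cutoff`.
#'
#' @param sc an `sc_counts` (post-QC; zero-count cells are an error).
#' @param scale_factor library-size target.
#' @param mean_min,mean_max cutoffs on the (log-scale) gene mean.
#' @param dispersion_cutoff minimum standardized dispersion.
#' @param n_bins bins for dispersion standardization.
#' @return object of class `sc_norm`: list with `norm` (dense genes x cells
#'   log-normalized matrix), `var_genes`, `gene_stats` (mean, dispersion,
#'   scaled dispersion per gene), `total_umi`, `mito_fraction`.
#' @export
normalize_and_select <- function(sc, scale_factor = 1e4, mean_min = 0.0123,
                                 mean_max = 3, dispersion_cutoff = 0.5,
                                 n_bins = 20) {
  stopifnot(inherits(sc, "sc_counts"))
  tot <- Matrix::colSums(sc$counts)
  if (any(tot == 0)) stop("zero-count cell present; run qc_filter first")
  norm <- as.matrix(sc$counts %*% Matrix::Diagonal(x = scale_factor / tot))
  dimnames(norm) <- dimnames(sc$counts)
  norm <- log1p(norm)
  ex <- expm1(norm)
  mu <- rowMeans(ex)
  v <- apply(ex, 1, stats::var)
  gmean <- log1p(mu)
  disp <- ifelse(mu > 0 & v > 0, log(v / mu), -Inf)
  bins <- cut(gmean, breaks = n_bins)
  zdisp <- rep(NA_real_, length(disp))
  for (b in levels(bins)) {
    ii <- which(bins == b & is.finite(disp))
    if (length(ii) >= 2) {
      s <- stats::sd(disp[ii])
      zdisp[ii] <- if (s > 0) (disp[ii] - mean(disp[ii])) / s else 0
    } else if (length(ii) == 1) zdisp[ii] <- 0
  }
  keep <- !is.na(zdisp) & gmean >= mean_min & gmean <= mean_max &
    zdisp >= dispersion_cutoff
  mito <- Matrix::colSums(sc$counts[rownames(sc$counts) %in% sc$mito_genes, ,
                                    drop = FALSE])
  structure(list(norm = norm, var_genes = rownames(norm)[keep],
                 gene_stats = data.frame(gene = rownames(norm), mean = gmean,
                                         dispersion = disp,
                                         dispersion_scaled = zdisp,
                                         variable = keep,
                                         stringsAsFactors = FALSE),
                 total_umi = tot, mito_fraction = mito / tot),
            class = "sc_norm")
}

#' Score cells by the mean expression of a gene list
#'
#' Used for the cell-cycle covariate: the mean log-normalized expression of
#' the listed genes per cell.
#'
#' @param normobj an `sc_norm`.
#' @param gene_list character vector of gene symbols.
#' @return numeric per-cell score.
#' @export
score_gene_list <- function(normobj, gene_list) {
  gg <- intersect(gene_list, rownames(normobj$norm))
  if (!length(gg)) return(rep(0, ncol(normobj$norm)))
  colMeans(normobj$norm[gg, , drop = FALSE])
}

#' Cluster cells by SNN Louvain community detection
#'
#' Technical covariates are regressed out of the variable-gene expression,
#' genes are z-scaled (clipped at +/-10), cells are embedded in the first
#' `n_components` principal components, a shared-nearest-neighbor graph
#' (Jaccard weights over the `k_neighbors`-NN sets, pruned below 1/15) is
#' built, and communities are found by Louvain modularity optimization at
#' the given resolution. Labels are deterministic given the seed and are
#' relabeled by decreasing cluster size.
#'
#' @param normobj an `sc_norm`.
#' @param covariates optional data frame of per-cell covariates to regress
#'   out (e.g. cell-cycle score, mito fraction, total UMI).
#' @param n_components principal components to keep.
#' @param resolution Louvain resolution parameter.
#' @param k_neighbors nearest neighbors for the SNN graph.
#' @param seed integer seed.
#' @return list with `labels` (factor per cell), `pca` (cell x component
#'   scores), `n_clusters`.
#' @export
cluster_cells <- function(normobj, covariates = NULL, n_components = 10,
                          resolution = 0.6, k_neighbors = 20, seed = 1) {
  stopifnot(inherits(normobj, "sc_norm"))
  X <- normobj$norm[normobj$var_genes, , drop = FALSE]
  n_cells <- ncol(X)
  if (n_cells <= k_neighbors)
    stop("fewer cells than k_neighbors")
  if (!is.null(covariates)) {
    D <- cbind(1, as.matrix(covariates))
    # project out the covariate space from every gene at once
    H <- D %*% solve(crossprod(D), t(D))
    X <- X - X %*% H
  }
  X <- t(scale(t(X)))
  X[is.na(X)] <- 0
  X[X > 10] <- 10; X[X < -10] <- -10
  pc <- stats::prcomp(t(X), rank. = min(n_components, n_cells - 1,
                                        nrow(X)))$x
  d <- as.matrix(stats::dist(pc))
  nn <- t(apply(d, 1, function(r) order(r)[seq_len(k_neighbors)]))
  A <- Matrix::sparseMatrix(i = rep(seq_len(n_cells), k_neighbors),
                            j = as.vector(nn), x = 1,
                            dims = c(n_cells, n_cells))
  shared <- Matrix::tcrossprod(A)
  jac <- shared
  jac@x <- jac@x / (2 * k_neighbors - jac@x)
  jac@x[jac@x < 1 / 15] <- 0
  jac <- Matrix::drop0(jac)
  Matrix::diag(jac) <- 0
  g <- igraph::graph_from_adjacency_matrix(jac, mode = "undirected",
                                           weighted = TRUE)
  set.seed(seed)
  cl <- igraph::cluster_louvain(g, resolution = resolution)
  memb <- igraph::membership(cl)
  sizes <- sort(table(memb), decreasing = TRUE)
  relabel <- stats::setNames(seq_along(sizes), names(sizes))
  labels <- factor(relabel[as.character(memb)],
                   levels = seq_along(sizes))
  names(labels) <- colnames(normobj$norm)
  list(labels = labels, pca = pc, n_clusters = nlevels(labels))
}

# two-sided Wilcoxon rank-sum p from precomputed global ranks of one gene;
# exact (no ties, both groups <= 8) or normal approximation with tie
# correction and continuity correction, matching stats::wilcox.test
.wilcox_p_from_ranks <- function(r, in_idx, ties_term, has_ties) {
  n1 <- length(in_idx)
  n <- length(r)
  n2 <- n - n1
  W <- sum(r[in_idx]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  if (n1 <= 8 && n2 <= 8) {
    if (!has_ties) {
      # symmetric exact distribution: double the observed tail
      p <- if (W > mu) 2 * stats::pwilcox(W - 1, n1, n2, lower.tail = FALSE)
           else 2 * stats::pwilcox(W, n1, n2)
    } else {
      # ties: exact conditional permutation over group assignments
      w_all <- utils::combn(n, n1, function(ii) sum(r[ii])) -
        n1 * (n1 + 1) / 2
      p <- mean(abs(w_all - mu) >= abs(W - mu) - 1e-9)
    }
    return(min(p, 1))
  }
  sigma2 <- n1 * n2 / 12 * ((n + 1) - ties_term / (n * (n - 1)))
  if (sigma2 <= 0) return(1)
  z <- (W - mu - sign(W - mu) * 0.5) / sqrt(sigma2)
  min(2 * stats::pnorm(-abs(z)), 1)
}

#' Wilcoxon marker detection per cluster
#'
#' For every gene and cluster, a two-sided Wilcoxon rank-sum test of the
#' in-cluster cells against all other cells on log-normalized expression;
#' Bonferroni adjustment across genes within each cluster. `pct_in` and
#' `pct_out` are the fractions of cells with nonzero counts inside and
#' outside the cluster; the log fold change is the difference of
#' `log(mean(expm1(x)) + 1)` between groups. Singleton clusters are
#' skipped with a warning.
#'
#' @param normobj an `sc_norm`.
#' @param labels cluster factor from [cluster_cells()].
#' @param genes optional subset of genes to test (default: all).
#' @return data frame of class `marker_table`: `gene`, `cluster`, `p`,
#'   `p_adjusted`, `pct_in`, `pct_out`, `log_fold_change`.
#' @export
find_markers <- function(normobj, labels, genes = NULL) {
  stopifnot(inherits(normobj, "sc_norm"))
  labels <- as.factor(labels)
  if (nlevels(droplevels(labels)) < 2) stop("need at least 2 clusters")
  X <- normobj$norm
  if (!is.null(genes)) X <- X[intersect(genes, rownames(X)), , drop = FALSE]
  G <- nrow(X)
  out <- vector("list", 0)
  # per-gene global ranks are shared across clusters
  ranks <- vector("list", G)
  ties <- numeric(G); has_ties <- logical(G)
  for (g in seq_len(G)) {
    r <- rank(X[g, ])
    ranks[[g]] <- r
    tab <- table(r)
    ties[g] <- sum(tab^3 - tab)
    has_ties[g] <- any(tab > 1)
  }
  ex <- expm1(X)
  for (cl in levels(droplevels(labels))) {
    in_idx <- which(labels == cl)
    if (length(in_idx) < 2) {
      warning("singleton cluster ", cl, " skipped")
      next
    }
    out_idx <- which(labels != cl)
    p <- vapply(seq_len(G), function(g)
      .wilcox_p_from_ranks(ranks[[g]], in_idx, ties[g], has_ties[g]),
      numeric(1))
    pct_in <- Matrix::rowMeans(X[, in_idx, drop = FALSE] > 0)
    pct_out <- Matrix::rowMeans(X[, out_idx, drop = FALSE] > 0)
    lfc <- log(rowMeans(ex[, in_idx, drop = FALSE]) + 1) -
      log(rowMeans(ex[, out_idx, drop = FALSE]) + 1)
    out[[length(out) + 1]] <- data.frame(
      gene = rownames(X), cluster = cl, p = p,
      p_adjusted = pmin(p * G, 1), pct_in = unname(pct_in),
      pct_out = unname(pct_out), log_fold_change = unname(lfc),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("marker_table", "data.frame")
  res
}

#' Cell-type specificity of risk genes
#'
#' For each risk gene present in the marker table, clusters are ranked by
#' marker evidence: positive-fold clusters first, then by p-value, then by
#' decreasing log fold change, then by cluster label (deterministic
#' tie-break); the top `top_k` are reported. Genes absent from the matrix
#' or never detected above `min_pct` of cells in any cluster are reported
#' as not expressed.
#'
#' @param markers a `marker_table`.
#' @param risk_genes character vector of gene symbols.
#' @param top_k clusters to report per gene.
#' @param min_pct detection floor on `pct_in`.
#' @return data frame: `gene`, `expressed`, `top_clusters` (comma-joined),
#'   `top_p` (best p).
#' @export
risk_gene_specificity <- function(markers, risk_genes, top_k = 3,
                                  min_pct = 0.05) {
  out <- lapply(risk_genes, function(g) {
    m <- markers[markers$gene == g, , drop = FALSE]
    if (!nrow(m) || max(m$pct_in) < min_pct)
      return(data.frame(gene = g, expressed = FALSE, top_clusters = "",
                        top_p = NA_real_, stringsAsFactors = FALSE))
    m <- m[order(m$log_fold_change <= 0, m$p, -m$log_fold_change,
                 m$cluster), , drop = FALSE]
    sel <- utils::head(m, top_k)
    data.frame(gene = g, expressed = TRUE,
               top_clusters = paste(sel$cluster, collapse = ","),
               top_p = sel$p[1], stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Hair-cell meta-analysis across expression datasets
#'
#' Per dataset, each gene's log expression is fit by a linear model on the
#' hair-cell indicator with an age covariate (moderated statistics via
#' limma), giving a signed z toward higher expression in hair cells. The
#' combined statistic is Stouffer's equal-weight `Z = sum(z_i) / sqrt(k)`
#' over the datasets containing the gene, with a one-sided p and
#' Benjamini-Hochberg FDR across genes.
#'
#' @param datasets list of lists with elements `expr` (genes x samples log
#'   expression matrix), `hair` (logical per sample), `age` (numeric per
#'   sample).
#' @param genes character vector of genes to combine.
#' @param fdr FDR threshold for the selective-expression flag.
#' @return data frame: `gene`, `k` (datasets used), `z_combined`, `p`
#'   (one-sided), `fdr`, `flagged`, plus per-dataset z columns.
#' @export
haircell_meta <- function(datasets, genes, fdr = 0.1) {
  if (length(datasets) < 2) stop("need at least 2 datasets")
  zmat <- matrix(NA_real_, length(genes), length(datasets),
                 dimnames = list(genes, paste0("z_dataset", seq_along(datasets))))
  for (d in seq_along(datasets)) {
    ds <- datasets[[d]]
    gg <- intersect(genes, rownames(ds$expr))
    if (!length(gg)) next
    design <- stats::model.matrix(~hair + age,
                                  data.frame(hair = as.numeric(ds$hair),
                                             age = ds$age))
    fit <- limma::eBayes(limma::lmFit(ds$expr[gg, , drop = FALSE], design))
    t_stat <- fit$t[, "hair"]
    zmat[gg, d] <- limma::zscoreT(t_stat, df = fit$df.total)
  }
  k <- rowSums(!is.na(zmat))
  if (any(k == 0))
    warning(sum(k == 0), " gene(s) missing from every dataset")
  z_comb <- unname(ifelse(k > 0,
                          rowSums(zmat, na.rm = TRUE) / sqrt(pmax(k, 1)),
                          NA_real_))
  p <- stats::pnorm(z_comb, lower.tail = FALSE)
  q <- stats::p.adjust(p, method = "BH")
  out <- data.frame(gene = genes, k = k, z_combined = z_comb, p = p,
                    fdr = q, flagged = !is.na(q) & q < fdr,
                    stringsAsFactors = FALSE)
  cbind(out, as.data.frame(zmat, row.names = NULL))
}
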