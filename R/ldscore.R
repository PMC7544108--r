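# Per-category LD scores from a reference panel.

#' Compute per-variant, per-category LD scores
#'
#' For each variant j and annotation category c, the LD score is
#' `l_jc = sum_k adj_r2(j, k) * a_kc` over panel variants k within
#' `window_bp` of j on the same chromosome, where `adj_r2` is the unbiased
#' estimator `r2_hat - (1 - r2_hat) / (n - 2)` of the squared genotype
#' correlation (the self pair contributes exactly 1).
#'
#' @param panel a `reference_panel`.
#' @param annotations optional `annotation_matrix` aligned to the panel;
#'   defaults to the base category only.
#' @param window_bp half-width of the LD window in base pairs.
#' @param chunk_size variants per computation chunk (memory/speed knob).
#' @return object of class `ldscore_table`: list with `id`, `scores`
#'   (variants x categories matrix), `categories`, `m_c`.
#' @export
compute_ld_scores <- function(panel, annotations = NULL, window_bp = 1e6,
                              chunk_size = 500L) {
  stopifnot(inherits(panel, "reference_panel"))
  if (is.null(annotations)) annotations <- make_annotations(panel)
  memb <- annotations$membership
  M <- nrow(panel$variants)
  if (nrow(memb) != M) stop("annotations not aligned to panel")
  n <- panel$individuals
  if (n < 3) stop("panel too small for the unbiased r2 estimator")
  span <- max(diff(range(panel$variants$pos[panel$block == panel$block[1]])), 0)
  if (window_bp < span)
    warning("LD window smaller than the panel's block span; scores truncated")

  X <- scale(panel$genotypes)  # n x M standardized dosages
  pos <- panel$variants$pos
  chrom <- panel$variants$chrom
  scores <- matrix(0, M, ncol(memb), dimnames = list(NULL, colnames(memb)))
  storage.mode(memb) <- "double"

  start <- 1L
  while (start <= M) {
    end <- min(start + chunk_size - 1L, M)
    jj <- start:end
    # neighbor superset: chunk chromosomes, positions within the chunk's
    # window (the exact per-pair mask is applied below)
    nb <- which(chrom %in% unique(chrom[jj]) &
                pos >= min(pos[jj]) - window_bp & pos <= max(pos[jj]) + window_bp)
    r <- crossprod(X[, jj, drop = FALSE], X[, nb, drop = FALSE]) / (n - 1)
    r2 <- r^2
    adj <- r2 - (1 - r2) / (n - 2)
    # zero out pairs outside the per-variant window or on another chromosome
    keep <- abs(outer(pos[jj], pos[nb], "-")) <= window_bp &
      outer(chrom[jj], chrom[nb], "==")
    adj[!keep] <- 0
    # the self pair has r2_hat = 1 exactly -> adjustment 0, contributes 1
    scores[jj, ] <- adj %*% memb[nb, , drop = FALSE]
    start <- end + 1L
  }
  structure(list(id = panel$variants$id, scores = scores,
                 categories = colnames(memb), m_c = annotations$m_c),
            class = "ldscore_table")
}

#' @export
print.ldscore_table <- function(x, ...) {
  cat(sprintf("ldscore_table: %d variants x %d categories (mean base l = %.2f)\n",
              length(x$id), ncol(x$scores), mean(x$scores[, 1])))
  invisible(x)
}
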