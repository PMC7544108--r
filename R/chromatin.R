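# ATAC interval operations: replicate merging, blacklist subtraction,
# GAT-style workspace permutation enrichment, and chromatin-state fold
# enrichment. Peak sets are GRanges (1-based, closed); BED I/O converts.

.as_granges_peaks <- function(x) {
  if (methods::is(x, "GRanges")) return(x)
  GenomicRanges::GRanges(x$chrom, IRanges::IRanges(x$start, x$end))
}

#' Reproducible peaks: replicate intersection
#'
#' Returns the portions of `rep1` that overlap `rep2` by at least one base
#' (bedtools-intersect semantics on merged inputs).
#'
#' @param rep1,rep2 `GRanges` peak sets on the same assembly.
#' @return `GRanges` of reproducible peak portions.
#' @export
merge_replicate_peaks <- function(rep1, rep2) {
  GenomicRanges::intersect(GenomicRanges::reduce(rep1),
                           GenomicRanges::reduce(rep2),
                           ignore.strand = TRUE)
}

#' Remove peaks overlapping a blacklist
#'
#' Any peak overlapping a blacklist interval by at least one base is removed
#' entirely (whole-peak removal, not trimming).
#'
#' @param peaks,blacklist `GRanges`.
#' @return filtered `GRanges`.
#' @export
subtract_blacklist <- function(peaks, blacklist) {
  if (!length(blacklist)) return(peaks)
  peaks[!IRanges::overlapsAny(peaks, blacklist, ignore.strand = TRUE)]
}

# cumulative-coverage lookup for fast overlap of many placed intervals with
# a fixed reduced interval set: cov(x) = reference bases in [1, x)
.coverage_fun <- function(gr) {
  gr <- GenomicRanges::reduce(gr)
  by_chrom <- split(gr, as.character(GenomicRanges::seqnames(gr)))
  lapply(by_chrom, function(g) {
    s <- GenomicRanges::start(g); e <- GenomicRanges::end(g) + 1  # half-open
    o <- order(s)
    s <- s[o]; e <- e[o]
    list(s = s, e = e, cum = c(0, cumsum(e - s)))
  })
}

.coverage_at <- function(cf, chrom, x) {
  out <- numeric(length(x))
  for (cc in unique(chrom)) {
    ii <- chrom == cc
    f <- cf[[cc]]
    if (is.null(f)) next
    j <- findInterval(x[ii], f$s)
    v <- numeric(sum(ii))
    nz <- j > 0
    v[nz] <- f$cum[j[nz] + 1] - pmax(0, f$e[j[nz]] - x[ii][nz])
    out[ii] <- v
  }
  out
}

#' Permutation test of interval overlap within a workspace
#'
#' The observed statistic is the number of bases (or, with
#' `mode = "count"`, the number of query intervals) overlapping the
#' reference. The null distribution places each query interval, with its
#' length preserved, uniformly at random within the workspace (independent
#' placements, following the nucleotide-overlap statistic of GAT-style
#' samplers). Fold is observed over the null mean; the empirical p-value is
#' `(1 + #{null >= observed}) / (n_permutations + 1)`.
#'
#' @param query,reference,workspace `GRanges`; the query must lie within
#'   the workspace.
#' @param n_permutations number of placements.
#' @param seed integer seed.
#' @param mode `"bases"` (default) or `"count"`.
#' @return list with `fold`, `p`, `observed`, `null_mean`, `null_sd`.
#' @export
permutation_enrichment <- function(query, reference, workspace,
                                   n_permutations = 10000, seed = 1,
                                   mode = c("bases", "count")) {
  mode <- match.arg(mode)
  ws <- GenomicRanges::reduce(workspace)
  outside <- GenomicRanges::setdiff(GenomicRanges::reduce(query), ws,
                                    ignore.strand = TRUE)
  if (sum(GenomicRanges::width(outside)) > 0)
    stop("query must lie within the workspace")
  qw <- GenomicRanges::width(query)
  wsw <- GenomicRanges::width(ws)
  if (sum(wsw) < sum(qw))
    stop("workspace smaller than the total query length")
  if (any(max(qw) > max(wsw)))
    stop("a query interval is longer than every workspace interval")
  ov <- GenomicRanges::intersect(GenomicRanges::reduce(query),
                                 GenomicRanges::reduce(reference),
                                 ignore.strand = TRUE)
  observed <- if (mode == "bases") sum(GenomicRanges::width(ov)) else
    sum(IRanges::overlapsAny(query, reference, ignore.strand = TRUE))

  cf <- .coverage_fun(reference)
  ws_chrom <- as.character(GenomicRanges::seqnames(ws))
  ws_start <- GenomicRanges::start(ws)
  set.seed(seed)
  nq <- length(qw)
  # valid start counts per (workspace tile, query interval): width - L + 1;
  # all permutations of one interval are drawn in a single vectorized pass
  valid <- pmax(outer(wsw, qw, function(w, l) w - l + 1), 0)
  ov_mat <- matrix(0, n_permutations, nq)
  for (i in seq_len(nq)) {
    tile <- sample.int(length(wsw), n_permutations, replace = TRUE,
                       prob = valid[, i])
    off <- floor(stats::runif(n_permutations) * valid[cbind(tile, i)])
    s <- ws_start[tile] + off              # 1-based start
    e <- s + qw[i]                         # half-open end
    ov_mat[, i] <- .coverage_at(cf, ws_chrom[tile], e) -
      .coverage_at(cf, ws_chrom[tile], s)
  }
  null <- if (mode == "bases") rowSums(ov_mat) else rowSums(ov_mat > 0)
  nm <- mean(null)
  list(fold = if (nm > 0) observed / nm else NA_real_,
       p = (1 + sum(null >= observed)) / (n_permutations + 1),
       observed = observed, null_mean = nm, null_sd = stats::sd(null))
}

#' Chromatin-state fold enrichment of a peak set
#'
#' For each state s, fold = (fraction of query bases in s) / (fraction of
#' the workspace in s); the workspace is the segmentation's span. The SE is
#' the across-chromosome standard error of the per-chromosome folds. States
#' absent from the workspace get NA fold (flagged).
#'
#' @param query `GRanges`.
#' @param segmentation `GRanges` with a `name` metadata column of state
#'   labels, partitioning the workspace.
#' @return data frame: `state`, `fold`, `se`, `query_bases`, `state_bases`.
#' @export
state_enrichment <- function(query, segmentation) {
  states <- sort(unique(segmentation$name))
  qr <- GenomicRanges::reduce(query)
  chroms <- unique(as.character(GenomicRanges::seqnames(segmentation)))
  per_chrom <- function(cc) {
    seg <- segmentation[as.character(GenomicRanges::seqnames(segmentation)) == cc]
    q <- qr[as.character(GenomicRanges::seqnames(qr)) == cc]
    W <- sum(GenomicRanges::width(seg))
    Q <- sum(GenomicRanges::width(GenomicRanges::intersect(
      q, GenomicRanges::reduce(seg), ignore.strand = TRUE)))
    vapply(states, function(ss) {
      sgr <- GenomicRanges::reduce(seg[seg$name == ss])
      ws <- sum(GenomicRanges::width(sgr))
      if (ws == 0 || Q == 0) return(NA_real_)
      qs <- sum(GenomicRanges::width(GenomicRanges::intersect(
        q, sgr, ignore.strand = TRUE)))
      (qs / Q) / (ws / W)
    }, numeric(1))
  }
  fold_mat <- vapply(chroms, per_chrom, numeric(length(states)))
  fold_mat <- matrix(fold_mat, nrow = length(states),
                     dimnames = list(states, chroms))
  # genome-wide fold and across-chromosome SE
  W <- sum(GenomicRanges::width(segmentation))
  Q <- sum(GenomicRanges::width(GenomicRanges::intersect(
    qr, GenomicRanges::reduce(segmentation), ignore.strand = TRUE)))
  out <- do.call(rbind, lapply(states, function(ss) {
    sgr <- GenomicRanges::reduce(segmentation[segmentation$name == ss])
    ws <- sum(GenomicRanges::width(sgr))
    qs <- sum(GenomicRanges::width(GenomicRanges::intersect(
      qr, sgr, ignore.strand = TRUE)))
    folds <- fold_mat[ss, ]
    folds <- folds[is.finite(folds)]
    data.frame(state = ss,
               fold = if (ws > 0) (qs / Q) / (ws / W) else NA_real_,
               se = if (length(folds) > 1)
                 stats::sd(folds) / sqrt(length(folds)) else NA_real_,
               query_bases = qs, state_bases = ws,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
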