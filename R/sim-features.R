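# Synthetic genome geometry: gene models, replicate ATAC peak sets per cell
# class, blacklist, cross-assembly chain, chromatin loops, enhancers and a
# chromatin-state segmentation, with the interval conventions the real
# inputs use (BED 0-based half-open on disk, GRanges in memory).

.rand_intervals <- function(chrom_lengths, n_per_chrom, width_fun) {
  out <- lapply(names(chrom_lengths), function(cc) {
    n <- n_per_chrom[[cc]]
    if (n == 0) return(NULL)
    w <- pmax(50, round(width_fun(n)))
    s <- floor(stats::runif(n) * pmax(chrom_lengths[[cc]] - w, 1))
    data.frame(chrom = cc, start = s, end = pmin(s + w, chrom_lengths[[cc]]))
  })
  out <- do.call(rbind, out)
  if (is.null(out)) return(GenomicRanges::GRanges())
  gr <- GenomicRanges::GRanges(out$chrom,
                               IRanges::IRanges(out$start + 1, out$end))
  GenomicRanges::sort(gr)
}

#' Generate synthetic genome features
#'
#' Produces, for a toy genome, the annotation inputs the downstream stages
#' consume: gene models with strand-aware TSSs; two jittered replicate ATAC
#' peak sets per cell class sharing at least `share_frac` of their peaks; a
#' blacklist; a cross-assembly chain map covering `chain_coverage` of the
#' source genome in shifted blocks; chromatin loops on a fixed bin grid
#' with log-uniform p-values; an enhancer set; and a chromatin-state
#' segmentation partitioning each chromosome.
#'
#' Two assemblies are emulated: the ATAC peaks, blacklist and enhancers
#' live on a source (mouse-like) assembly whose chromosomes carry the
#' `src_prefix`; the gene models, loops and state segmentation live on the
#' target (GWAS) assembly; the chain maps source to target.
#'
#' @param chrom_lengths named chromosome lengths in bp (shared by the two
#'   assemblies).
#' @param n_genes total gene count.
#' @param peak_density peaks per Mb (expected; Poisson per chromosome).
#' @param loop_density loops per Mb (expected).
#' @param state_labels chromatin-state labels.
#' @param cell_classes labels of the ATAC cell classes.
#' @param share_frac fraction of base peaks shared between replicates.
#' @param chain_coverage fraction of each chromosome covered by chain
#'   blocks.
#' @param bin_size loop bin width.
#' @param src_prefix chromosome-name prefix of the source assembly.
#' @param seed integer seed.
#' @return list with `genes` (data frame), `peaks` (per cell class, lists
#'   with `rep1`, `rep2` `GRanges`), `blacklist`, `chain` (`chain_map`),
#'   `loops` (data frame), `enhancers`, `states` (`GRanges` with `name`).
#' @export
gen_genome_features <- function(chrom_lengths, n_genes = 200,
                                peak_density = 50, loop_density = 1,
                                state_labels = paste0("E", 1:7),
                                cell_classes = c("epithelial",
                                                 "non_epithelial"),
                                share_frac = 0.7, chain_coverage = 0.8,
                                bin_size = 40000, src_prefix = "mm",
                                seed = 1) {
  if (any(chrom_lengths <= 0)) stop("chromosome lengths must be positive")
  set.seed(seed)
  mb <- chrom_lengths / 1e6
  chroms <- names(chrom_lengths)
  src_lengths <- stats::setNames(as.numeric(chrom_lengths),
                                 paste0(src_prefix, chroms))

  # gene models: TSS-anchored bodies, strand-aware
  g_chrom <- sample(chroms, n_genes, replace = TRUE,
                    prob = chrom_lengths / sum(chrom_lengths))
  g_len <- round(stats::runif(n_genes, 5e3, 5e4))
  g_tss <- vapply(seq_len(n_genes), function(i)
    round(stats::runif(1, g_len[i] + 1,
                       chrom_lengths[[g_chrom[i]]] - g_len[i])), numeric(1))
  g_strand <- sample(c("+", "-"), n_genes, replace = TRUE)
  genes <- data.frame(
    gene_id = sprintf("G%04d", seq_len(n_genes)),
    symbol = sprintf("Gene%d", seq_len(n_genes)),
    chrom = g_chrom,
    start = ifelse(g_strand == "+", g_tss, g_tss - g_len + 1),
    end = ifelse(g_strand == "+", g_tss + g_len - 1, g_tss),
    strand = g_strand, tss = g_tss, stringsAsFactors = FALSE)
  genes <- genes[order(genes$chrom, genes$start), , drop = FALSE]
  rownames(genes) <- NULL

  jitter_gr <- function(gr, sd = 30) {
    if (!length(gr)) return(gr)
    s <- pmax(1, GenomicRanges::start(gr) + round(stats::rnorm(length(gr), 0, sd)))
    e <- pmax(s + 50, GenomicRanges::end(gr) + round(stats::rnorm(length(gr), 0, sd)))
    GenomicRanges::sort(GenomicRanges::GRanges(
      GenomicRanges::seqnames(gr), IRanges::IRanges(s, e)))
  }
  peak_widths <- function(n) stats::rlnorm(n, log(400), 0.4)
  peaks <- lapply(cell_classes, function(cc) {
    n_per <- stats::setNames(stats::rpois(length(chroms), peak_density * mb),
                             chroms)
    if (sum(n_per) == 0) {
      warning("peak density yields zero peaks for cell class ", cc)
      return(list(rep1 = GenomicRanges::GRanges(),
                  rep2 = GenomicRanges::GRanges()))
    }
    base <- .rand_intervals(src_lengths, as.list(
      stats::setNames(n_per, names(src_lengths))), peak_widths)
    shared <- sort(sample(length(base), round(share_frac * length(base))))
    extra_n <- stats::setNames(as.list(
      stats::rpois(length(chroms), (1 - share_frac) * peak_density * mb)),
      chroms)
    mk_rep <- function() {
      ex <- .rand_intervals(src_lengths, stats::setNames(
        extra_n, names(src_lengths)), peak_widths)
      GenomicRanges::sort(c(jitter_gr(base[shared]), ex))
    }
    list(rep1 = mk_rep(), rep2 = mk_rep())
  })
  names(peaks) <- cell_classes

  blacklist <- .rand_intervals(
    src_lengths, stats::setNames(as.list(pmax(1, round(0.2 * mb))),
                                 names(src_lengths)),
    function(n) stats::runif(n, 1e3, 1e4))

  # chain: per chromosome, alternating mapped blocks and gaps; one chain per
  # ~1 Mb span with its own target offset
  blocks <- NULL; cid <- 0L
  for (cc in chroms) {
    pos <- 0
    while (pos < chrom_lengths[[cc]] * 0.98) {
      cid <- cid + 1L
      span <- min(round(stats::runif(1, 5e5, 1.5e6)),
                  chrom_lengths[[cc]] - pos)
      offset <- round(stats::rnorm(1, 0, 2e5))
      t_pos <- pos; q_pos <- max(pos + offset, 0)
      score <- round(stats::runif(1, 1e3, 1e6))
      chain_end <- pos + span
      while (t_pos < chain_end) {
        blen <- min(round(stats::runif(1, 2e3, 3e4)), chain_end - t_pos)
        if (stats::runif(1) < chain_coverage) {
          blocks <- rbind(blocks, data.frame(
            chain_id = cid, score = score,
            src_chrom = paste0(src_prefix, cc),
            src_start = t_pos, src_end = t_pos + blen,
            tgt_chrom = cc, tgt_start = q_pos,
            tgt_end = q_pos + blen))
          q_pos <- q_pos + blen
        }
        gap <- round(stats::runif(1, 0, 2e3))
        t_pos <- t_pos + blen + gap
        q_pos <- q_pos + gap
      }
      pos <- chain_end + round(stats::runif(1, 0, 5e4))
    }
  }
  tgt_sizes <- stats::setNames(as.numeric(chrom_lengths) * 2, chroms)
  chain <- chain_map(blocks, src_lengths * 2, tgt_sizes)

  # loops: inter-bin pairs on the bin grid, log-uniform p-values
  loops <- do.call(rbind, lapply(chroms, function(cc) {
    n <- stats::rpois(1, loop_density * mb[[cc]])
    if (n == 0) return(NULL)
    nbin <- floor(chrom_lengths[[cc]] / bin_size)
    if (nbin < 3) return(NULL)
    a <- sample.int(nbin - 2, n, replace = TRUE) - 1L
    d <- 1L + stats::rgeom(n, 0.15)
    b <- pmin(a + d, nbin - 1L)
    data.frame(chrom_a = cc, start_a = a * bin_size,
               chrom_b = cc, start_b = b * bin_size,
               bin_size = bin_size, p = 10^-stats::runif(n, 0, 40),
               stringsAsFactors = FALSE)
  }))
  if (is.null(loops)) {
    warning("loop density yields zero loops")
    loops <- data.frame(chrom_a = character(0), start_a = numeric(0),
                        chrom_b = character(0), start_b = numeric(0),
                        bin_size = numeric(0), p = numeric(0))
  }

  # enhancers: half placed inside first-cell-class peaks (so open
  # chromatin is genuinely enriched for them), half background
  enhancers <- .rand_intervals(
    src_lengths, stats::setNames(as.list(pmax(1, round(1 * mb))),
                                 names(src_lengths)),
    function(n) stats::runif(n, 500, 3000))
  pk1 <- peaks[[1]]$rep1
  if (length(pk1)) {
    take <- sample(length(pk1), min(length(pk1), max(1, round(sum(mb)))))
    inside <- GenomicRanges::resize(pk1[take],
                                    width = pmax(200, GenomicRanges::width(
                                      pk1[take]) - 100),
                                    fix = "center")
    enhancers <- GenomicRanges::sort(c(enhancers, inside))
  }

  # states: partition each chromosome into labeled segments
  state_df <- do.call(rbind, lapply(chroms, function(cc) {
    bp <- sort(unique(c(0, round(stats::runif(
      max(3, round(mb[[cc]] * 20)), 1, chrom_lengths[[cc]] - 1)),
      chrom_lengths[[cc]])))
    data.frame(chrom = cc, start = bp[-length(bp)] + 1, end = bp[-1],
               name = sample(state_labels, length(bp) - 1, replace = TRUE),
               stringsAsFactors = FALSE)
  }))
  states <- GenomicRanges::GRanges(state_df$chrom,
                                   IRanges::IRanges(state_df$start,
                                                    state_df$end),
                                   name = state_df$name)

  list(genes = genes, peaks = peaks, blacklist = blacklist, chain = chain,
       loops = loops, enhancers = enhancers, states = states,
       chrom_lengths = chrom_lengths, src_lengths = src_lengths,
       seed = seed)
}
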