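# Functional fine-mapping of candidate SNPs: coding-consequence filtering,
# open-chromatin regulatory tagging, proximal (TSS distance) and distal
# (chromatin loop) target-gene assignment, and the three-tier per-locus
# prioritization rule.

.coding_consequences <- c("missense", "stopgain", "frameshift",
                          "nonframeshift_indel", "splice_donor",
                          "splice_acceptor")

#' Deleterious protein-coding candidate variants
#'
#' Keeps candidates whose annotated consequence is protein-altering
#' (missense, stopgain, frameshift, non-frameshift indel, splice donor or
#' acceptor) and whose CADD Phred score is at least `cadd_min`. Candidates
#' absent from the effect table default to noncoding (fine-mapping sets
#' routinely include unannotated tag SNPs).
#'
#' @param candidates candidate data frame from [expand_candidates()].
#' @param effects data frame with columns `id`, `consequence`, `gene_id`,
#'   `cadd_phred` (and optionally `aa_change`).
#' @param cadd_min minimum CADD Phred score.
#' @return data frame of retained coding hits: `id`, `locus_id`, `gene_id`,
#'   `consequence`, `cadd_phred` (plus `aa_change` if present).
#' @export
classify_coding <- function(candidates, effects, cadd_min = 10) {
  m <- match(candidates$id, effects$id)
  cons <- ifelse(is.na(m), "noncoding", effects$consequence[m])
  cadd <- ifelse(is.na(m), 0, effects$cadd_phred[m])
  keep <- cons %in% .coding_consequences & cadd >= cadd_min
  out <- data.frame(id = candidates$id[keep],
                    locus_id = candidates$locus_id[keep],
                    gene_id = effects$gene_id[m[keep]],
                    consequence = cons[keep], cadd_phred = cadd[keep],
                    stringsAsFactors = FALSE)
  if ("aa_change" %in% names(effects))
    out$aa_change <- effects$aa_change[m[keep]]
  out[order(out$locus_id, out$id), , drop = FALSE]
}

#' Candidates with regulatory potential (open-chromatin overlap)
#'
#' A candidate is retained iff its position lies within
#' `[start - flank_bp, end + flank_bp)` (0-based half-open; both boundaries
#' inclusive on the left, so a SNP exactly `flank_bp` bases left of a region
#' start is retained) of any homologous open chromatin region. The matching
#' regions' cell classes are recorded.
#'
#' @param candidates candidate data frame (columns `id`, `locus_id`,
#'   `chrom`, `pos`).
#' @param homologous_ocr `GRanges` of open chromatin on the GWAS assembly,
#'   with an optional `cell_class` metadata column.
#' @param flank_bp flank in bp around each region.
#' @return the retained candidate rows with an added `cell_class` column
#'   (comma-joined over matching regions).
#' @export
regulatory_candidates <- function(candidates, homologous_ocr, flank_bp = 500) {
  if (!nrow(candidates) || !length(homologous_ocr))
    return(cbind(candidates[0, , drop = FALSE], cell_class = character(0)))
  # 0-based arithmetic: pos0 in [start0 - flank, end0 + flank)
  s0 <- GenomicRanges::start(homologous_ocr) - 1
  e0 <- GenomicRanges::end(homologous_ocr)
  ocr_gr <- GenomicRanges::GRanges(
    as.character(GenomicRanges::seqnames(homologous_ocr)),
    IRanges::IRanges(start = s0 - flank_bp + 1, end = e0 + flank_bp))
  snp_gr <- GenomicRanges::GRanges(candidates$chrom,
                                   IRanges::IRanges(candidates$pos,
                                                    candidates$pos))
  hits <- GenomicRanges::findOverlaps(snp_gr, ocr_gr, ignore.strand = TRUE)
  qh <- S4Vectors::queryHits(hits)
  if (!length(qh))
    return(cbind(candidates[0, , drop = FALSE], cell_class = character(0)))
  cls <- if (!is.null(homologous_ocr$cell_class))
    homologous_ocr$cell_class[S4Vectors::subjectHits(hits)] else
      rep("ocr", length(qh))
  agg <- tapply(cls, qh, function(x) paste(sort(unique(x)), collapse = ","))
  idx <- as.integer(names(agg))
  out <- candidates[idx, , drop = FALSE]
  out$cell_class <- as.character(agg)
  rownames(out) <- NULL
  out
}

#' Proximal target genes by TSS distance
#'
#' Every gene whose transcription start site lies within
#' `max_tss_distance` bp (inclusive) of a regulatory SNP is a proximal
#' target of that SNP.
#'
#' @param reg_snps regulatory candidates (columns `id`, `locus_id`,
#'   `chrom`, `pos`).
#' @param genes gene-model data frame with `gene_id`, `chrom`, `tss`.
#' @param max_tss_distance distance cutoff in bp.
#' @return data frame: `id`, `locus_id`, `gene_id`, `tss_distance`.
#' @export
assign_proximal <- function(reg_snps, genes, max_tss_distance = 20000) {
  if (!nrow(reg_snps))
    return(data.frame(id = character(0), locus_id = integer(0),
                      gene_id = character(0), tss_distance = numeric(0)))
  out <- lapply(seq_len(nrow(reg_snps)), function(i) {
    d <- abs(genes$tss - reg_snps$pos[i])
    sel <- which(genes$chrom == reg_snps$chrom[i] & d <= max_tss_distance)
    if (!length(sel)) return(NULL)
    data.frame(id = reg_snps$id[i], locus_id = reg_snps$locus_id[i],
               gene_id = genes$gene_id[sel], tss_distance = d[sel],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    return(data.frame(id = character(0), locus_id = integer(0),
                      gene_id = character(0), tss_distance = numeric(0)))
  rownames(out) <- NULL
  out
}

#' Distal target genes through chromatin loops
#'
#' The genome is tiled in `bin_size` bins (`bin = floor(pos0 / bin_size)`
#' on 0-based positions). Loops connecting the same bin pair in several
#' tissues are collapsed to their minimum p-value; loops with
#' `p < loop_p_max` touching a SNP's bin make every gene whose TSS falls in
#' the partner bin a distal target. Same-bin SNP-TSS pairs are never distal
#' calls (loops are strictly inter-bin; proximity handles them).
#'
#' @param reg_snps regulatory candidates (columns `id`, `locus_id`,
#'   `chrom`, `pos`).
#' @param loops data frame: `chrom_a`, `start_a`, `chrom_b`, `start_b`
#'   (0-based bin starts), `bin_size`, `p`.
#' @param genes gene-model data frame with `gene_id`, `chrom`, `tss`.
#' @param loop_p_max strict p-value threshold for loop significance.
#' @param bin_size bin width in bp.
#' @return data frame: `id`, `locus_id`, `gene_id`, `loop_p`.
#' @export
assign_distal <- function(reg_snps, loops, genes, loop_p_max = 1e-25,
                          bin_size = 40000) {
  empty <- data.frame(id = character(0), locus_id = integer(0),
                      gene_id = character(0), loop_p = numeric(0))
  if (!nrow(reg_snps) || !nrow(loops)) return(empty)
  lp <- loops
  # collapse multi-tissue duplicates of a bin pair to the minimum p
  key <- paste(lp$chrom_a, lp$start_a, lp$chrom_b, lp$start_b)
  minp <- tapply(lp$p, key, min)
  lp <- lp[!duplicated(key), , drop = FALSE]
  lp$p <- as.numeric(minp[paste(lp$chrom_a, lp$start_a,
                                lp$chrom_b, lp$start_b)])
  lp <- lp[lp$p < loop_p_max, , drop = FALSE]
  lp <- lp[!(lp$chrom_a == lp$chrom_b & lp$start_a == lp$start_b), ,
           drop = FALSE]
  if (!nrow(lp)) return(empty)
  gene_bin <- floor((genes$tss - 1) / bin_size) * bin_size
  snp_bin <- floor((reg_snps$pos - 1) / bin_size) * bin_size
  out <- lapply(seq_len(nrow(reg_snps)), function(i) {
    touch_a <- lp$chrom_a == reg_snps$chrom[i] & lp$start_a == snp_bin[i]
    touch_b <- lp$chrom_b == reg_snps$chrom[i] & lp$start_b == snp_bin[i]
    partners <- rbind(
      data.frame(chrom = lp$chrom_b[touch_a], bin = lp$start_b[touch_a],
                 p = lp$p[touch_a]),
      data.frame(chrom = lp$chrom_a[touch_b], bin = lp$start_a[touch_b],
                 p = lp$p[touch_b]))
    if (!nrow(partners)) return(NULL)
    hits <- lapply(seq_len(nrow(partners)), function(j) {
      sel <- which(genes$chrom == partners$chrom[j] &
                   gene_bin == partners$bin[j])
      if (!length(sel)) return(NULL)
      data.frame(id = reg_snps$id[i], locus_id = reg_snps$locus_id[i],
                 gene_id = genes$gene_id[sel], loop_p = partners$p[j],
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, hits)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) return(empty)
  # one row per SNP-gene pair, strongest loop
  out <- out[order(out$id, out$gene_id, out$loop_p), , drop = FALSE]
  out <- out[!duplicated(out[, c("id", "gene_id")]), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Tiered per-locus gene prioritization
#'
#' Applies the three-tier hierarchy locus by locus: (i) if any gene at a
#' locus carries a risk-associated deleterious coding variant, those genes
#' (and only those) are emitted at tier `coding`; (ii) otherwise the
#' proximal target genes of regulatory SNPs, tier `proximal`; (iii)
#' otherwise the distal (loop) target genes, tier `distal`. Loci with no
#' hits emit nothing. The union of all evidence genes across tiers is also
#' returned, before tiering.
#'
#' @param coding_hits output of [classify_coding()].
#' @param proximal_hits output of [assign_proximal()].
#' @param distal_hits output of [assign_distal()].
#' @return list with `prioritized` (data frame `locus_id`, `gene_id`,
#'   `tier`, `evidence_snps`, `n_snps`) and `union_genes` (data frame
#'   `locus_id`, `gene_id`, `mechanisms`).
#' @export
prioritize <- function(coding_hits, proximal_hits, distal_hits) {
  mk <- function(df, mech) {
    if (is.null(df) || !nrow(df)) return(NULL)
    data.frame(locus_id = df$locus_id, gene_id = df$gene_id, id = df$id,
               mechanism = mech, stringsAsFactors = FALSE)
  }
  all_hits <- rbind(mk(coding_hits, "coding"), mk(proximal_hits, "proximal"),
                    mk(distal_hits, "distal"))
  if (is.null(all_hits) || !nrow(all_hits))
    return(list(prioritized = data.frame(locus_id = integer(0),
                                         gene_id = character(0),
                                         tier = character(0),
                                         evidence_snps = character(0),
                                         n_snps = integer(0)),
                union_genes = data.frame(locus_id = integer(0),
                                         gene_id = character(0),
                                         mechanisms = character(0))))
  all_hits <- all_hits[!is.na(all_hits$gene_id), , drop = FALSE]
  union_genes <- do.call(rbind, lapply(
    split(all_hits, paste(all_hits$locus_id, all_hits$gene_id)),
    function(g) data.frame(locus_id = g$locus_id[1], gene_id = g$gene_id[1],
                           mechanisms = paste(sort(unique(g$mechanism)),
                                              collapse = ","))))
  union_genes <- union_genes[order(union_genes$locus_id,
                                   union_genes$gene_id), , drop = FALSE]
  rownames(union_genes) <- NULL

  pri <- lapply(sort(unique(all_hits$locus_id)), function(lid) {
    h <- all_hits[all_hits$locus_id == lid, , drop = FALSE]
    tier <- if (any(h$mechanism == "coding")) "coding"
      else if (any(h$mechanism == "proximal")) "proximal" else "distal"
    h <- h[h$mechanism == tier, , drop = FALSE]
    do.call(rbind, lapply(split(h, h$gene_id), function(g)
      data.frame(locus_id = lid, gene_id = g$gene_id[1], tier = tier,
                 evidence_snps = paste(sort(unique(g$id)), collapse = ","),
                 n_snps = length(unique(g$id)), stringsAsFactors = FALSE)))
  })
  pri <- do.call(rbind, pri)
  pri <- pri[order(pri$locus_id, pri$gene_id), , drop = FALSE]
  rownames(pri) <- NULL
  list(prioritized = pri, union_genes = union_genes)
}
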