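#!/usr/bin/env Rscript
# Stage 6: functional fine-mapping of the candidate SNPs — coding
# consequences, open-chromatin overlap, proximal (TSS) and distal (loop)
# target genes, and the tiered per-locus prioritization.

suppressPackageStartupMessages({
  library(otomap)
  library(GenomicRanges)  # c() dispatch on GRanges in script context
})

state <- readRDS("results/inputs/state.rds")
cand <- utils::read.table("results/loci/candidates.tsv", header = TRUE,
                          sep = "\t", stringsAsFactors = FALSE)
genes <- read_genes("results/inputs/genes.tsv")
loops <- read_loops("results/inputs/loops.tsv")
lifted <- readRDS("results/chromatin/lifted_ocr.rds")
out <- "results/finemap"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

# synthetic variant-effect table: a few candidates carry deleterious
# coding consequences
set.seed(child_seed(state$seed, "effects"))
n_eff <- max(3, round(0.02 * nrow(cand)))
eff_ids <- sample(cand$id, n_eff)
nearest_gene <- vapply(match(eff_ids, cand$id), function(i) {
  d <- abs(genes$tss - cand$pos[i])
  genes$gene_id[which.min(ifelse(genes$chrom == cand$chrom[i], d, Inf))]
}, character(1))
effects <- data.frame(
  id = eff_ids,
  consequence = sample(c("missense", "stopgain", "synonymous"), n_eff,
                       replace = TRUE, prob = c(0.6, 0.1, 0.3)),
  gene_id = nearest_gene,
  cadd_phred = stats::runif(n_eff, 0, 35))

ocr <- c(lifted$epithelial, lifted$non_epithelial)
ocr$cell_class <- rep(c("epithelial", "non_epithelial"),
                      c(length(lifted$epithelial),
                        length(lifted$non_epithelial)))

coding <- classify_coding(cand, effects, cadd_min = 10)
message(nrow(coding), " deleterious coding candidate(s)")
reg <- regulatory_candidates(cand, ocr, flank_bp = 500)
message(nrow(reg), " of ", nrow(cand),
        " candidates lie within 500 bp of a homologous OCR")
prox <- assign_proximal(reg, genes, max_tss_distance = 20000)
dist <- assign_distal(reg, loops, genes, loop_p_max = 1e-25,
                      bin_size = 40000)
message(length(unique(prox$gene_id)), " proximal and ",
        length(unique(dist$gene_id)), " distal target gene(s)")

res <- prioritize(coding, prox, dist)
message(nrow(res$prioritized), " prioritized gene-locus pairs; ",
        nrow(res$union_genes), " genes in the evidence union")
utils::write.table(res$prioritized,
                   file.path(out, "prioritized_genes.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)
utils::write.table(res$union_genes, file.path(out, "union_genes.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

# per-SNP annotation table (mechanism + target gene)
ann_rows <- rbind(
  if (nrow(coding)) data.frame(id = coding$id, locus_id = coding$locus_id,
                               mechanism = "coding",
                               gene_id = coding$gene_id),
  if (nrow(prox)) data.frame(id = prox$id, locus_id = prox$locus_id,
                             mechanism = "proximal",
                             gene_id = prox$gene_id),
  if (nrow(dist)) data.frame(id = dist$id, locus_id = dist$locus_id,
                             mechanism = "distal", gene_id = dist$gene_id))
if (!is.null(ann_rows))
  utils::write.table(ann_rows, file.path(out, "snp_annotations.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
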