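#!/usr/bin/env Rscript
# Stage 7: single-cell pipeline — QC, normalization, clustering, markers,
# risk-gene cell-type specificity, and the hair-cell meta-analysis.

suppressPackageStartupMessages(library(otomap))

state <- readRDS("results/inputs/state.rds")
sc <- read_counts_mtx("results/inputs/sc_counts")
truth <- utils::read.table("results/inputs/sc_truth.tsv", header = TRUE,
                           sep = "\t", stringsAsFactors = FALSE)
out <- "results/single_cell"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

qc <- qc_filter(sc, min_umi = 50, max_umi = 20000, max_mito = 0.20)
message("QC: removed ", qc$report$n_removed, " of ", ncol(sc$counts),
        " cells (", qc$report$n_low_umi, " low UMI, ",
        qc$report$n_high_umi, " high UMI, ", qc$report$n_high_mito,
        " high mito)")

nm <- normalize_and_select(qc$sc, mean_max = 8)
message(length(nm$var_genes), " variable genes")
covs <- data.frame(mito = nm$mito_fraction, numi = nm$total_umi)
cl <- cluster_cells(nm, covs, n_components = 10, resolution = 0.6,
                    seed = child_seed(state$seed, "cluster"))
message(cl$n_clusters, " clusters over ", length(cl$labels), " cells")
truth_kept <- truth$celltype[match(qc$report$kept_barcodes, truth$barcode)]
ctab <- table(cluster = cl$labels, celltype = truth_kept)
utils::write.table(as.data.frame(ctab),
                   file.path(out, "cluster_vs_truth.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)

mk <- find_markers(nm, cl$labels)
utils::write.table(mk, file.path(out, "markers.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)

# specificity of the prioritized risk genes' stand-ins: the planted
# hair-cell markers plus a few random genes
risk_genes <- c(sprintf("g%04d", 1:6), sprintf("g%04d", 500:505))
spec <- risk_gene_specificity(mk, risk_genes, top_k = 3)
utils::write.table(spec, file.path(out, "risk_gene_specificity.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
message(sum(spec$expressed), " of ", nrow(spec),
        " risk genes detected in the matrix")

# cross-dataset hair-cell meta-analysis with planted enrichment
genes <- sprintf("g%04d", 1:150)
ds <- gen_haircell_datasets(3, genes, haircell_genes = sprintf("g%04d", 1:6),
                            fold = 4,
                            seed = child_seed(state$seed, "hcmeta"))
meta <- haircell_meta(ds, genes, fdr = 0.1)
utils::write.table(meta, file.path(out, "haircell_meta.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)
message(sum(meta$flagged), " genes selectively expressed in hair cells ",
        "(FDR < 0.1); planted: ",
        sum(meta$flagged[match(sprintf("g%04d", 1:6), meta$gene)]),
        " of 6")
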