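#!/usr/bin/env Rscript
# Stage 8: polygenic-score replication — phenotype PCA, cohort QC,
# threshold scoring from a discovery GWAS conditioned on the planted
# effects, and variance explained in threshold PC1.

suppressPackageStartupMessages(library(otomap))

state <- readRDS("results/inputs/state.rds")
out <- "results/prs"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

G <- read_dosages("results/inputs/cohort_dosages.tsv")
thr <- utils::read.table("results/inputs/cohort_thresholds.tsv",
                         header = TRUE, sep = "\t")
thr_m <- as.matrix(thr[, -1])

pc <- phenotype_pca(thr_m)
message(sprintf("PC1 explains %.1f%% of threshold variance",
                100 * pc$var_explained[1]))

qc <- qc_cohort(G, miss_ind = 0.10, miss_snp = 0.10, maf_min = 0.05,
                hwe_p = 1e-6)
message("cohort QC: ", qc$report$n_individuals, " individuals, ",
        qc$report$n_snps, " SNPs retained (removed: ",
        qc$report$n_snp_missing, " missingness, ", qc$report$n_snp_maf,
        " MAF, ", qc$report$n_snp_hwe, " HWE)")

# discovery GWAS conditioned on the planted effects (the scoring stage
# needs effect-direction alignment, unlike the heritability stage)
disc <- gen_sumstats(state$panel, state$truth, 50000, mode = "conditional",
                     seed = child_seed(state$seed, "prs_discovery"))[[1]]

kept_ind <- match(rownames(qc$genotypes), rownames(G))
prs <- compute_prs(qc$genotypes,
                   state$cohort$target_info, disc,
                   thresholds = c(0.001, 0.005, 0.01, 0.05, 0.1, 0.5, 1))
ev <- evaluate_prs(prs, pc$scores[kept_ind, 1])
print(ev)
utils::write.table(ev, file.path(out, "prs_evaluation.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)
best <- attr(ev, "best")
message(sprintf(
  "best threshold p <= %g: %d SNPs, %.2f%% of PC1 variance (p = %.2g)",
  best$threshold, best$n_snps, 100 * best$r2, best$p))
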