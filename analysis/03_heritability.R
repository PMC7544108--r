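#!/usr/bin/env Rscript
# Stage 3: SNP heritability, confounding attribution, stratified
# enrichment of the cochlear open-chromatin annotation, and the genetic
# correlation between the two simulated hearing traits.

suppressPackageStartupMessages(library(otomap))

state <- readRDS("results/inputs/state.rds")
ss1 <- read_sumstats("results/inputs/sumstats_trait1.tsv")
ss2 <- read_sumstats("results/inputs/sumstats_trait2.tsv")
out <- "results/heritability"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

lsc <- compute_ld_scores(state$panel, state$ann, window_bp = 5e4)

uni <- fit_ldsc(ss1, lsc, n = 50000)
print(uni)
strat <- fit_stratified_ldsc(ss1, lsc, state$ann, n = 50000)
print(strat)
write_sldsc_report(strat, file.path(out, "stratified_fit.tsv"))

rg <- fit_genetic_correlation(ss1, ss2, lsc, 50000, 50000,
                              n_overlap = 50000)
print(rg)

utils::write.table(
  data.frame(quantity = c("h2", "h2_se", "intercept", "intercept_se",
                          "mean_chi2", "polygenic_attribution",
                          "ocr_enrichment", "ocr_enrichment_p", "rg",
                          "rg_se"),
             value = c(uni$h2, uni$h2_se, uni$intercept, uni$intercept_se,
                       uni$mean_chi2, uni$attribution,
                       strat$table$enrichment[strat$table$category ==
                                                "cochlear_ocr"],
                       strat$table$enrichment_p[strat$table$category ==
                                                  "cochlear_ocr"],
                       rg$rg, rg$rg_se)),
  file.path(out, "summary.tsv"), sep = "\t", quote = FALSE,
  row.names = FALSE)
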