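#!/usr/bin/env Rscript
# Stage 4: ATAC replicate merging, blacklist subtraction, cross-species
# interval mapping (50% matched-bases rule), VISTA-style permutation
# enrichment and chromatin-state folds.

suppressPackageStartupMessages(library(otomap))

state <- readRDS("results/inputs/state.rds")
feats <- state$features
out <- "results/chromatin"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

ocr_by_class <- lapply(names(feats$peaks), function(cc) {
  merged <- merge_replicate_peaks(feats$peaks[[cc]]$rep1,
                                  feats$peaks[[cc]]$rep2)
  clean <- subtract_blacklist(merged, feats$blacklist)
  message(cc, ": ", length(feats$peaks[[cc]]$rep1), " rep1 peaks -> ",
          length(merged), " reproducible -> ", length(clean),
          " after blacklist")
  clean
})
names(ocr_by_class) <- names(feats$peaks)

# project mouse-like OCRs to the target assembly, 50% matched bases
lifted <- lapply(names(ocr_by_class), function(cc) {
  res <- map_intervals(feats$chain, ocr_by_class[[cc]], min_match = 0.5)
  message(cc, ": ", length(res$mapped), " of ",
          length(ocr_by_class[[cc]]), " OCRs mapped (",
          round(100 * mean(res$report$status == "mapped"), 1), "%)")
  write_bed(res$mapped, file.path(out, sprintf("ocr_%s_lifted.bed", cc)))
  res$mapped
})
names(lifted) <- names(ocr_by_class)

# enhancer overlap enrichment within the source genome workspace
ws <- GenomicRanges::GRanges(
  names(feats$src_lengths),
  IRanges::IRanges(1, unname(feats$src_lengths)))
enr <- lapply(names(ocr_by_class), function(cc) {
  pe <- permutation_enrichment(ocr_by_class[[cc]], feats$enhancers, ws,
                               n_permutations = 1000,
                               seed = child_seed(state$seed, "gat"))
  message(sprintf("%s vs enhancers: %.2f-fold, p = %.3g", cc, pe$fold,
                  pe$p))
  data.frame(cell_class = cc, fold = pe$fold, p = pe$p,
             observed = pe$observed, null_mean = pe$null_mean)
})
utils::write.table(do.call(rbind, enr),
                   file.path(out, "enhancer_enrichment.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)

# chromatin-state folds of the lifted (target-assembly) epithelial OCRs
st <- state_enrichment(lifted[[1]], feats$states)
utils::write.table(st, file.path(out, "state_enrichment.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)

saveRDS(lifted, file.path(out, "lifted_ocr.rds"))
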