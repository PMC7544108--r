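#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study inputs.
#
# Emulates the statistical structure of the real study inputs at desk
# scale: an LD reference panel with heterogeneous blocks, GWAS summary
# statistics for a hearing-difficulty-like trait (plus a genetically
# correlated companion trait), cochlear-like genome annotations (ATAC
# peaks per cell class, blacklist, mouse-to-human chain, Hi-C loops,
# chromatin states, gene models), single-cell UMI counts and a target
# cohort with multi-frequency hearing thresholds. All outputs are written
# under results/inputs/ in their standard on-disk formats.

suppressPackageStartupMessages(library(otomap))

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args)) as.integer(args[[1]]) else 1L
out <- "results/inputs"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

message("master seed: ", seed)

## LD reference panel: 1,000 individuals x 10,000 SNPs, AR(1) blocks of 20
## with adjacent dosage correlation drawn per block from [0.2, 0.9]
## placed on the GWAS assembly (chr1), spanning its first 11 Mb
panel <- gen_reference_panel(1000, 10000, 20, c(0.2, 0.9), chrom = "chr1",
                             seed = child_seed(seed, "panel"))

## annotations: an open-chromatin-like category over 2% of SNPs
set.seed(child_seed(seed, "annotation"))
ocr_idx <- sort(sample.int(10000, 200))
ann <- make_annotations(panel, list(cochlear_ocr = ocr_idx))

## planted truth: h2 = 0.3 with 9-fold enrichment in the OCR category,
## rg = 0.8 with the companion trait
truth <- make_simulation_truth(panel, h2_total = 0.3, annotations = ann,
                               enrichment = c(cochlear_ocr = 9), rg = 0.8,
                               seed = child_seed(seed, "truth"))

ss <- gen_sumstats(panel, truth, sample_size = 50000, n_traits = 2,
                   confounding_intercept = 1, env_corr = 0.2,
                   n_overlap = 50000, seed = child_seed(seed, "sumstats"))
write_sumstats(ss[[1]], file.path(out, "sumstats_trait1.tsv"), seed = seed)
write_sumstats(ss[[2]], file.path(out, "sumstats_trait2.tsv"), seed = seed)

## genome features on a 2-chromosome toy genome
feats <- gen_genome_features(c(chr1 = 60e6, chr2 = 40e6), n_genes = 1000,
                             peak_density = 40, loop_density = 3,
                             seed = child_seed(seed, "features"))
write_genes(feats$genes, file.path(out, "genes.tsv"), seed = seed)
for (cc in names(feats$peaks)) for (rr in c("rep1", "rep2"))
  write_bed(feats$peaks[[cc]][[rr]],
            file.path(out, sprintf("atac_%s_%s.bed", cc, rr)))
write_bed(feats$blacklist, file.path(out, "blacklist.bed"))
write_chain(feats$chain, file.path(out, "mm_to_hs.chain"))
write_loops(feats$loops, file.path(out, "loops.tsv"), seed = seed)
write_bed(feats$enhancers, file.path(out, "vista_like_enhancers.bed"))
write_bed(feats$states, file.path(out, "chromatin_states.bed"))

## single-cell counts: 10 cochlear-like cell types, 200 cells each
types <- stats::setNames(rep(200, 10),
                         c("hair_cells", "supporting_cells", "pillar",
                           "deiters", "marginal", "intermediate", "basal",
                           "spiral_ganglion", "fibrocytes", "immune"))
markers <- lapply(seq_along(types), function(i)
  list(genes = ((i - 1) * 25 + 1):(i * 25), fold = 8))
names(markers) <- names(types)
sc_sim <- gen_sc_counts(types, n_genes = 800, marker_spec = markers,
                        depth_mean = 2000, violator_frac = 0.05,
                        seed = child_seed(seed, "sc"))
write_counts_mtx(sc_sim$sc, file.path(out, "sc_counts"))
utils::write.table(sc_sim$truth, file.path(out, "sc_truth.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

## target cohort: 1,500 individuals, 3 threshold frequencies
cohort <- gen_target_cohort(1500, panel, truth, n_frequencies = 3,
                            h2_score = 0.05, noise_sd = 0.3,
                            miss_rate = 0.002, n_lowmaf = 20,
                            n_hwe_violating = 5,
                            seed = child_seed(seed, "cohort"))
write_dosages(cohort$genotypes, file.path(out, "cohort_dosages.tsv"),
              seed = seed)
utils::write.table(
  data.frame(individual = rownames(cohort$genotypes), cohort$thresholds),
  file.path(out, "cohort_thresholds.tsv"), sep = "\t", quote = FALSE,
  row.names = FALSE)

saveRDS(list(panel = panel, ann = ann, truth = truth, features = feats,
             sc = sc_sim, cohort = cohort, seed = seed),
        "results/inputs/state.rds")

message("wrote synthetic inputs for ", nrow(panel$variants),
        " variants, ", nrow(feats$genes), " genes, ",
        ncol(sc_sim$sc$counts), " cells, ",
        nrow(cohort$genotypes), " cohort individuals")
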