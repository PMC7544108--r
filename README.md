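# otomap

Multi-omic mapping of hearing-difficulty GWAS risk loci to cochlear
genes, as a tested, fully synthetic-data-driven R pipeline.

Age-related hearing impairment is common and highly polygenic, and most
of its association signal falls in non-coding DNA. Because the damaged
tissue — the cochlear sensory epithelium, above all the hair cells —
cannot be sampled in living people, linking risk loci to genes requires
layering mouse cochlear epigenomes, chromatin contact maps and
single-cell transcriptomes on top of human GWAS results. otomap
implements that chain of analyses end to end for statisticians and
genomicists who want the machinery itself: every stage is an exported,
unit-tested function, and synthetic-data generators with planted truth
stand in for the biobank, ATAC-seq, Hi-C and single-cell inputs so the
whole pipeline runs and validates offline.

## What is implemented

- **Locus definition** — greedy LD clumping of genome-wide significant
  SNPs (p < 5·10⁻⁸), locus assembly from r² > 0.6 membership with 250 kb
  block merging, and expansion to the r² > 0.9 fine-mapping candidate
  set (`clump_lead_snps`, `define_risk_loci`, `expand_candidates`).
- **LD score regression** — heritability with confounding attribution,
  stratified enrichment `(share of h² in an annotation)/(share of
  SNPs)`, and cross-trait genetic correlation, all with delete-one
  block-jackknife uncertainty (`fit_ldsc`, `fit_stratified_ldsc`,
  `fit_genetic_correlation`, `compute_ld_scores`).
- **Gene-level association** — mean-χ² gene statistic with an
  eigenvalue-weighted chi-square null (Imhof-type inversion),
  competitive gene-set test, and cell-type gene-property regression on
  quantile-normalized expression (`gene_test`, `gene_set_test`,
  `gene_property_test`).
- **Chromatin intervals** — ATAC replicate intersection, whole-peak
  blacklist removal, UCSC-chain projection with the 50% matched-bases
  rule, GAT-style workspace permutation enrichment, chromatin-state
  folds (`merge_replicate_peaks`, `map_intervals`,
  `permutation_enrichment`, `state_enrichment`).
- **Fine-mapping tiers** — deleterious coding variants (CADD ≥ 10),
  ±500 bp open-chromatin overlap, proximal targets within 20 kb of a
  TSS, distal targets through 40 kb chromatin-loop bins (p < 10⁻²⁵),
  and the strict coding → proximal → distal tier rule per locus
  (`classify_coding`, `regulatory_candidates`, `assign_proximal`,
  `assign_distal`, `prioritize`).
- **Single cell** — UMI/mitochondrial QC, log normalization and
  variable-gene selection, SNN-Louvain clustering, exact/approximate
  Wilcoxon markers with expression fractions, risk-gene specificity,
  and an equal-weight Stouffer hair-cell meta-analysis at FDR < 0.1
  (`qc_filter`, `cluster_cells`, `find_markers`, `haircell_meta`).
- **Polygenic scores** — threshold-phenotype PCA, cohort QC with the
  exact Hardy-Weinberg test, p-value-threshold scoring with allele
  harmonization, incremental R² evaluation (`phenotype_pca`,
  `qc_cohort`, `compute_prs`, `evaluate_prs`).
- **Synthetic data** — calibrated AR(1)-block LD panels, summary
  statistics drawn from the LDSC generative model (marginal,
  conditional-on-effects and genotype modes), two-assembly genome
  features with a chain between them, negative-binomial single-cell
  counts with planted markers and QC violators, and a replication
  cohort whose threshold PC1 carries a planted genetic signal
  (`gen_reference_panel`, `gen_sumstats`, `gen_genome_features`,
  `gen_sc_counts`, `gen_target_cohort`).

The model at the core of the heritability stage is the LD score
regression `E[χ²_j] = a0 + N Σ_c τ_c ℓ_{j,c}`, with `ℓ_{j,c} = Σ_k
r²_{jk} a_{k,c}`; the synthetic summary statistics are drawn from its
generative twin, `z ~ N(0, a0·R + N·R·diag(h²)·R)` blockwise on the
panel's empirical LD, so planted h², enrichment and r_g are recoverable
ground truth.

## Worked example

```r
library(otomap)

set.seed(2024)
panel <- gen_reference_panel(1000, 10000, 20, c(0.2, 0.9), seed = 2024)
ann   <- make_annotations(panel, list(ocr = sort(sample.int(10000, 200))))
truth <- make_simulation_truth(panel, h2_total = 0.3, annotations = ann,
                               enrichment = c(ocr = 9), seed = 7)
ss    <- gen_sumstats(panel, truth, sample_size = 50000, seed = 11)[[1]]
lsc   <- compute_ld_scores(panel, ann, window_bp = 5e4)

fit_ldsc(ss, lsc, n = 50000)
#> LDSC: h2 = 0.3163 (SE 0.0297), intercept = 0.8585 (SE 0.2300), mean chi2 = 5.928
#>   share of inflation ascribed to polygenicity: 102.9%

fit_stratified_ldsc(ss, lsc, ann,
                    n = 50000)$table[2, c("category", "prop_h2",
                                          "enrichment", "enrichment_p")]
#>   category   prop_h2 enrichment enrichment_p
#> 2      ocr 0.1664946    8.32473 2.513056e-09
```

One replicate recovers the planted heritability (0.3) within a
jackknife SE, an intercept consistent with 1 (no confounding was
planted; the polygenic share of the χ² inflation is accordingly ~100%),
and the planted 9-fold open-chromatin enrichment over 2% of SNPs; the
enrichment p-value tests `prop_h2 = prop_snps`.

The full narrative lives in `analysis/01_simulate_inputs.R` through
`analysis/08_prs.R`: stage 1 writes every input in its standard on-disk
format (summary-statistics TSV, BED, UCSC chain, loop TSV, MatrixMarket
counts, dosage TSV), and the later stages re-read those files, print
what they found and write tables under `results/`.

```sh
Rscript analysis/01_simulate_inputs.R 1
Rscript analysis/02_define_loci.R
# ... through analysis/08_prs.R
```

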