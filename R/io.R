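# Readers and writers for the pipeline's on-disk formats. Tab-separated
# text throughout; interval files use BED conventions (0-based half-open on
# disk, 1-based closed GRanges in memory); sparse counts use MatrixMarket
# with gene/barcode sidecars. Generator outputs record their seeds in `#`
# header comments.

.write_tsv <- function(df, path, seed = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(seed)) writeLines(sprintf("# seed=%d", seed), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

.read_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' Write / read GWAS summary statistics
#'
#' Columns: chrom, pos, id, effect_allele, other_allele, beta, se, p, n.
#' @param ss summary-statistics data frame.
#' @param path file path.
#' @param seed optional seed recorded in the header.
#' @export
write_sumstats <- function(ss, path, seed = NULL) {
  .check_sumstats(ss)
  .write_tsv(ss[, c("chrom", "pos", "id", "effect_allele", "other_allele",
                    "beta", "se", "p", "n")], path, seed)
}

#' @rdname write_sumstats
#' @export
read_sumstats <- function(path) {
  ss <- .read_tsv(path)
  ss$chrom <- as.character(ss$chrom)
  .check_sumstats(ss)
  ss
}

#' Write / read BED interval files
#'
#' BED3 (or BED4 when the `GRanges` has a `name` column); disk coordinates
#' are 0-based half-open, in-memory `GRanges` 1-based closed.
#' @param gr a `GRanges`.
#' @param path file path.
#' @export
write_bed <- function(gr, path) {
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1,
                   end = GenomicRanges::end(gr))
  if (!is.null(gr$name)) df$name <- gr$name
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
}

#' @rdname write_bed
#' @export
read_bed <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE)
  gr <- GenomicRanges::GRanges(df[[1]], IRanges::IRanges(df[[2]] + 1, df[[3]]))
  if (ncol(df) >= 4) gr$name <- df[[4]]
  gr
}

#' Write / read chromatin loop tables
#'
#' Columns: chrom_a, start_a, chrom_b, start_b, bin_size, p (bin starts are
#' 0-based multiples of the bin size).
#' @param loops loop data frame.
#' @param path file path.
#' @param seed optional header seed.
#' @export
write_loops <- function(loops, path, seed = NULL) .write_tsv(loops, path, seed)

#' @rdname write_loops
#' @export
read_loops <- function(path) {
  df <- .read_tsv(path)
  df$chrom_a <- as.character(df$chrom_a)
  df$chrom_b <- as.character(df$chrom_b)
  df
}

#' Write / read gene-model tables
#'
#' GFF-like TSV with 1-based closed bodies: gene_id, symbol, chrom, start,
#' end, strand, tss.
#' @param genes gene data frame.
#' @param path file path.
#' @param seed optional header seed.
#' @export
write_genes <- function(genes, path, seed = NULL) .write_tsv(genes, path, seed)

#' @rdname write_genes
#' @export
read_genes <- function(path) {
  df <- .read_tsv(path)
  df$chrom <- as.character(df$chrom)
  df
}

#' Write / read sparse UMI counts (MatrixMarket triplet)
#'
#' Writes `<prefix>.mtx`, `<prefix>.genes.tsv`, `<prefix>.barcodes.tsv`;
#' mitochondrial genes are recognized by their `mt-` prefix on re-read.
#' @param sc an `sc_counts`.
#' @param prefix path prefix.
#' @export
write_counts_mtx <- function(sc, prefix) {
  stopifnot(inherits(sc, "sc_counts"))
  Matrix::writeMM(sc$counts, paste0(prefix, ".mtx"))
  writeLines(rownames(sc$counts), paste0(prefix, ".genes.tsv"))
  writeLines(colnames(sc$counts), paste0(prefix, ".barcodes.tsv"))
  invisible(prefix)
}

#' @rdname write_counts_mtx
#' @export
read_counts_mtx <- function(prefix) {
  m <- methods::as(Matrix::readMM(paste0(prefix, ".mtx")), "CsparseMatrix")
  rownames(m) <- readLines(paste0(prefix, ".genes.tsv"))
  colnames(m) <- readLines(paste0(prefix, ".barcodes.tsv"))
  sc_counts(m)
}

#' Write / read cohort dosage matrices
#'
#' Transposed dosage TSV: one row per variant (id column first), one
#' column per individual; missing dosages are `NA`.
#' @param genotypes individuals x variants matrix.
#' @param path file path.
#' @param seed optional header seed.
#' @export
write_dosages <- function(genotypes, path, seed = NULL) {
  df <- data.frame(id = colnames(genotypes), t(genotypes),
                   check.names = FALSE)
  .write_tsv(df, path, seed)
}

#' @rdname write_dosages
#' @export
read_dosages <- function(path) {
  df <- .read_tsv(path)
  ids <- df$id
  m <- t(as.matrix(df[, -1, drop = FALSE]))
  colnames(m) <- ids
  m
}

#' Write a stratified-LDSC fit report
#'
#' One row per category: category, m_c, prop_snps, prop_h2, enrichment,
#' enrichment_p, tau, tau_se.
#' @param fit an `sldsc_fit`.
#' @param path file path.
#' @export
write_sldsc_report <- function(fit, path) {
  stopifnot(inherits(fit, "sldsc_fit"))
  .write_tsv(fit$table, path)
}
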