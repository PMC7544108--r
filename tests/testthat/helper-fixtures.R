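# Small shared fixtures, built once per test run.

# a compact panel reused by several interval/locus tests
tiny_panel <- function(n = 300, m = 100, block = 20, corr = 0.8, seed = 7)
  gen_reference_panel(n, m, block, corr, seed = seed)

# a hand-built summary-statistics frame over arbitrary ids
manual_sumstats <- function(id, p, chrom = "1",
                            pos = seq(1e5, by = 1e4,
                                      length.out = length(id)),
                            n = 1e4) {
  z <- stats::qnorm(p / 2, lower.tail = FALSE)
  se <- rep(0.01, length(id))
  data.frame(chrom = chrom, pos = pos, id = id,
             effect_allele = "A", other_allele = "G",
             beta = z * se, se = se, p = p, n = n,
             stringsAsFactors = FALSE)
}

# GRanges shorthand
gr <- function(chrom, start, end, ...) {
  g <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end))
  mc <- list(...)
  for (nm in names(mc)) S4Vectors::mcols(g)[[nm]] <- mc[[nm]]
  g
}
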