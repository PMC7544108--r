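#' Derive a child seed from a master seed and a stage label
#'
#' Every generator in the package takes a single integer seed. Pipelines that
#' need several independent random streams derive one child seed per stage
#' from a master seed with this splitting rule: the stage label is hashed
#' with a base-131 rolling polynomial modulo the Mersenne prime 2^31 - 1,
#' combined with the master seed by a fixed linear-congruential step, and
#' reduced to the integer range. The rule is deterministic and recorded in
#' output file headers.
#'
#' @param master integer master seed.
#' @param stage character stage label, e.g. `"panel"` or `"sumstats"`.
#' @return a single integer in `[1, 2^31 - 2]`.
#' @export
child_seed <- function(master, stage) {
  stopifnot(length(master) == 1L, is.finite(master), is.character(stage),
            length(stage) == 1L, nchar(stage) > 0L)
  h <- 0
  for (code in utf8ToInt(stage)) h <- (h * 131 + code) %% 2147483647
  as.integer((abs(as.numeric(master)) %% 2147483647 * 48271 + h) %% 2147483645 + 1)
}

#' Classify allele pairs for harmonization between two datasets
#'
#' Compares (effect, other) allele pairs of the same variant in two sources.
#' Returns one of `"same"` (identical orientation), `"flip"` (effect and
#' other swapped; the effect sign must be flipped), `"ambiguous"`
#' (strand-ambiguous A/T or C/G pair, indistinguishable from a strand flip),
#' or `"mismatch"` (alleles incompatible).
#'
#' @param ea1,oa1 effect/other alleles in the first source.
#' @param ea2,oa2 effect/other alleles in the second source.
#' @return character vector of classifications.
#' @export
classify_alleles <- function(ea1, oa1, ea2, oa2) {
  ea1 <- toupper(ea1); oa1 <- toupper(oa1)
  ea2 <- toupper(ea2); oa2 <- toupper(oa2)
  amb <- (ea1 == "A" & oa1 == "T") | (ea1 == "T" & oa1 == "A") |
         (ea1 == "C" & oa1 == "G") | (ea1 == "G" & oa1 == "C")
  out <- rep("mismatch", length(ea1))
  out[ea1 == ea2 & oa1 == oa2] <- "same"
  out[ea1 == oa2 & oa1 == ea2] <- "flip"
  out[amb] <- "ambiguous"
  out
}

# chi-square tail p for a z score, numerically safe in both tails
.z_to_p <- function(z) stats::pchisq(z^2, df = 1, lower.tail = FALSE)

# internal: validate a summary-statistics data frame
.check_sumstats <- function(ss) {
  need <- c("chrom", "pos", "id", "effect_allele", "other_allele",
            "beta", "se", "p", "n")
  miss <- setdiff(need, names(ss))
  if (length(miss))
    stop("summary statistics missing columns: ", paste(miss, collapse = ", "))
  if (any(ss$se <= 0)) stop("non-positive standard errors in summary statistics")
  invisible(ss)
}

#' Chi-square statistics of a summary-statistics table
#' @param ss summary-statistics data frame (see [gen_sumstats()]).
#' @return numeric vector of (beta/se)^2.
#' @export
sumstats_chi2 <- function(ss) {
  .check_sumstats(ss)
  (ss$beta / ss$se)^2
}
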