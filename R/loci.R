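# Risk-locus definition: greedy LD clumping of genome-wide significant SNPs,
# locus assembly from LD membership with distance-based merging, and
# expansion to the fine-mapping candidate set.

#' Greedy LD clumping of genome-wide significant SNPs
#'
#' Significant SNPs are visited in ascending p (ties broken by genomic
#' position); each SNP not absorbed by an earlier lead becomes a lead, and a
#' later SNP is absorbed iff its r2 with an existing lead is at least
#' `r2_independence`. The retained leads are therefore mutually below the
#' independence threshold.
#'
#' @param sumstats summary-statistics data frame.
#' @param ld an `ld_provider` covering the significant SNPs.
#' @param p_threshold genome-wide significance threshold.
#' @param r2_independence absorption threshold (leads are LD-independent
#'   below it).
#' @return character vector of lead SNP ids, ordered by p then position.
#' @export
clump_lead_snps <- function(sumstats, ld, p_threshold = 5e-8,
                            r2_independence = 0.6) {
  .check_sumstats(sumstats)
  sig <- sumstats[sumstats$p < p_threshold, , drop = FALSE]
  if (!nrow(sig)) return(character(0))
  sig <- sig[order(sig$p, sig$chrom, sig$pos), , drop = FALSE]
  absorbed <- rep(FALSE, nrow(sig))
  leads <- character(0)
  for (i in seq_len(nrow(sig))) {
    if (absorbed[i]) next
    lead <- sig$id[i]
    leads <- c(leads, lead)
    rest <- which(!absorbed & seq_len(nrow(sig)) > i)
    if (!length(rest)) next
    r2 <- ld_r2_one_many(ld, lead, sig$id[rest])
    if (anyNA(r2))
      stop("missing LD for a significant pair: ", lead, " vs ",
           paste(sig$id[rest][is.na(r2)], collapse = ","))
    absorbed[rest[r2 >= r2_independence]] <- TRUE
  }
  leads
}

#' Define risk loci from lead SNPs
#'
#' Each lead's LD block is the set of all provider variants (whether or not
#' they were tested in the GWAS) with r2 strictly above `r2_membership` with
#' the lead, plus the lead itself. Blocks on the same chromosome whose
#' intervals are separated by at most `merge_kb` kilobases (or that overlap,
#' e.g. through a shared member) are merged into one locus. Loci are
#' numbered in genomic order.
#'
#' @param leads lead ids from [clump_lead_snps()].
#' @param sumstats summary-statistics data frame (used to count tested
#'   members).
#' @param ld an `ld_provider`.
#' @param r2_membership strict membership threshold.
#' @param merge_kb maximum gap between LD blocks to merge, in kb.
#' @return data frame of class `risk_loci` with columns `locus_id`, `chrom`,
#'   `start`, `end`, `n_snps`, `n_gwas_snps`, `leads` (comma-joined);
#'   attribute `members` holds the SNP-to-locus map (id, chrom, pos,
#'   locus_id, tested).
#' @export
define_risk_loci <- function(leads, sumstats, ld, r2_membership = 0.6,
                             merge_kb = 250) {
  if (!length(leads)) {
    out <- data.frame(locus_id = integer(0), chrom = character(0),
                      start = numeric(0), end = numeric(0),
                      n_snps = integer(0), n_gwas_snps = integer(0),
                      leads = character(0), stringsAsFactors = FALSE)
    attr(out, "members") <- data.frame()
    class(out) <- c("risk_loci", "data.frame")
    return(out)
  }
  blocks <- lapply(leads, function(ld_id) {
    prt <- ld_partners(ld, ld_id, r2_membership)
    if (!ld_id %in% prt$id)
      prt <- rbind(prt, data.frame(id = ld_id, chrom = ld$chrom[[ld_id]],
                                   pos = ld$pos[[ld_id]], r2 = 1))
    prt
  })
  binfo <- data.frame(
    lead = leads,
    chrom = vapply(blocks, function(b) b$chrom[1], character(1)),
    start = vapply(blocks, function(b) min(b$pos), numeric(1)),
    end = vapply(blocks, function(b) max(b$pos), numeric(1)),
    stringsAsFactors = FALSE
  )
  # merge blocks per chromosome when gap <= merge_kb * 1000
  ord <- order(binfo$chrom, binfo$start, binfo$end)
  gap <- merge_kb * 1000
  comp <- integer(nrow(binfo))
  cur <- 0L; cur_chrom <- ""; cur_end <- -Inf
  for (i in ord) {
    if (binfo$chrom[i] != cur_chrom || binfo$start[i] - cur_end > gap) {
      cur <- cur + 1L
      cur_chrom <- binfo$chrom[i]
      cur_end <- binfo$end[i]
    } else cur_end <- max(cur_end, binfo$end[i])
    comp[i] <- cur
  }
  tested_ids <- sumstats$id
  members_all <- NULL
  rows <- lapply(sort(unique(comp)), function(cc) {
    sel <- which(comp == cc)
    mem <- unique(do.call(rbind, blocks[sel])[, c("id", "chrom", "pos")])
    mem$tested <- mem$id %in% tested_ids
    list(mem = mem,
         row = data.frame(chrom = binfo$chrom[sel[1]],
                          start = min(mem$pos), end = max(mem$pos),
                          n_snps = nrow(mem), n_gwas_snps = sum(mem$tested),
                          leads = paste(binfo$lead[sel], collapse = ","),
                          stringsAsFactors = FALSE))
  })
  out <- do.call(rbind, lapply(rows, `[[`, "row"))
  ord2 <- order(out$chrom, out$start)
  out <- out[ord2, , drop = FALSE]
  out <- cbind(locus_id = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  members <- do.call(rbind, lapply(seq_along(ord2), function(k) {
    mem <- rows[[ord2[k]]]$mem
    mem$locus_id <- k
    mem
  }))
  rownames(members) <- NULL
  attr(out, "members") <- members
  class(out) <- c("risk_loci", "data.frame")
  out
}

#' Expand loci to the fine-mapping candidate set
#'
#' For every lead of every locus, collects all provider variants with
#' r2 strictly above `r2_candidate` with that lead (the lead itself has
#' r2 = 1). Variants absent from the summary statistics are included and
#' flagged `tested = FALSE` (they carry no p-value). A variant tagged by
#' several leads records the lead with the highest r2.
#'
#' @param loci a `risk_loci` object.
#' @param ld an `ld_provider`.
#' @param sumstats summary-statistics data frame.
#' @param r2_candidate strict r2 threshold for candidacy.
#' @return data frame with columns `id`, `chrom`, `pos`, `locus_id`,
#'   `lead_id`, `r2_with_lead`, `tested`, `p` (NA when untested).
#' @export
expand_candidates <- function(loci, ld, sumstats, r2_candidate = 0.9) {
  stopifnot(inherits(loci, "risk_loci"))
  out <- NULL
  for (i in seq_len(nrow(loci))) {
    for (lead in strsplit(loci$leads[i], ",")[[1]]) {
      prt <- ld_partners(ld, lead, r2_candidate)
      if (!lead %in% prt$id)
        prt <- rbind(prt, data.frame(id = lead, chrom = ld$chrom[[lead]],
                                     pos = ld$pos[[lead]], r2 = 1))
      if (nrow(prt)) {
        prt$locus_id <- loci$locus_id[i]
        prt$lead_id <- lead
        out <- rbind(out, prt)
      }
    }
  }
  if (is.null(out)) return(data.frame())
  # best lead per candidate: highest r2, ties by lead order of appearance
  out <- out[order(out$id, -out$r2), , drop = FALSE]
  out <- out[!duplicated(out$id), , drop = FALSE]
  names(out)[names(out) == "r2"] <- "r2_with_lead"
  out$tested <- out$id %in% sumstats$id
  out$p <- sumstats$p[match(out$id, sumstats$id)]
  out <- out[order(out$locus_id, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Look up previously reported SNPs in a summary-statistics table
#'
#' @param sumstats summary-statistics data frame.
#' @param snp_ids ids to look up.
#' @param alpha nominal significance level.
#' @return data frame with columns `id`, `found`, `p` (NA when absent),
#'   `nominal` (p < alpha).
#' @export
lookup_replication <- function(sumstats, snp_ids, alpha = 0.05) {
  .check_sumstats(sumstats)
  if (!length(snp_ids))
    return(data.frame(id = character(0), found = logical(0),
                      p = numeric(0), nominal = logical(0)))
  p <- sumstats$p[match(snp_ids, sumstats$id)]
  data.frame(id = snp_ids, found = !is.na(p), p = p,
             nominal = !is.na(p) & p < alpha, stringsAsFactors = FALSE)
}
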