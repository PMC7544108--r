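# LD providers: pairwise r2 either computed from a genotype panel or looked
# up in a precomputed long-format table. Pairs beyond the LD window (default
# 1 Mb) or on different chromosomes are treated as r2 = 0; within the window
# a table provider must contain the pair, otherwise the caller errors rather
# than silently assuming independence.

#' LD provider backed by a reference panel
#'
#' @param panel a `reference_panel`.
#' @param window_bp LD window half-width; pairs farther apart are r2 = 0.
#' @return an object of class `ld_provider`.
#' @export
ld_from_panel <- function(panel, window_bp = 1e6) {
  stopifnot(inherits(panel, "reference_panel"))
  structure(list(type = "panel", panel = panel, window_bp = window_bp,
                 pos = stats::setNames(panel$variants$pos, panel$variants$id),
                 chrom = stats::setNames(panel$variants$chrom, panel$variants$id),
                 col = stats::setNames(seq_len(nrow(panel$variants)),
                                       panel$variants$id)),
            class = "ld_provider")
}

#' LD provider backed by a precomputed pairwise r2 table
#'
#' @param pairs data frame with columns `id_a`, `id_b`, `r2`.
#' @param variants data frame with columns `id`, `chrom`, `pos` covering all
#'   variants the provider knows about.
#' @param window_bp LD window half-width.
#' @return an object of class `ld_provider`.
#' @export
ld_from_table <- function(pairs, variants, window_bp = 1e6) {
  stopifnot(all(c("id_a", "id_b", "r2") %in% names(pairs)),
            all(c("id", "chrom", "pos") %in% names(variants)))
  key <- c(paste(pairs$id_a, pairs$id_b, sep = "\r"),
           paste(pairs$id_b, pairs$id_a, sep = "\r"))
  r2 <- stats::setNames(c(pairs$r2, pairs$r2), key)
  structure(list(type = "table", r2 = r2, window_bp = window_bp,
                 pairs = pairs,
                 pos = stats::setNames(variants$pos, variants$id),
                 chrom = stats::setNames(variants$chrom, variants$id),
                 ids = variants$id),
            class = "ld_provider")
}

#' Variant ids known to an LD provider
#' @param ld an `ld_provider`.
#' @return character vector of ids.
#' @export
ld_ids <- function(ld) {
  if (ld$type == "panel") ld$panel$variants$id else ld$ids
}

#' Pairwise r2 between two vectors of variant ids
#'
#' Vectorized over pairs. Pairs beyond the window or across chromosomes
#' return 0. For a table provider, an in-window pair absent from the table
#' returns NA (callers that require LD must treat NA as an error).
#'
#' @param ld an `ld_provider`.
#' @param id1,id2 equal-length id vectors.
#' @return numeric vector of r2 values.
#' @export
ld_r2 <- function(ld, id1, id2) {
  same_chrom <- ld$chrom[id1] == ld$chrom[id2]
  inwin <- same_chrom & abs(ld$pos[id1] - ld$pos[id2]) <= ld$window_bp
  out <- numeric(length(id1))
  ii <- which(inwin)
  if (length(ii)) {
    if (ld$type == "panel") {
      G <- ld$panel$genotypes
      c1 <- ld$col[id1[ii]]; c2 <- ld$col[id2[ii]]
      out[ii] <- vapply(seq_along(ii), function(k)
        stats::cor(G[, c1[k]], G[, c2[k]])^2, numeric(1))
    } else {
      out[ii] <- unname(ld$r2[paste(id1[ii], id2[ii], sep = "\r")])
      out[ii][id1[ii] == id2[ii]] <- 1
    }
  }
  out
}

#' r2 between one variant and many (vectorized)
#'
#' Like [ld_r2()] with a scalar first argument; computed in one pass for a
#' panel provider.
#'
#' @param ld an `ld_provider`.
#' @param id a single variant id.
#' @param ids vector of ids.
#' @return numeric vector of r2 values (NA where a table provider lacks an
#'   in-window pair).
#' @export
ld_r2_one_many <- function(ld, id, ids) {
  if (!length(ids)) return(numeric(0))
  inwin <- ld$chrom[ids] == ld$chrom[[id]] &
    abs(ld$pos[ids] - ld$pos[[id]]) <= ld$window_bp
  out <- numeric(length(ids))
  ii <- which(inwin)
  if (length(ii)) {
    if (ld$type == "panel") {
      G <- ld$panel$genotypes
      out[ii] <- as.numeric(
        stats::cor(G[, ld$col[id]], G[, ld$col[ids[ii]], drop = FALSE]))^2
    } else {
      out[ii] <- unname(ld$r2[paste(id, ids[ii], sep = "\r")])
      out[ii][ids[ii] == id] <- 1
    }
  }
  out
}

#' All LD partners of a variant above an r2 threshold
#'
#' Returns every variant known to the provider (including variants absent
#' from any summary-statistics table) whose r2 with `id` strictly exceeds
#' `r2_min`, within the LD window. The query variant itself is included
#' with r2 = 1.
#'
#' @param ld an `ld_provider`.
#' @param id a single variant id.
#' @param r2_min strict lower bound on r2.
#' @return data frame with columns `id`, `chrom`, `pos`, `r2`.
#' @export
ld_partners <- function(ld, id, r2_min) {
  cand <- ld_ids(ld)
  cand <- cand[ld$chrom[cand] == ld$chrom[[id]] &
               abs(ld$pos[cand] - ld$pos[[id]]) <= ld$window_bp]
  if (ld$type == "panel") {
    G <- ld$panel$genotypes
    r2 <- as.numeric(stats::cor(G[, ld$col[id]], G[, ld$col[cand], drop = FALSE]))^2
  } else {
    r2 <- unname(ld$r2[paste(id, cand, sep = "\r")])
    r2[cand == id] <- 1
    r2[is.na(r2)] <- 0  # absent pairs in a table provider carry no LD claim
  }
  keep <- r2 > r2_min
  data.frame(id = cand[keep], chrom = unname(ld$chrom[cand[keep]]),
             pos = unname(ld$pos[cand[keep]]), r2 = r2[keep],
             stringsAsFactors = FALSE)
}
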