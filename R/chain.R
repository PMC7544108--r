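# Cross-assembly interval projection through UCSC chain alignments, with the
# minimum-matched-bases acceptance rule used for mouse-to-human liftover of
# open chromatin regions.

#' Construct a chain map from aligned blocks
#'
#' A chain map is a set of chains; each chain has a score and a list of
#' gapless aligned blocks with equal lengths on the source and target
#' assemblies (plus-strand only). Blocks within a chain must be ordered and
#' non-overlapping on both sides.
#'
#' @param blocks data frame with columns `chain_id`, `score`, `src_chrom`,
#'   `src_start` (0-based), `src_end`, `tgt_chrom`, `tgt_start`, `tgt_end`.
#' @param src_sizes,tgt_sizes named chromosome lengths (needed to write the
#'   UCSC chain format; inferred loosely if omitted).
#' @return object of class `chain_map`.
#' @export
chain_map <- function(blocks, src_sizes = NULL, tgt_sizes = NULL) {
  need <- c("chain_id", "score", "src_chrom", "src_start", "src_end",
            "tgt_chrom", "tgt_start", "tgt_end")
  stopifnot(all(need %in% names(blocks)))
  if (any(blocks$src_end - blocks$src_start !=
          blocks$tgt_end - blocks$tgt_start))
    stop("aligned block lengths must be equal on both assemblies")
  blocks <- blocks[order(blocks$chain_id, blocks$src_start), , drop = FALSE]
  for (cid in unique(blocks$chain_id)) {
    b <- blocks[blocks$chain_id == cid, ]
    if (length(unique(b$src_chrom)) != 1 || length(unique(b$tgt_chrom)) != 1)
      stop("a chain must stay on one chromosome pair")
    if (nrow(b) > 1 && (any(diff(b$src_start) <= 0) ||
                        any(b$src_start[-1] < b$src_end[-nrow(b)]) ||
                        any(b$tgt_start[-1] < b$tgt_end[-nrow(b)])))
      stop("blocks must be ordered and non-overlapping within a chain")
  }
  if (is.null(src_sizes)) {
    src_sizes <- tapply(blocks$src_end, blocks$src_chrom, max) * 2
    src_sizes <- stats::setNames(as.numeric(src_sizes), names(src_sizes))
  }
  if (is.null(tgt_sizes)) {
    tgt_sizes <- tapply(blocks$tgt_end, blocks$tgt_chrom, max) * 2
    tgt_sizes <- stats::setNames(as.numeric(tgt_sizes), names(tgt_sizes))
  }
  rownames(blocks) <- NULL
  structure(list(blocks = blocks, src_sizes = src_sizes,
                 tgt_sizes = tgt_sizes),
            class = "chain_map")
}

#' Identity chain over a set of chromosomes
#'
#' @param chrom_lengths named vector of chromosome lengths (bp).
#' @param score chain score.
#' @return a `chain_map` mapping every chromosome to itself unchanged.
#' @export
identity_chain <- function(chrom_lengths, score = 1e6) {
  blocks <- data.frame(
    chain_id = seq_along(chrom_lengths),
    score = score,
    src_chrom = names(chrom_lengths), src_start = 0,
    src_end = as.numeric(chrom_lengths),
    tgt_chrom = names(chrom_lengths), tgt_start = 0,
    tgt_end = as.numeric(chrom_lengths),
    stringsAsFactors = FALSE
  )
  chain_map(blocks, chrom_lengths, chrom_lengths)
}

#' Project intervals through a chain map
#'
#' Each peak is projected through the aligned blocks of the single
#' best-scoring chain overlapping it (peaks spanning several chains are
#' mapped via that chain only and reported). The peak is accepted iff the
#' fraction of its bases that project is at least `min_match`; the output
#' interval spans the projected bases on the target assembly.
#'
#' @param chain a `chain_map`.
#' @param peaks `GRanges` on the source assembly (1-based, closed).
#' @param min_match minimum mapped-base fraction for acceptance.
#' @return list with `mapped` (`GRanges` on the target with metadata
#'   `mapped_fraction` and `src_index`) and `report` (per-peak data frame:
#'   `src_index`, `status` in {mapped, below_min_match, no_chain},
#'   `mapped_fraction`, `n_chains` overlapped).
#' @export
map_intervals <- function(chain, peaks, min_match = 0.5) {
  stopifnot(inherits(chain, "chain_map"))
  bl <- chain$blocks
  # 0-based half-open peak coordinates
  ps <- GenomicRanges::start(peaks) - 1
  pe <- GenomicRanges::end(peaks)
  pchrom <- as.character(GenomicRanges::seqnames(peaks))
  chain_score <- tapply(bl$score, bl$chain_id, max)

  n <- length(peaks)
  status <- character(n); frac <- numeric(n); nch <- integer(n)
  out_chrom <- character(n); out_s <- numeric(n); out_e <- numeric(n)
  bl_gr <- GenomicRanges::GRanges(bl$src_chrom,
                                  IRanges::IRanges(bl$src_start + 1, bl$src_end))
  pk_gr <- GenomicRanges::GRanges(pchrom, IRanges::IRanges(ps + 1, pe))
  hits <- GenomicRanges::findOverlaps(pk_gr, bl_gr, ignore.strand = TRUE)
  hl <- split(S4Vectors::subjectHits(hits), S4Vectors::queryHits(hits))

  for (i in seq_len(n)) {
    rows <- hl[[as.character(i)]]
    if (is.null(rows)) { status[i] <- "no_chain"; next }
    cids <- unique(bl$chain_id[rows])
    nch[i] <- length(cids)
    best <- cids[which.max(chain_score[as.character(cids)])]
    rows <- rows[bl$chain_id[rows] == best]
    os <- pmax(ps[i], bl$src_start[rows])
    oe <- pmin(pe[i], bl$src_end[rows])
    mapped <- sum(oe - os)
    frac[i] <- mapped / (pe[i] - ps[i])
    if (frac[i] >= min_match && mapped > 0) {
      status[i] <- "mapped"
      proj_s <- bl$tgt_start[rows] + (os - bl$src_start[rows])
      proj_e <- bl$tgt_start[rows] + (oe - bl$src_start[rows])
      out_chrom[i] <- bl$tgt_chrom[rows[1]]
      out_s[i] <- min(proj_s)
      out_e[i] <- max(proj_e)
    } else status[i] <- "below_min_match"
  }
  ok <- status == "mapped"
  mapped_gr <- GenomicRanges::GRanges(
    out_chrom[ok], IRanges::IRanges(out_s[ok] + 1, out_e[ok]))
  mapped_gr$mapped_fraction <- frac[ok]
  mapped_gr$src_index <- which(ok)
  list(mapped = mapped_gr,
       report = data.frame(src_index = seq_len(n), status = status,
                           mapped_fraction = frac, n_chains = nch,
                           stringsAsFactors = FALSE))
}

#' Write a chain map in UCSC chain format
#'
#' Plus-strand chains only: a header line
#' `chain score tName tSize tStrand tStart tEnd qName qSize qStrand qStart
#' qEnd id` followed by `size dt dq` block lines, where the t side is the
#' source assembly (the one lifted from) and the q side the target.
#'
#' @param chain a `chain_map`.
#' @param path output file.
#' @export
write_chain <- function(chain, path) {
  con <- file(path, "w")
  on.exit(close(con))
  bl <- chain$blocks
  for (cid in unique(bl$chain_id)) {
    b <- bl[bl$chain_id == cid, , drop = FALSE]
    hdr <- sprintf("chain %d %s %d + %d %d %s %d + %d %d %d",
                   as.integer(b$score[1]), b$src_chrom[1],
                   as.integer(chain$src_sizes[[b$src_chrom[1]]]),
                   as.integer(min(b$src_start)), as.integer(max(b$src_end)),
                   b$tgt_chrom[1],
                   as.integer(chain$tgt_sizes[[b$tgt_chrom[1]]]),
                   as.integer(min(b$tgt_start)), as.integer(max(b$tgt_end)),
                   as.integer(cid))
    writeLines(hdr, con)
    sizes <- b$src_end - b$src_start
    if (nrow(b) > 1) {
      dt <- b$src_start[-1] - b$src_end[-nrow(b)]
      dq <- b$tgt_start[-1] - b$tgt_end[-nrow(b)]
      writeLines(paste(sizes[-nrow(b)], dt, dq), con)
    }
    writeLines(c(as.character(sizes[nrow(b)]), ""), con)
  }
}

#' Read a UCSC chain file (plus-strand chains)
#'
#' @param path chain file.
#' @return a `chain_map`.
#' @export
read_chain <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  out <- list(); src_sizes <- c(); tgt_sizes <- c()
  i <- 1
  while (i <= length(lines)) {
    f <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (f[1] != "chain") stop("malformed chain file at line ", i)
    score <- as.numeric(f[2])
    s_chrom <- f[3]; s_size <- as.numeric(f[4]); s_pos <- as.numeric(f[6])
    t_chrom <- f[8]; t_size <- as.numeric(f[9]); t_pos <- as.numeric(f[11])
    cid <- if (length(f) >= 13) as.integer(f[13]) else length(out) + 1L
    if (f[5] != "+" || f[10] != "+")
      stop("only plus-strand chains are supported")
    src_sizes[s_chrom] <- s_size; tgt_sizes[t_chrom] <- t_size
    i <- i + 1
    repeat {
      g <- as.numeric(strsplit(trimws(lines[i]), "\\s+")[[1]])
      out[[length(out) + 1]] <- data.frame(
        chain_id = cid, score = score, src_chrom = s_chrom,
        src_start = s_pos, src_end = s_pos + g[1],
        tgt_chrom = t_chrom, tgt_start = t_pos, tgt_end = t_pos + g[1])
      i <- i + 1
      if (length(g) == 1) break
      s_pos <- s_pos + g[1] + g[2]
      t_pos <- t_pos + g[1] + g[3]
    }
  }
  chain_map(do.call(rbind, out), src_sizes, tgt_sizes)
}
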