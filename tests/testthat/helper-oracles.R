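# Independent brute-force oracles used across the suite. These deliberately
# re-derive results by the most naive route available (exhaustive loops,
# enumeration, closed forms) and share no code with the implementation.

# naive greedy clumping: double loop over significant SNPs in (p, pos) order
oracle_clump <- function(sumstats, r2mat, p_threshold, r2_independence) {
  sig <- sumstats[sumstats$p < p_threshold, , drop = FALSE]
  sig <- sig[order(sig$p, sig$chrom, sig$pos), , drop = FALSE]
  leads <- character(0)
  for (i in seq_len(nrow(sig))) {
    absorbed <- FALSE
    for (l in leads) {
      if (r2mat[sig$id[i], l] >= r2_independence) { absorbed <- TRUE; break }
    }
    if (!absorbed) leads <- c(leads, sig$id[i])
  }
  leads
}

# union-find locus partition oracle over lead LD blocks
oracle_loci_partition <- function(leads, all_ids, pos, r2mat, r2_membership,
                                  merge_bp) {
  blocks <- lapply(leads, function(l) {
    mem <- all_ids[r2mat[all_ids, l] > r2_membership | all_ids == l]
    c(min(pos[mem]), max(pos[mem]))
  })
  k <- length(leads)
  # repeated pairwise merging (quadratic, fine at test scale)
  comp <- seq_len(k)
  repeat {
    changed <- FALSE
    for (i in seq_len(k)) for (j in seq_len(k)) if (comp[i] != comp[j]) {
      gap <- max(blocks[[i]][1], blocks[[j]][1]) -
        min(blocks[[i]][2], blocks[[j]][2])
      if (gap <= merge_bp) {
        comp[comp == comp[j]] <- comp[i]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  comp
}

# exhaustive candidate expansion oracle
oracle_candidates <- function(leads, all_ids, r2mat, r2_candidate) {
  out <- list()
  for (l in leads) {
    ids <- all_ids[r2mat[all_ids, l] > r2_candidate | all_ids == l]
    for (id in ids) {
      prev <- out[[id]]
      if (is.null(prev) || r2mat[id, l] > prev$r2 ||
          (id == l && prev$r2 < 1))
        out[[id]] <- list(lead = l, r2 = if (id == l) 1 else r2mat[id, l])
    }
  }
  out
}

# naive interval join: SNP in gene body, closed interval
oracle_snp_gene_join <- function(sumstats, genes) {
  res <- NULL
  for (i in seq_len(nrow(genes))) for (j in seq_len(nrow(sumstats))) {
    if (genes$chrom[i] == sumstats$chrom[j] &&
        sumstats$pos[j] >= genes$start[i] && sumstats$pos[j] <= genes$end[i])
      res <- rbind(res, data.frame(gene_id = genes$gene_id[i],
                                   id = sumstats$id[j]))
  }
  res
}

# exact two-sided Wilcoxon rank-sum p by full enumeration of group
# assignments (group sizes <= 8)
oracle_wilcox_exact <- function(x, y) {
  all_v <- c(x, y)
  n1 <- length(x)
  r <- rank(all_v)
  w_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combs <- utils::combn(length(all_v), n1)
  w_all <- apply(combs, 2, function(ii) sum(r[ii]) - n1 * (n1 + 1) / 2)
  mu <- mean(w_all)
  p <- mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-9)
  min(p, 1)
}

# brute-force Benjamini-Hochberg step-up
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- numeric(n)
  prev <- 1
  for (i in n:1) {
    q[o[i]] <- min(prev, p[o[i]] * n / i)
    prev <- q[o[i]]
  }
  q
}

# exact HWE p by direct multinomial enumeration over heterozygote counts
oracle_hwe <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  n_a <- 2 * n_aa + n_ab
  lgp <- function(h) {
    na_ <- (n_a - h) / 2; nb_ <- (2 * n - n_a - h) / 2
    lfactorial(n) - lfactorial(na_) - lfactorial(h) - lfactorial(nb_) +
      h * log(2) + lfactorial(n_a) + lfactorial(2 * n - n_a) -
      lfactorial(2 * n)
  }
  hets <- seq(n_a %% 2, min(n_a, 2 * n - n_a), by = 2)
  pr <- exp(sapply(hets, lgp))
  obs <- pr[hets == n_ab]
  sum(pr[pr <= obs * (1 + 1e-12)])
}

# naive rule-application oracle for tier prioritization
oracle_prioritize <- function(coding, proximal, distal) {
  loci <- sort(unique(c(coding$locus_id, proximal$locus_id,
                        distal$locus_id)))
  res <- NULL
  for (l in loci) {
    cg <- unique(stats::na.omit(coding$gene_id[coding$locus_id == l]))
    pg <- unique(proximal$gene_id[proximal$locus_id == l])
    dg <- unique(distal$gene_id[distal$locus_id == l])
    if (length(cg)) sel <- data.frame(locus_id = l, gene_id = cg,
                                      tier = "coding")
    else if (length(pg)) sel <- data.frame(locus_id = l, gene_id = pg,
                                           tier = "proximal")
    else if (length(dg)) sel <- data.frame(locus_id = l, gene_id = dg,
                                           tier = "distal")
    else next
    res <- rbind(res, sel)
  }
  if (is.null(res)) return(res)
  res <- res[order(res$locus_id, res$gene_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# pairwise r2 matrix of a panel (dense, for small instances)
panel_r2_matrix <- function(panel) {
  r <- stats::cor(panel$genotypes)^2
  dimnames(r) <- list(panel$variants$id, panel$variants$id)
  r
}
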