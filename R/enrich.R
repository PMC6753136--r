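#' Hypergeometric feature enrichment of a CpG or SNP set
#'
#' For each annotation, overlap of the foreground set with the annotated
#' members of the universe is tested two-sided (doubled smaller
#' hypergeometric tail, capped at 1). Fold = (k/n) / (K/N). A result is
#' significant only when the fold passes the gates (> fold_hi or < fold_lo)
#' AND p is below the Bonferroni-corrected alpha / n_annotations.
#'
#' @param foreground ids, a subset of universe.
#' @param universe all ids.
#' @param annotations named list of id vectors (annotated universe members).
#' @param fold_hi,fold_lo fold-change gates (1.2 / 0.8).
#' @param alpha experiment-wide alpha.
#' @param n_annotations Bonferroni divisor (defaults to
#'   \code{length(annotations)}).
#' @return data.frame: annotation_id, n_universe, n_annotated, n_foreground,
#'   n_overlap, fold, p, p_bonferroni, significant.
#' @export
hypergeom_enrichment <- function(foreground, universe, annotations,
                                 fold_hi = 1.2, fold_lo = 0.8, alpha = 0.05,
                                 n_annotations = length(annotations)) {
  if (!all(foreground %in% universe)) {
    stop("input error: foreground must be a subset of the universe")
  }
  N <- length(unique(universe))
  fg <- unique(foreground)
  n <- length(fg)
  rows <- lapply(names(annotations), function(a) {
    ann <- intersect(unique(annotations[[a]]), universe)
    K <- length(ann)
    k <- length(intersect(fg, ann))
    if (n == 0 || K == 0) {
      return(data.frame(annotation_id = a, n_universe = N, n_annotated = K,
                        n_foreground = n, n_overlap = k, fold = NA_real_,
                        p = NA_real_, p_bonferroni = NA_real_,
                        significant = FALSE, stringsAsFactors = FALSE))
    }
    fold <- (k / n) / (K / N)
    upper <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    lower <- stats::phyper(k, K, N - K, n)
    p <- min(1, 2 * min(upper, lower))
    pb <- min(1, p * n_annotations)
    sig <- (fold > fold_hi || fold < fold_lo) && p < alpha / n_annotations
    data.frame(annotation_id = a, n_universe = N, n_annotated = K,
               n_foreground = n, n_overlap = k, fold = fold, p = p,
               p_bonferroni = pb, significant = sig, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Minor-allele-frequency bin for permutation matching
#'
#' Four left-open right-closed bins: (0.01, 0.05], (0.05, 0.1], (0.1, 0.2],
#' (0.2, 0.5]. Vectorized.
#'
#' @param maf minor allele frequencies, each in (0.01, 0.5].
#' @return integer bin indices 1..4.
#' @export
maf_bin <- function(maf) {
  if (any(maf <= 0.01 | maf > 0.5)) {
    stop("out-of-range error: MAF must lie in (0.01, 0.5]")
  }
  findInterval(maf, c(0.01, 0.05, 0.1, 0.2), left.open = TRUE)
}

# Overlap counter: number of SNP positions falling in half-open [start,end)
# BED intervals of one state (intervals merged per chromosome first).
interval_overlap_count <- function(chrom, pos, intervals) {
  total <- 0L
  for (cc in unique(chrom)) {
    iv <- intervals[intervals$chrom == cc, , drop = FALSE]
    if (nrow(iv) == 0) next
    iv <- iv[order(iv$start), , drop = FALSE]
    # merge overlapping intervals
    merged_s <- iv$start[1]; merged_e <- iv$end[1]
    ss <- c(); ee <- c()
    if (nrow(iv) > 1) {
      for (r in 2:nrow(iv)) {
        if (iv$start[r] <= merged_e) {
          merged_e <- max(merged_e, iv$end[r])
        } else {
          ss <- c(ss, merged_s); ee <- c(ee, merged_e)
          merged_s <- iv$start[r]; merged_e <- iv$end[r]
        }
      }
    }
    ss <- c(ss, merged_s); ee <- c(ee, merged_e)
    p <- pos[chrom == cc]
    j <- findInterval(p, ss)
    total <- total + sum(j >= 1 & p < ee[pmax(j, 1)])
  }
  total
}

#' MAF-matched permutation enrichment over chromatin-state intervals
#'
#' The observed overlap of the tested SNPs with each state's intervals is
#' compared against \code{n_perm} random SNP sets drawn from the pool with
#' the tested set's exact per-MAF-bin counts. Fold = observed overlap /
#' mean permuted overlap; the empirical enrichment p is
#' (1 + #permutations >= observed) / (n_perm + 1), mirrored for depletion,
#' combined two-sided by doubling the smaller tail, and BH-FDR corrected
#' across states. SNP positions are points inside half-open [start, end)
#' BED intervals.
#'
#' @param test_snps data.frame: snp_id, chrom, pos, maf.
#' @param pool_snps candidate pool (excluding the tested SNPs), same columns.
#' @param state_intervals named list of data.frames (chrom, start, end).
#' @param n_perm number of permutations (1000).
#' @param seed RNG seed.
#' @return data.frame: annotation_id, n_overlap, mean_perm_overlap, fold,
#'   p_enrich, p_deplete, p, fdr, significant.
#' @export
maf_matched_permutation <- function(test_snps, pool_snps, state_intervals,
                                    n_perm = 1000L, seed = 1L) {
  if (any(test_snps$snp_id %in% pool_snps$snp_id)) {
    pool_snps <- pool_snps[!pool_snps$snp_id %in% test_snps$snp_id, , drop = FALSE]
  }
  tb <- maf_bin(test_snps$maf)
  pb <- maf_bin(pool_snps$maf)
  need <- table(factor(tb, levels = 1:4))
  have <- table(factor(pb, levels = 1:4))
  short <- which(have < need)
  if (length(short) > 0) {
    stop("insufficient pool SNPs in MAF bin(s): ",
         paste(short, collapse = ", "))
  }
  set.seed(seed)
  pool_by_bin <- split(seq_len(nrow(pool_snps)), factor(pb, levels = 1:4))
  perm_idx <- lapply(seq_len(n_perm), function(i) {
    unlist(lapply(1:4, function(b) {
      if (need[b] == 0) return(integer(0))
      sample(pool_by_bin[[b]], need[b])
    }), use.names = FALSE)
  })
  rows <- lapply(names(state_intervals), function(st) {
    iv <- state_intervals[[st]]
    obs <- interval_overlap_count(test_snps$chrom, test_snps$pos, iv)
    perm <- vapply(perm_idx, function(ix) {
      interval_overlap_count(pool_snps$chrom[ix], pool_snps$pos[ix], iv)
    }, numeric(1))
    mu <- mean(perm)
    fold <- if (mu > 0) obs / mu else NA_real_
    p_en <- (1 + sum(perm >= obs)) / (n_perm + 1)
    p_de <- (1 + sum(perm <= obs)) / (n_perm + 1)
    data.frame(annotation_id = st, n_overlap = obs, mean_perm_overlap = mu,
               fold = fold, p_enrich = p_en, p_deplete = p_de,
               p = min(1, 2 * min(p_en, p_de)), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- stats::p.adjust(out$p, method = "BH")
  out$significant <- out$fdr < 0.05
  attr(out, "perm_bin_counts") <- need
  out
}
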