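#' eQTM scan: pairwise CpG-expression association
#'
#' Linear regression of every expression residual on every methylation
#' residual (both pre-adjusted for covariates and principal components
#' upstream), with the Bonferroni threshold computed from the realized
#' scan dimensions alpha / (n_cpg * n_gene). A pair is cis when the CpG
#' lies within 1 Mb of the gene's TSS.
#'
#' @param meth_resid samples x CpGs residual matrix.
#' @param expr_resid samples x genes residual matrix.
#' @param cpg_map data.frame: cpg_id, chrom, pos.
#' @param tss_map data.frame: gene_id, chrom, tss.
#' @param alpha experiment-wide alpha (default 0.05).
#' @param cis_window_bp cis window around the TSS (1 Mb).
#' @return data.frame (cpg_id, gene_id, beta, se, t, p, cis_flag,
#'   significant) with attributes \code{threshold} and \code{n_tests}.
#' @export
eqtm_scan <- function(meth_resid, expr_resid, cpg_map, tss_map, alpha = 0.05,
                      cis_window_bp = 1e6) {
  M <- as.matrix(meth_resid); E <- as.matrix(expr_resid)
  stopifnot(nrow(M) == nrow(E))
  n <- nrow(M)
  keep_m <- apply(M, 2, stats::sd) > 0
  keep_e <- apply(E, 2, stats::sd) > 0
  M <- M[, keep_m, drop = FALSE]; E <- E[, keep_e, drop = FALSE]
  cpg_map <- cpg_map[keep_m, , drop = FALSE]
  tss_map <- tss_map[keep_e, , drop = FALSE]
  Mc <- scale(M, scale = FALSE); Ec <- scale(E, scale = FALSE)
  Ms <- scale(Mc, center = FALSE, scale = sqrt(colSums(Mc^2)))
  Es <- scale(Ec, center = FALSE, scale = sqrt(colSums(Ec^2)))
  CC <- crossprod(Ms, Es)
  CC[CC >= 1] <- 1 - 1e-12; CC[CC <= -1] <- -1 + 1e-12
  df <- n - 2L
  TT <- CC * sqrt(df / (1 - CC^2))
  P <- 2 * stats::pt(-abs(TT), df = df)
  n_tests <- ncol(M) * ncol(E)
  thr <- alpha / n_tests
  idx <- expand.grid(i = seq_len(ncol(M)), j = seq_len(ncol(E)))
  sd_m <- sqrt(colSums(Mc^2)); sd_e <- sqrt(colSums(Ec^2))
  beta <- CC[cbind(idx$i, idx$j)] * sd_e[idx$j] / sd_m[idx$i]
  tv <- TT[cbind(idx$i, idx$j)]
  cis <- cpg_map$chrom[idx$i] == tss_map$chrom[idx$j] &
    abs(cpg_map$pos[idx$i] - tss_map$tss[idx$j]) <= cis_window_bp
  out <- data.frame(cpg_id = cpg_map$cpg_id[idx$i],
                    gene_id = tss_map$gene_id[idx$j],
                    beta = beta, se = beta / tv, t = tv,
                    p = P[cbind(idx$i, idx$j)], cis_flag = cis,
                    significant = P[cbind(idx$i, idx$j)] < thr,
                    stringsAsFactors = FALSE)
  attr(out, "threshold") <- thr
  attr(out, "n_tests") <- n_tests
  out
}

#' Detect trans-meQTL hotspots
#'
#' Counts distinct trans target CpGs per SNP over the final significant
#' trans records, merges SNPs within 1 Mb of each other or in LD
#' (r-squared >= 0.2) into one hotspot, names the member with the largest
#' target count (ties: lowest best p, then position) the index SNP, and
#' retains hotspots whose index targets at least \code{min_targets} CpGs.
#'
#' @param trans_records final-stage significant trans association records.
#' @param genotypes LD reference \code{genotype_matrix}.
#' @param min_targets minimum index target count (30).
#' @param merge_bp positional merge radius (1 Mb).
#' @param merge_r2 LD merge threshold (0.2).
#' @return list of hotspots: hotspot_id, index_snp, member_snps,
#'   target_cpgs, n_targets.
#' @export
detect_hotspots <- function(trans_records, genotypes, min_targets = 30L,
                            merge_bp = 1e6, merge_r2 = 0.2) {
  tr <- trans_records[trans_records$class %in% c("trans_intra", "trans_inter"), ,
                      drop = FALSE]
  if (nrow(tr) == 0) return(list())
  snps <- sort(unique(tr$snp_id))
  smap <- genotypes$map[match(snps, genotypes$map$snp_id), ]
  targets <- lapply(snps, function(s) unique(tr$cpg_id[tr$snp_id == s]))
  best_p <- vapply(snps, function(s) min(tr$p[tr$snp_id == s]), numeric(1))
  n <- length(snps)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (a in seq_len(n)) for (b in seq_len(n)) {
    if (b <= a) next
    near <- smap$chrom[a] == smap$chrom[b] &&
      abs(smap$pos[a] - smap$pos[b]) <= merge_bp
    linked <- FALSE
    if (!near) {
      r2 <- suppressWarnings(stats::cor(genotypes$dosage[, snps[a]],
                                        genotypes$dosage[, snps[b]]))^2
      linked <- !is.na(r2) && r2 >= merge_r2
    }
    if (near || linked) {
      ra <- find(a); rb <- find(b)
      if (ra != rb) parent[rb] <- ra
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  comps <- split(seq_len(n), roots)
  out <- list()
  for (comp in comps) {
    cnt <- lengths(targets[comp])
    ord <- order(-cnt, best_p[comp], smap$pos[comp])
    idx <- comp[ord[1]]
    if (cnt[ord[1]] < min_targets) next
    out[[length(out) + 1L]] <- list(
      hotspot_id = sprintf("H%d", length(out) + 1L),
      index_snp = snps[idx], member_snps = snps[comp],
      target_cpgs = targets[[idx]], n_targets = length(targets[[idx]]))
  }
  out
}

#' Link a hotspot to nearby cis-eGenes
#'
#' Returns genes with a significant cis-eQTL among the hotspot's member
#' SNPs, requiring the gene's TSS within the window of the member SNP.
#'
#' @param hotspot one element of \code{\link{detect_hotspots}} output.
#' @param eqtl_records significant cis-eQTL records (snp_id, gene_id;
#'   optionally pos_snp and tss for the window check).
#' @param tss_map data.frame gene_id, chrom, tss (for the window check).
#' @param genotypes \code{genotype_matrix} (SNP positions).
#' @param window_bp cis window (1 Mb).
#' @return character vector of linked eGene ids.
#' @export
link_hotspot_egenes <- function(hotspot, eqtl_records, tss_map, genotypes,
                                window_bp = 1e6) {
  if (nrow(eqtl_records) == 0) return(character(0))
  rec <- eqtl_records[eqtl_records$snp_id %in% hotspot$member_snps, , drop = FALSE]
  if (nrow(rec) == 0) return(character(0))
  smap <- genotypes$map
  keep <- vapply(seq_len(nrow(rec)), function(r) {
    i <- match(rec$snp_id[r], smap$snp_id)
    j <- match(rec$gene_id[r], tss_map$gene_id)
    !is.na(i) && !is.na(j) && smap$chrom[i] == tss_map$chrom[j] &&
      abs(smap$pos[i] - tss_map$tss[j]) <= window_bp
  }, logical(1))
  sort(unique(rec$gene_id[keep]))
}

#' Enrichment of hotspot target CpGs among eGene-associated CpGs
#'
#' Associates each eGene's expression with every CpG (Bonferroni-corrected
#' at alpha over the realized scan size), then tests by hypergeometric
#' enrichment whether the hotspot's trans target CpGs are over-represented
#' among the eGene-associated CpGs.
#'
#' @param egene_expr samples x eGenes expression (residual) matrix.
#' @param target_cpgs hotspot target CpG ids.
#' @param meth_resid samples x CpGs methylation residual matrix.
#' @param cpg_map CpG map (ids must match meth_resid columns).
#' @param alpha scan alpha.
#' @return list(assoc = association table, fold, p_hyper,
#'   egene_cpgs = eGene-associated CpG ids).
#' @export
egene_transcpg_enrichment <- function(egene_expr, target_cpgs, meth_resid,
                                      cpg_map, alpha = 0.05) {
  if (length(target_cpgs) == 0) {
    return(list(assoc = NULL, fold = NA_real_, p_hyper = NA_real_,
                egene_cpgs = character(0)))
  }
  gm <- data.frame(gene_id = colnames(egene_expr),
                   chrom = NA_character_, tss = NA_real_,
                   stringsAsFactors = FALSE)
  assoc <- eqtm_scan(meth_resid, egene_expr, cpg_map, gm, alpha = alpha)
  egene_cpgs <- unique(assoc$cpg_id[assoc$significant])
  res <- hypergeom_enrichment(foreground = target_cpgs,
                              universe = cpg_map$cpg_id,
                              annotations = list(egene_assoc = egene_cpgs))
  list(assoc = assoc, fold = res$fold[1], p_hyper = res$p[1],
       egene_cpgs = egene_cpgs)
}
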