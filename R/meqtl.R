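#' Scan configuration for meQTL mapping
#'
#' Defaults follow standard practice for blood meQTL mapping: a 1 Mb cis
#' window, long-range cis from 1 to 5 Mb (excluded from both final classes),
#' liberal prefilter thresholds of 1e-6 (cis) and 1e-10 (trans), and
#' Bonferroni final thresholds alpha / n_tests computed per class.
#'
#' @param cis_window,long_range_limit window sizes in bp (inclusive bounds).
#' @param prefilter_cis_p,prefilter_trans_p stage-one retention thresholds.
#' @param alpha experiment-wide type-I error rate.
#' @param n_cis_tests,n_trans_tests test-universe sizes used for the final
#'   Bonferroni thresholds (NULL = use realized counts from the scan).
#' @param maf_min minor-allele-frequency filter.
#' @return object of class \code{scan_config}.
#' @export
scan_config <- function(cis_window = 1e6, long_range_limit = 5e6,
                        prefilter_cis_p = 1e-6, prefilter_trans_p = 1e-10,
                        alpha = 0.05, n_cis_tests = NULL, n_trans_tests = NULL,
                        maf_min = 0.01) {
  if (cis_window >= long_range_limit) stop("cis_window must be below long_range_limit")
  structure(list(cis_window = cis_window, long_range_limit = long_range_limit,
                 prefilter_cis_p = prefilter_cis_p,
                 prefilter_trans_p = prefilter_trans_p, alpha = alpha,
                 n_cis_tests = n_cis_tests, n_trans_tests = n_trans_tests,
                 maf_min = maf_min), class = "scan_config")
}

#' Classify a SNP-CpG pair by genomic distance
#'
#' cis: same chromosome within the cis window (inclusive);
#' long_range_cis: beyond the cis window but within the long-range limit;
#' trans_intra: same chromosome beyond the limit; trans_inter: different
#' chromosomes. Vectorized over all arguments.
#'
#' @param chrom_snp,pos_snp,chrom_cpg,pos_cpg positions (1-based bp).
#' @param config a \code{\link{scan_config}}.
#' @return character vector of classes.
#' @export
classify_pair <- function(chrom_snp, pos_snp, chrom_cpg, pos_cpg,
                          config = scan_config()) {
  d <- abs(pos_snp - pos_cpg)
  same <- chrom_snp == chrom_cpg
  ifelse(!same, "trans_inter",
         ifelse(d <= config$cis_window, "cis",
                ifelse(d <= config$long_range_limit, "long_range_cis",
                       "trans_intra")))
}

# Eigen-rotation of a kinship matrix for fast single-component LMM fits.
kinship_rotation <- function(K) {
  E <- eigen((K + t(K)) / 2, symmetric = TRUE)
  d <- pmax(E$values, 0)
  list(U = E$vectors, d = d, degenerate = (max(d) - min(d)) < 1e-8)
}

# Profiled-REML fit of y ~ X with one kinship component, in rotated space.
# Returns the last fixed-effect coefficient's Wald test (plus all pieces).
lmm_rotated_fit <- function(yr, Xr, d, degenerate) {
  n <- length(yr); p <- ncol(Xr)
  gls <- function(w) {
    WX <- Xr * w
    XtWX <- crossprod(Xr, WX)
    bet <- solve(XtWX, crossprod(WX, yr))
    r <- yr - Xr %*% bet
    rss <- sum(w * r * r)
    list(bet = bet, XtWX = XtWX, rss = rss, r = r)
  }
  if (degenerate) {
    f <- gls(rep(1, n)); delta <- 0
  } else {
    nll <- function(logd) {
      w <- 1 / (exp(logd) * d + 1)
      f <- gls(w)
      0.5 * ((n - p) * log(f$rss) - sum(log(w)) +
               determinant(f$XtWX)$modulus[1])
    }
    opt <- stats::optimize(nll, c(-12, 12), tol = 1e-8)
    delta <- exp(opt$minimum)
    f <- gls(1 / (delta * d + 1))
  }
  sigma2e <- f$rss / (n - p)
  covb <- sigma2e * solve(f$XtWX)
  se <- sqrt(diag(covb))
  tval <- drop(f$bet) / se
  list(beta = drop(f$bet), se = se, t = tval,
       p = 2 * stats::pt(-abs(tval), df = n - p),
       delta = delta, sigma2e = sigma2e, resid_rot = drop(f$r),
       w = if (degenerate) rep(1, n) else 1 / (delta * d + 1))
}

#' Pre-adjust methylation for covariates and pedigree
#'
#' Step one of the two-step scan: per CpG, an LME with the fixed covariates
#' and a kinship random effect is fitted (single-component REML via
#' eigen-rotation) and the conditional residuals retained. When the kinship
#' matrix is degenerate (all samples exchangeable, K proportional to I) the
#' random effect is unidentifiable and the residuals collapse to ordinary
#' least-squares residuals; per-CpG fit failures are downgraded the same
#' way and counted in the \code{downgraded} attribute.
#'
#' @param cpgs a \code{cpg_matrix} or plain matrix.
#' @param covariates covariate matrix or NULL (intercept always included).
#' @param kinship kinship matrix.
#' @return residual matrix (samples x CpGs) with attribute \code{cpg_map}.
#' @export
residualize_methylation <- function(cpgs, covariates = NULL, kinship) {
  M <- if (inherits(cpgs, "cpg_matrix")) cpgs$beta else as.matrix(cpgs)
  n <- nrow(M)
  X <- cbind(intercept = rep(1, n), covariates)
  qx <- qr(X)
  rot <- kinship_rotation(kinship)
  Xr <- crossprod(rot$U, X)
  out <- matrix(NA_real_, n, ncol(M), dimnames = dimnames(M))
  downgraded <- 0L
  for (j in seq_len(ncol(M))) {
    y <- M[, j]
    if (rot$degenerate) {
      out[, j] <- qr.resid(qx, y)
      next
    }
    fit <- tryCatch(lmm_rotated_fit(drop(crossprod(rot$U, y)), Xr, rot$d,
                                    FALSE),
                    error = function(e) NULL)
    if (is.null(fit)) {
      out[, j] <- qr.resid(qx, y)
      downgraded <- downgraded + 1L
    } else {
      # conditional residuals y - Xb - u = sigma2e * V^-1 (y - Xb)
      out[, j] <- drop(rot$U %*% (fit$w * fit$resid_rot))
    }
  }
  attr(out, "cpg_map") <- if (inherits(cpgs, "cpg_matrix")) cpgs$map else NULL
  attr(out, "downgraded") <- downgraded
  out
}

#' Fast stage-one linear scan of residuals against SNP dosages
#'
#' Simple linear regression of every CpG residual on every SNP dosage,
#' vectorized through correlation algebra. When \code{covariates} are
#' supplied, dosages (and residuals) are projected off them and the
#' regression degrees of freedom reduced accordingly, making the stage-one
#' t statistic identical to the covariate-adjusted joint fit on unrelated
#' samples. Only pairs passing the class-specific prefilter (cis 1e-6;
#' everything else at the trans threshold) are retained.
#'
#' @param residuals residual matrix from \code{\link{residualize_methylation}}
#'   (attribute \code{cpg_map} required, or pass \code{cpg_map}).
#' @param genotypes a \code{genotype_matrix}.
#' @param config a \code{\link{scan_config}}.
#' @param covariates optional covariates to project out of the dosages.
#' @param cpg_map CpG map override (cpg_id, chrom, pos).
#' @return association data.frame (stage = "prefilter") with attributes
#'   \code{n_tests_by_class} and \code{n_skipped}.
#' @export
fast_linear_scan <- function(residuals, genotypes, config = scan_config(),
                             covariates = NULL, cpg_map = NULL) {
  if (is.null(cpg_map)) cpg_map <- attr(residuals, "cpg_map")
  if (is.null(cpg_map)) stop("input error: no CpG map available")
  R <- as.matrix(residuals)
  n <- nrow(R)
  G <- genotypes$dosage
  smap <- genotypes$map
  maf <- realized_maf(genotypes)
  keep_snp <- maf >= config$maf_min
  sdG <- apply(G, 2, stats::sd)
  n_skipped <- sum(keep_snp & sdG == 0) + sum(apply(R, 2, stats::sd) == 0)
  keep_snp <- keep_snp & sdG > 0
  G <- G[, keep_snp, drop = FALSE]
  smap <- smap[keep_snp, , drop = FALSE]
  keep_cpg <- apply(R, 2, stats::sd) > 0
  R <- R[, keep_cpg, drop = FALSE]
  cpg_map <- cpg_map[keep_cpg, , drop = FALSE]

  if (!is.null(covariates)) {
    X <- cbind(1, covariates)
    qx <- qr(X)
    G <- qr.resid(qx, G)
    R <- qr.resid(qx, R)
    df <- n - qx$rank - 1L
  } else {
    G <- scale(G, scale = FALSE)
    R <- scale(R, scale = FALSE)
    df <- n - 2L
  }
  Gs <- scale(G, center = FALSE, scale = sqrt(colSums(G^2)))
  Rs <- scale(R, center = FALSE, scale = sqrt(colSums(R^2)))
  CC <- crossprod(Gs, Rs)                  # SNP x CpG correlations
  CC[CC >= 1] <- 1 - 1e-12; CC[CC <= -1] <- -1 + 1e-12
  TT <- CC * sqrt(df / (1 - CC^2))
  P <- 2 * stats::pt(-abs(TT), df = df)

  cls <- outer(seq_len(nrow(smap)), seq_len(nrow(cpg_map)),
               function(i, j) classify_pair(smap$chrom[i], smap$pos[i],
                                            cpg_map$chrom[j], cpg_map$pos[j],
                                            config))
  thr <- ifelse(cls == "cis", config$prefilter_cis_p, config$prefilter_trans_p)
  hit <- which(P < thr, arr.ind = TRUE)
  n_by_class <- table(factor(cls, levels = c("cis", "long_range_cis",
                                             "trans_intra", "trans_inter")))
  sd_g <- sqrt(colSums(G^2)); sd_r <- sqrt(colSums(R^2))
  i <- hit[, 1]; j <- hit[, 2]
  beta <- CC[hit] * sd_r[j] / sd_g[i]
  tv <- TT[hit]
  out <- data.frame(snp_id = smap$snp_id[i], cpg_id = cpg_map$cpg_id[j],
                    chrom_snp = smap$chrom[i], pos_snp = smap$pos[i],
                    chrom_cpg = cpg_map$chrom[j], pos_cpg = cpg_map$pos[j],
                    beta = beta, se = beta / tv, t = tv, p = P[hit],
                    class = cls[hit], stage = rep("prefilter", length(i)),
                    stringsAsFactors = FALSE)
  out <- out[order(out$p), ]
  rownames(out) <- NULL
  attr(out, "n_tests_by_class") <- n_by_class
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Stage-two mixed-model refit of prefiltered SNP-CpG pairs
#'
#' Refits every retained pair as a full LME: methylation as the outcome,
#' SNP dosage plus covariates as fixed effects, kinship random effect. The
#' Wald test of the SNP coefficient replaces the stage-one statistic. On
#' unrelated cohorts the model collapses to ordinary least squares and the
#' refit t equals the direct regression t.
#'
#' @param records prefilter association data.frame.
#' @param cpgs a \code{cpg_matrix}.
#' @param genotypes a \code{genotype_matrix}.
#' @param covariates covariate matrix or NULL.
#' @param kinship kinship matrix.
#' @return association data.frame (stage = "final"), \code{flagged} column
#'   marking non-converged refits (excluded from significance calls).
#' @export
lme_refit <- function(records, cpgs, genotypes, covariates = NULL, kinship) {
  if (nrow(records) == 0) return(cbind(records, flagged = logical(0)))
  M <- if (inherits(cpgs, "cpg_matrix")) cpgs$beta else as.matrix(cpgs)
  G <- genotypes$dosage
  n <- nrow(M)
  rot <- kinship_rotation(kinship)
  X0 <- cbind(intercept = rep(1, n), covariates)
  X0r <- crossprod(rot$U, X0)
  ycache <- new.env(parent = emptyenv())
  gcache <- new.env(parent = emptyenv())
  out <- records
  out$stage <- "final"
  out$flagged <- FALSE
  for (r in seq_len(nrow(records))) {
    cid <- records$cpg_id[r]; sid <- records$snp_id[r]
    if (is.null(ycache[[cid]])) ycache[[cid]] <- drop(crossprod(rot$U, M[, cid]))
    if (is.null(gcache[[sid]])) gcache[[sid]] <- drop(crossprod(rot$U, G[, sid]))
    Xr <- cbind(X0r, snp = gcache[[sid]])
    fit <- tryCatch(lmm_rotated_fit(ycache[[cid]], Xr, rot$d, rot$degenerate),
                    error = function(e) NULL)
    if (is.null(fit)) {
      out$flagged[r] <- TRUE
      out$beta[r] <- out$se[r] <- out$t[r] <- out$p[r] <- NA_real_
    } else {
      k <- ncol(Xr)
      out$beta[r] <- fit$beta[k]; out$se[r] <- fit$se[k]
      out$t[r] <- fit$t[k]; out$p[r] <- fit$p[k]
    }
  }
  out
}

#' Apply final Bonferroni significance thresholds
#'
#' cis threshold = alpha / n_cis_tests, trans threshold =
#' alpha / n_trans_tests; long-range cis pairs (1-5 Mb) are excluded from
#' both classes, and flagged (non-converged) records are never called.
#'
#' @param records final-stage association data.frame.
#' @param config a \code{\link{scan_config}}; when its test counts are NULL
#'   the realized counts must be given.
#' @param n_cis_tests,n_trans_tests realized test counts (override config).
#' @return list(records = significant subset, cis_threshold, trans_threshold).
#' @export
apply_significance <- function(records, config = scan_config(),
                               n_cis_tests = NULL, n_trans_tests = NULL) {
  nc <- if (!is.null(n_cis_tests)) n_cis_tests else config$n_cis_tests
  nt <- if (!is.null(n_trans_tests)) n_trans_tests else config$n_trans_tests
  if (is.null(nc) || is.null(nt) || nc <= 0 || nt <= 0) {
    stop("input error: positive cis/trans test counts are required")
  }
  cis_thr <- config$alpha / nc
  trans_thr <- config$alpha / nt
  flagged <- if ("flagged" %in% names(records)) records$flagged else FALSE
  keep <- !flagged & !is.na(records$p) &
    ((records$class == "cis" & records$p < cis_thr) |
       (records$class %in% c("trans_intra", "trans_inter") &
          records$p < trans_thr))
  list(records = records[keep, , drop = FALSE], cis_threshold = cis_thr,
       trans_threshold = trans_thr)
}

#' Greedy LD pruning of a SNP set
#'
#' SNPs are visited in ascending p order (ties broken by smaller position,
#' then lexicographic id; without p values, by position then id) and
#' retained iff their squared dosage correlation with every
#' already-retained SNP is below the threshold.
#'
#' @param snp_ids candidate SNP ids.
#' @param genotypes a \code{genotype_matrix}.
#' @param r2_threshold squared-correlation cutoff (e.g. 0.2 for locus
#'   pruning, 0.01 for MR instrument selection).
#' @param p optional per-SNP p-values (same order as snp_ids).
#' @param rank_by_p rank by p (default) or by position alone.
#' @return retained SNP ids, in retention order; dropped-for-missing ids in
#'   the \code{dropped_missing} attribute.
#' @export
ld_prune <- function(snp_ids, genotypes, r2_threshold, p = NULL,
                     rank_by_p = !is.null(p)) {
  present <- snp_ids %in% colnames(genotypes$dosage)
  dropped <- snp_ids[!present]
  snp_ids2 <- snp_ids[present]
  if (!is.null(p)) p <- p[present]
  if (length(snp_ids2) == 0) {
    return(structure(character(0), dropped_missing = dropped))
  }
  pos <- genotypes$map$pos[match(snp_ids2, genotypes$map$snp_id)]
  ord <- if (rank_by_p && !is.null(p)) order(p, pos, snp_ids2) else
    order(pos, snp_ids2)
  D <- genotypes$dosage[, snp_ids2, drop = FALSE]
  kept <- integer(0)
  for (i in ord) {
    ok <- TRUE
    for (k in kept) {
      r2 <- suppressWarnings(stats::cor(D[, i], D[, k]))^2
      if (!is.na(r2) && r2 >= r2_threshold) { ok <- FALSE; break }
    }
    if (ok) kept <- c(kept, i)
  }
  structure(snp_ids2[kept], dropped_missing = dropped)
}

#' Genomic control inflation factor
#'
#' lambda = median of the observed 1-df chi-square statistics divided by
#' the null median qchisq(0.5, 1); values near 1 indicate a well-calibrated
#' scan.
#'
#' @param p_values association p-values in (0, 1].
#' @return lambda.
#' @export
genomic_control <- function(p_values) {
  if (any(p_values <= 0 | p_values > 1)) {
    stop("input error: p-values must lie in (0, 1]")
  }
  if (length(p_values) < 1000) {
    warning("fewer than 1000 p-values; lambda will be noisy")
  }
  chi <- stats::qchisq(p_values, df = 1, lower.tail = FALSE)
  stats::median(chi) / stats::qchisq(0.5, df = 1)
}

#' Directional concordance and replication rates between two scans
#'
#' Matches discovery and replication records on (snp_id, cpg_id) — effect
#' alleles are assumed harmonized — and reports the percentage of matched
#' pairs with the same sign of effect, plus replication rates at nominal
#' p < 0.05 and at the Bonferroni threshold 0.05 / n_matched.
#'
#' @param discovery,replication association data.frames with snp_id,
#'   cpg_id, beta, p.
#' @return list(directional_concordance (percent), rate_nominal,
#'   rate_bonferroni, n_matched).
#' @export
replication_concordance <- function(discovery, replication) {
  key_d <- paste(discovery$snp_id, discovery$cpg_id)
  key_r <- paste(replication$snp_id, replication$cpg_id)
  i <- match(key_d, key_r)
  ok <- !is.na(i)
  if (!any(ok)) {
    warning("no matched pairs between discovery and replication")
    return(list(directional_concordance = NA_real_, rate_nominal = NA_real_,
                rate_bonferroni = NA_real_, n_matched = 0L))
  }
  bd <- discovery$beta[ok]; br <- replication$beta[i[ok]]
  pr <- replication$p[i[ok]]
  nm <- sum(ok)
  list(directional_concordance = 100 * mean(sign(bd) == sign(br)),
       rate_nominal = mean(pr < 0.05),
       rate_bonferroni = mean(pr < 0.05 / nm),
       n_matched = nm)
}
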