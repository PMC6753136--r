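#' Select instrumental variables for one CpG from its cis-meQTL records
#'
#' Independent cis-meQTLs pruned at LD r-squared < 0.01, retaining the
#' variant with the lowest SNP-CpG p-value in each LD block. Multi-
#' instrument MR requires at least three instruments; smaller sets are
#' flagged insufficient.
#'
#' @param cis_records cis association records for a single CpG (snp_id, p).
#' @param genotypes a \code{genotype_matrix} (LD reference).
#' @param r2_threshold pruning threshold.
#' @param min_iv minimum instrument count.
#' @return character vector of SNP ids with attribute \code{insufficient}.
#' @export
select_ivs <- function(cis_records, genotypes, r2_threshold = 0.01,
                       min_iv = 3L) {
  ivs <- ld_prune(cis_records$snp_id, genotypes, r2_threshold,
                  p = cis_records$p)
  attr(ivs, "insufficient") <- length(ivs) < min_iv
  ivs
}

#' Harmonize exposure and outcome summary statistics
#'
#' Matches SNPs by id; when the outcome lists the same effect/other alleles
#' the row is kept as-is, when the alleles are swapped the outcome beta's
#' sign is flipped, palindromic SNPs (A/T or C/G) with MAF in [0.42, 0.58]
#' are dropped as strand-ambiguous, and ids or allele pairs with no match
#' are dropped.
#'
#' @param exposure data.frame: snp_id, effect_allele, other_allele,
#'   beta (gamma), se, maf.
#' @param outcome data.frame: snp_id, effect_allele, other_allele, beta, se.
#' @return aligned IV table: snp_id, gamma, se_gamma, Gamma, se_Gamma, maf,
#'   harmonization_action; dropped rows are retained with their action but
#'   excluded via the \code{kept} flag.
#' @export
harmonize <- function(exposure, outcome) {
  i <- match(exposure$snp_id, outcome$snp_id)
  action <- rep("dropped_unmatched", nrow(exposure))
  Gam <- rep(NA_real_, nrow(exposure)); seG <- rep(NA_real_, nrow(exposure))
  pal <- function(a, b) (a == "A" & b == "T") | (a == "T" & b == "A") |
    (a == "C" & b == "G") | (a == "G" & b == "C")
  for (r in seq_len(nrow(exposure))) {
    if (is.na(i[r])) next
    ea_x <- exposure$effect_allele[r]; oa_x <- exposure$other_allele[r]
    ea_y <- outcome$effect_allele[i[r]]; oa_y <- outcome$other_allele[i[r]]
    if (pal(ea_x, oa_x) && !is.na(exposure$maf[r]) &&
        exposure$maf[r] >= 0.42 && exposure$maf[r] <= 0.58) {
      action[r] <- "dropped_palindromic"
      next
    }
    if (ea_x == ea_y && oa_x == oa_y) {
      action[r] <- "kept"
      Gam[r] <- outcome$beta[i[r]]; seG[r] <- outcome$se[i[r]]
    } else if (ea_x == oa_y && oa_x == ea_y) {
      action[r] <- "sign_flipped"
      Gam[r] <- -outcome$beta[i[r]]; seG[r] <- outcome$se[i[r]]
    }
  }
  out <- data.frame(snp_id = exposure$snp_id, gamma = exposure$beta,
                    se_gamma = exposure$se, Gamma = Gam, se_Gamma = seG,
                    maf = exposure$maf, harmonization_action = action,
                    kept = action %in% c("kept", "sign_flipped"),
                    stringsAsFactors = FALSE)
  out
}

#' Inverse-variance-weighted Mendelian randomization
#'
#' Per-instrument Wald ratios beta_j = Gamma_j / gamma_j with first-order
#' standard errors se_j = se_Gamma_j / |gamma_j| are combined by fixed-
#' effect inverse-variance weighting; this is algebraically the weighted
#' through-origin regression of Gamma on gamma with weights 1/se_Gamma^2.
#' Instruments with gamma = 0 are rejected before fitting. An optional
#' multiplicative random-effects scaling inflates the standard error by
#' max(1, sqrt(Q / (J - 1))).
#'
#' @param table aligned IV table (only \code{kept} rows are used).
#' @param random_effects apply the multiplicative scaling.
#' @return list(theta, se_theta, p_mr, J, ratios, ratio_se).
#' @export
ivw_mr <- function(table, random_effects = FALSE) {
  tab <- table[table$kept & table$gamma != 0, , drop = FALSE]
  J <- nrow(tab)
  if (J < 2) stop("insufficient instruments for IVW (need >= 2)")
  b <- tab$Gamma / tab$gamma
  s <- tab$se_Gamma / abs(tab$gamma)
  w <- 1 / s^2
  theta <- sum(b * w) / sum(w)
  se <- 1 / sqrt(sum(w))
  if (random_effects) {
    Q <- sum(w * (b - theta)^2)
    se <- se * max(1, sqrt(Q / (J - 1)))
  }
  list(theta = theta, se_theta = se,
       p_mr = 2 * stats::pnorm(-abs(theta / se)), J = J,
       ratios = stats::setNames(b, tab$snp_id), ratio_se = s)
}

#' Cochran's Q heterogeneity test across instrument ratios
#'
#' Q = sum_j (beta_j - theta)^2 / se_j^2 referred to chi-square with J - 1
#' degrees of freedom; per-instrument contributions are returned for
#' outlier ranking.
#'
#' @param table aligned IV table.
#' @param theta IVW estimate to test against.
#' @return list(q_stat, p_heter, q_contrib).
#' @export
cochran_q <- function(table, theta) {
  tab <- table[table$kept & table$gamma != 0, , drop = FALSE]
  b <- tab$Gamma / tab$gamma
  s <- tab$se_Gamma / abs(tab$gamma)
  qj <- (b - theta)^2 / s^2
  Q <- sum(qj)
  J <- length(qj)
  list(q_stat = Q,
       p_heter = if (J >= 2) stats::pchisq(Q, df = J - 1, lower.tail = FALSE) else NA_real_,
       q_contrib = stats::setNames(qj, tab$snp_id))
}

#' MR-Egger intercept test for directional pleiotropy
#'
#' Rows are oriented so every gamma is non-negative (flipping both signs
#' where needed), then Gamma is regressed on gamma with an intercept and
#' weights 1/se_Gamma^2. A non-zero intercept (t-test with J - 2 df)
#' indicates directional pleiotropy; the slope is the Egger causal
#' estimate.
#'
#' @param table aligned IV table.
#' @return list(intercept, se_intercept, p_pleio, egger_slope).
#' @export
egger_intercept <- function(table) {
  tab <- table[table$kept & table$gamma != 0, , drop = FALSE]
  if (nrow(tab) < 3) stop("insufficient instruments for MR-Egger (need >= 3)")
  flip <- sign(tab$gamma)
  g <- tab$gamma * flip
  G <- tab$Gamma * flip
  if (max(g) - min(g) < 1e-12) {
    stop("collinearity error: all instrument strengths identical after orientation")
  }
  fit <- stats::lm(G ~ g, weights = 1 / tab$se_Gamma^2)
  sm <- summary(fit)$coefficients
  list(intercept = sm[1, 1], se_intercept = sm[1, 2], p_pleio = sm[1, 4],
       egger_slope = sm[2, 1])
}

#' Stepwise instrument refinement with heterogeneity/pleiotropy gates
#'
#' Repeats IVW, Cochran's Q and the Egger intercept test; while either
#' diagnostic p-value is below 0.05 the instrument with the largest Q
#' contribution is excluded and the tests repeated. The loop stops when
#' both diagnostics pass (status from the significance rules) or when
#' fewer than \code{min_iv} instruments would remain
#' (status insufficient_ivs). The exclusion order is recorded.
#'
#' @param table aligned IV table.
#' @param alpha_diag diagnostic gate (0.05).
#' @param min_iv minimum surviving instrument count.
#' @param p_threshold MR significance threshold used for the final status.
#' @param binary_outcome report exp(theta) as an odds ratio with 95% CI.
#' @return object of class \code{mr_result}.
#' @export
stepwise_iv_refinement <- function(table, alpha_diag = 0.05, min_iv = 3L,
                                   p_threshold = 0.05, binary_outcome = TRUE) {
  tab <- table[table$kept & table$gamma != 0, , drop = FALSE]
  n_init <- nrow(tab)
  excluded <- character(0)
  mk <- function(status, fit = NULL, qres = NULL, eg = NULL, n_final = nrow(tab)) {
    theta <- if (!is.null(fit)) fit$theta else NA_real_
    se <- if (!is.null(fit)) fit$se_theta else NA_real_
    structure(list(theta = theta, se_theta = se,
                   p_mr = if (!is.null(fit)) fit$p_mr else NA_real_,
                   or_value = if (binary_outcome) exp(theta) else NA_real_,
                   ci_low = if (binary_outcome) exp(theta - 1.96 * se) else theta - 1.96 * se,
                   ci_high = if (binary_outcome) exp(theta + 1.96 * se) else theta + 1.96 * se,
                   q_stat = if (!is.null(qres)) qres$q_stat else NA_real_,
                   p_heter = if (!is.null(qres)) qres$p_heter else NA_real_,
                   egger_intercept = if (!is.null(eg)) eg$intercept else NA_real_,
                   p_pleio = if (!is.null(eg)) eg$p_pleio else NA_real_,
                   n_iv_initial = n_init, n_iv_final = n_final,
                   excluded_ivs = excluded, status = status),
              class = "mr_result")
  }
  if (n_init < min_iv) return(mk("insufficient_ivs"))
  repeat {
    fit <- ivw_mr(tab)
    qres <- cochran_q(tab, fit$theta)
    eg <- tryCatch(egger_intercept(tab), error = function(e) NULL)
    p_pleio <- if (!is.null(eg)) eg$p_pleio else 1
    if (qres$p_heter >= alpha_diag && p_pleio >= alpha_diag) {
      status <- if (fit$p_mr < p_threshold) "significant" else "not_significant"
      return(mk(status, fit, qres, eg))
    }
    if (nrow(tab) - 1L < min_iv) {
      return(mk("diagnostics_failed", fit, qres, eg))
    }
    worst <- names(which.max(qres$q_contrib))
    excluded <- c(excluded, worst)
    tab <- tab[tab$snp_id != worst, , drop = FALSE]
  }
}

#' @export
print.mr_result <- function(x, ...) {
  cat(sprintf("mr_result: theta=%.4f (se %.4f) p=%.3g OR=%.3f [%.3f, %.3f]\n",
              x$theta, x$se_theta, x$p_mr, x$or_value, x$ci_low, x$ci_high))
  cat(sprintf("  Q=%.3f p_heter=%.3f egger_int=%.4f p_pleio=%.3f IVs %d -> %d (%s)\n",
              x$q_stat, x$p_heter, x$egger_intercept, x$p_pleio,
              x$n_iv_initial, x$n_iv_final, x$status))
  invisible(x)
}

#' Collapse correlated CpGs within 2 Mb to an index CpG
#'
#' CpG clusters (connected components of pairs within the window with
#' squared correlation at or above the threshold) are represented by the
#' member with the lowest MR p-value; the others point to their index.
#'
#' @param cpg_pos data.frame: cpg_id, chrom, pos.
#' @param cor_matrix CpG correlation matrix (dimnames = cpg ids).
#' @param p_mr named MR p-values per CpG.
#' @param window_bp clustering window (2 Mb).
#' @param r2_threshold squared-correlation threshold (0.5).
#' @return data.frame: cpg_id, kept, index_cpg.
#' @export
prune_cpgs <- function(cpg_pos, cor_matrix, p_mr, window_bp = 2e6,
                       r2_threshold = 0.5) {
  n <- nrow(cpg_pos)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (a in seq_len(n)) {
    for (b in seq_len(n)) {
      if (b <= a) next
      if (cpg_pos$chrom[a] != cpg_pos$chrom[b]) next
      if (abs(cpg_pos$pos[a] - cpg_pos$pos[b]) > window_bp) next
      r2 <- cor_matrix[cpg_pos$cpg_id[a], cpg_pos$cpg_id[b]]^2
      if (!is.na(r2) && r2 >= r2_threshold) {
        ra <- find(a); rb <- find(b)
        if (ra != rb) parent[rb] <- ra
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  out <- data.frame(cpg_id = cpg_pos$cpg_id, kept = FALSE,
                    index_cpg = NA_character_, stringsAsFactors = FALSE)
  for (g in unique(roots)) {
    members <- which(roots == g)
    idx <- members[which.min(p_mr[cpg_pos$cpg_id[members]])]
    out$kept[idx] <- TRUE
    out$index_cpg[members] <- cpg_pos$cpg_id[idx]
  }
  out
}

#' Multivariable MR for a group of moderately correlated CpGs
#'
#' Weighted regression of the outcome effects Gamma_j on the matrix of
#' exposure effects (one column per CpG) without an intercept, weights
#' 1/se_Gamma^2, giving the conditional causal effect of each exposure.
#' With a single exposure this reduces exactly to the IVW estimate.
#'
#' @param gamma_matrix J x K matrix of SNP-exposure effects (columns = CpGs).
#' @param Gamma,se_Gamma outcome effects and standard errors (length J).
#' @return data.frame: exposure, theta, se, p.
#' @export
multivariable_mr <- function(gamma_matrix, Gamma, se_Gamma) {
  X <- as.matrix(gamma_matrix)
  if (nrow(X) < ncol(X) + 1) stop("insufficient instruments for multivariable MR")
  if (qr(X)$rank < ncol(X)) {
    stop("collinearity error: exposure effect matrix is rank deficient (",
         paste(colnames(X), collapse = ", "), ")")
  }
  w <- 1 / se_Gamma^2
  XtWX <- crossprod(X, X * w)
  theta <- solve(XtWX, crossprod(X * w, Gamma))
  se <- sqrt(diag(solve(XtWX)))
  tv <- drop(theta) / se
  data.frame(exposure = colnames(X), theta = drop(theta), se = se,
             p = 2 * stats::pnorm(-abs(tv)), stringsAsFactors = FALSE)
}

#' Group CpGs for multivariable MR
#'
#' Connected components of the graph whose edges join CpGs within the
#' window with moderate correlation (0 < r-squared < the upper threshold);
#' highly correlated CpGs should be collapsed first via
#' \code{\link{prune_cpgs}}.
#'
#' @param cpg_pos data.frame: cpg_id, chrom, pos.
#' @param cor_matrix correlation matrix.
#' @param window_bp grouping window (2 Mb).
#' @param r2_upper upper squared-correlation bound (0.5).
#' @param r2_lower strictly positive lower bound.
#' @return list of cpg-id character vectors (groups of size >= 2).
#' @export
mvmr_groups <- function(cpg_pos, cor_matrix, window_bp = 2e6, r2_upper = 0.5,
                        r2_lower = 0) {
  n <- nrow(cpg_pos)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (a in seq_len(n)) for (b in seq_len(n)) {
    if (b <= a) next
    if (cpg_pos$chrom[a] != cpg_pos$chrom[b]) next
    if (abs(cpg_pos$pos[a] - cpg_pos$pos[b]) > window_bp) next
    r2 <- cor_matrix[cpg_pos$cpg_id[a], cpg_pos$cpg_id[b]]^2
    if (!is.na(r2) && r2 > r2_lower && r2 < r2_upper) {
      ra <- find(a); rb <- find(b)
      if (ra != rb) parent[rb] <- ra
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  grps <- split(cpg_pos$cpg_id, roots)
  grps[lengths(grps) >= 2]
}

#' MR of gene expression on an outcome trait
#'
#' The identical IVW engine applied with expression as the exposure, using
#' independent cis-eQTL instruments (LD r-squared < 0.01, at least 3); with
#' fewer than 3 instruments the single-instrument Wald ratio
#' Gamma / gamma with standard error se_Gamma / |gamma| is returned as a
#' fallback. The Bonferroni threshold is alpha / n_genes_tested.
#'
#' @param eqtl_records cis-eQTL records for one gene (snp_id, p, beta, se,
#'   effect_allele, other_allele, maf).
#' @param outcome_gwas outcome summary statistics.
#' @param genotypes LD reference \code{genotype_matrix}.
#' @param n_genes_tested genes tested (Bonferroni divisor).
#' @param alpha experiment-wide alpha.
#' @param binary_outcome report odds ratios.
#' @return \code{mr_result} with attribute \code{p_threshold}.
#' @export
mr_for_expression <- function(eqtl_records, outcome_gwas, genotypes,
                              n_genes_tested, alpha = 0.05,
                              binary_outcome = TRUE) {
  thr <- alpha / n_genes_tested
  ivs <- select_ivs(eqtl_records, genotypes)
  exp_tab <- eqtl_records[match(ivs, eqtl_records$snp_id), , drop = FALSE]
  aligned <- harmonize(exp_tab, outcome_gwas)
  kept <- aligned[aligned$kept, , drop = FALSE]
  if (nrow(kept) >= 3) {
    res <- stepwise_iv_refinement(aligned, p_threshold = thr,
                                  binary_outcome = binary_outcome)
  } else if (nrow(kept) >= 1) {
    top <- kept[which.min(exp_tab$p[match(kept$snp_id, exp_tab$snp_id)]), ]
    theta <- top$Gamma / top$gamma
    se <- top$se_Gamma / abs(top$gamma)
    p <- 2 * stats::pnorm(-abs(theta / se))
    res <- structure(list(theta = theta, se_theta = se, p_mr = p,
                          or_value = if (binary_outcome) exp(theta) else NA_real_,
                          ci_low = if (binary_outcome) exp(theta - 1.96 * se) else theta - 1.96 * se,
                          ci_high = if (binary_outcome) exp(theta + 1.96 * se) else theta + 1.96 * se,
                          q_stat = NA_real_, p_heter = NA_real_,
                          egger_intercept = NA_real_, p_pleio = NA_real_,
                          n_iv_initial = nrow(kept), n_iv_final = 1L,
                          excluded_ivs = character(0),
                          status = if (p < thr) "significant_wald" else "not_significant"),
                     class = "mr_result")
  } else {
    res <- structure(list(theta = NA_real_, se_theta = NA_real_, p_mr = NA_real_,
                          or_value = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                          q_stat = NA_real_, p_heter = NA_real_,
                          egger_intercept = NA_real_, p_pleio = NA_real_,
                          n_iv_initial = 0L, n_iv_final = 0L,
                          excluded_ivs = character(0), status = "insufficient_ivs"),
                     class = "mr_result")
  }
  attr(res, "p_threshold") <- thr
  res
}
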