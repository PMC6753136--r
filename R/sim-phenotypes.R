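#' Simulate CpG methylation beta values over a pedigree
#'
#' Each CpG's latent trait is z = beta_g * g + sqrt(m_r2) * m + a + c + e:
#' an optional cis causal-SNP effect (variance fraction
#' \code{cis_effect_r2}, counted inside the CpG's additive heritability), an
#' optional trans-hotspot mediation term m (the standardized level of a
#' mediator gene driven by the hotspot SNP), a polygenic additive effect a
#' with covariance sigma2_A * K, a shared-household effect c with covariance
#' sigma2_h * H, and i.i.d. noise. Latent traits are mapped into the
#' (0.02, 0.98) beta-value range by a gentle monotone sigmoid. All draws are
#' recorded in the returned truth table.
#'
#' @param genotypes a \code{genotype_matrix}.
#' @param kinship,household covariance matrices over the same samples.
#' @param config a \code{\link{sim_config}}.
#' @return list(methylation = \code{cpg_matrix} (beta matrix + CpG map),
#'   truth = \code{truth_table}).
#' @export
simulate_methylation <- function(genotypes, kinship, household, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 2L)
  dos <- genotypes$dosage
  n <- nrow(dos)
  ids <- rownames(dos)
  if (!identical(ids, rownames(kinship)) || !identical(ids, rownames(household))) {
    stop("matrix error: sample order of kinship/household must match genotypes")
  }
  LK <- tryCatch(chol(kinship + diag(1e-8, n)),
                 error = function(e) stop("matrix error: kinship not PSD"))
  LH <- tryCatch(chol(household + diag(1e-8, n)),
                 error = function(e) stop("matrix error: household not PSD"))

  layout <- config$chrom_layout
  cmap <- do.call(rbind, lapply(seq_len(nrow(layout)), function(i) {
    k <- max(1L, round(config$n_cpgs * layout$n_snps[i] / sum(layout$n_snps)))
    data.frame(chrom = layout$chrom[i],
               pos = sort(sample.int(layout$span_bp[i], k)),
               stringsAsFactors = FALSE)
  }))
  cmap <- cmap[seq_len(min(nrow(cmap), config$n_cpgs)), ]
  ncpg <- nrow(cmap)
  cmap$cpg_id <- sprintf("cg%06d", seq_len(ncpg))
  # genomic feature flags used by the enrichment module
  cmap$island <- stats::runif(ncpg) < 0.3
  cmap$promoter <- stats::runif(ncpg) < 0.2
  cmap$enhancer <- stats::runif(ncpg) < 0.15
  cmap$body <- stats::runif(ncpg) < 0.35
  cmap <- cmap[, c("cpg_id", "chrom", "pos", "island", "promoter", "enhancer", "body")]

  smap <- genotypes$map
  g_var <- apply(dos, 2, stats::var)

  # hotspot bookkeeping: mediator latents and trans target assignment
  hs <- config$hotspot_spec
  med_r2 <- rep(0, ncpg); hotspot_of <- rep(NA_integer_, ncpg)
  mediators <- list()
  if (!is.null(hs) && nrow(hs) > 0) {
    taken <- logical(ncpg)
    for (h in seq_len(nrow(hs))) {
      si <- hs$snp_index[h]
      g <- dos[, si]
      if (stats::var(g) <= 0) stop("generation error: monomorphic hotspot SNP")
      gr2 <- config$hotspot_gene_r2
      m <- sqrt(gr2) * as.numeric(scale(g)) + sqrt(1 - gr2) * stats::rnorm(n)
      is_trans <- cmap$chrom != smap$chrom[si] |
        abs(cmap$pos - smap$pos[si]) > 5e6
      cand <- which(is_trans & !taken)
      if (length(cand) < hs$n_targets[h]) {
        stop("generation error: not enough trans CpGs for hotspot targets")
      }
      tgt <- sample(cand, hs$n_targets[h])
      taken[tgt] <- TRUE
      med_r2[tgt] <- hs$mediation_r2[h]
      hotspot_of[tgt] <- h
      mediators[[h]] <- list(snp_index = si, snp_id = smap$snp_id[si],
                             latent = m, targets = cmap$cpg_id[tgt])
    }
  }

  must_have_qtl <- integer(0)
  if (!is.null(config$coloc_spec) && nrow(config$coloc_spec) > 0) {
    must_have_qtl <- config$coloc_spec$cpg_index
  }

  h2 <- stats::runif(ncpg, config$h2_additive_range[1], config$h2_additive_range[2])
  c2 <- stats::runif(ncpg, config$household_var_range[1], config$household_var_range[2])
  causal_snp <- rep(NA_character_, ncpg)
  causal_snps <- rep(NA_character_, ncpg)
  betas_latent <- rep(NA_character_, ncpg)
  causal_sets <- vector("list", ncpg)
  beta_latent <- rep(NA_real_, ncpg)
  r2_cis <- rep(0, ncpg)
  mu0 <- stats::runif(ncpg, -1, 1)
  s <- config$squash_scale

  beta_mat <- matrix(NA_real_, n, ncpg, dimnames = list(ids, cmap$cpg_id))
  latent <- matrix(NA_real_, n, ncpg, dimnames = list(ids, cmap$cpg_id))
  slope_bv <- rep(NA_real_, ncpg)

  for (j in seq_len(ncpg)) {
    wants_qtl <- (stats::runif(1) < config$p_cis_qtl) || (j %in% must_have_qtl)
    if (wants_qtl) {
      cand <- which(smap$chrom == cmap$chrom[j] &
                      abs(smap$pos - cmap$pos[j]) <= 1e6 & g_var > 0)
      if (length(cand) > 0) {
        # greedy pick of up to n_causal_per_cpg independent SNPs (r2 below
        # the MR instrument-pruning threshold); CpGs in a coloc pair stay
        # single-causal so the one-shared-variant hypothesis is realizable
        n_causal <- if (j %in% must_have_qtl) 1L else config$n_causal_per_cpg
        pool <- if (length(cand) == 1L) cand else sample(cand)
        ks <- pool[1]
        for (kk in pool[-1]) {
          if (length(ks) >= n_causal) break
          ld <- vapply(ks, function(k0)
            suppressWarnings(stats::cor(dos[, kk], dos[, k0]))^2, numeric(1))
          if (all(is.na(ld) | ld < 0.005)) ks <- c(ks, kk)
        }
        causal_sets[[j]] <- ks
        causal_snp[j] <- smap$snp_id[ks[1]]
        causal_snps[j] <- paste(smap$snp_id[ks], collapse = ";")
        r2_cis[j] <- config$cis_effect_r2
        if (h2[j] < r2_cis[j]) h2[j] <- r2_cis[j]
      }
    }
    sA <- h2[j] - r2_cis[j]
    se2 <- 1 - h2[j] - c2[j] - med_r2[j]
    if (se2 <= 0.01) { # keep a floor of residual noise
      c2[j] <- max(0, c2[j] + se2 - 0.01)
      se2 <- 1 - h2[j] - c2[j] - med_r2[j]
    }
    z <- sqrt(max(sA, 0)) * drop(crossprod(LK, stats::rnorm(n))) +
      sqrt(c2[j]) * drop(crossprod(LH, stats::rnorm(n))) +
      sqrt(se2) * stats::rnorm(n)
    if (!is.null(causal_sets[[j]])) {
      ks <- causal_sets[[j]]
      bks <- sqrt(r2_cis[j] / length(ks) / g_var[ks])
      beta_latent[j] <- bks[1]
      betas_latent[j] <- paste(format(bks, digits = 17, trim = TRUE),
                               collapse = ";")
      z <- z + drop(dos[, ks, drop = FALSE] %*% bks)
    }
    if (med_r2[j] > 0) {
      m <- mediators[[hotspot_of[j]]]$latent
      z <- z + sqrt(med_r2[j]) * as.numeric(scale(m))
    }
    latent[, j] <- z
    bv <- 0.02 + 0.96 * stats::plogis(mu0[j] + s * z)
    beta_mat[, j] <- bv
    slope_bv[j] <- stats::cov(bv, z) / stats::var(z)
  }

  truth_cpg <- data.frame(cpg_id = cmap$cpg_id, chrom = cmap$chrom,
                          pos = cmap$pos, h2 = h2, sigma2_h = c2,
                          sigma2_e = 1 - h2 - c2 - med_r2,
                          causal_snp = causal_snp, causal_snps = causal_snps,
                          beta_latent = beta_latent,
                          betas_latent = betas_latent,
                          r2_cis = r2_cis, mediation_r2 = med_r2,
                          hotspot = hotspot_of, mu0 = mu0,
                          slope_bv = slope_bv, stringsAsFactors = FALSE)
  truth <- list(cpg = truth_cpg, mediators = mediators,
                genotypes = genotypes, latent = latent,
                theta_causal = config$theta_causal, config = config)
  class(truth) <- "truth_table"
  meth <- list(beta = beta_mat, map = cmap)
  class(meth) <- "cpg_matrix"
  list(methylation = meth, truth = truth)
}

#' @export
print.cpg_matrix <- function(x, ...) {
  cat("cpg_matrix:", nrow(x$beta), "samples x", ncol(x$beta), "CpGs\n")
  invisible(x)
}

#' Simulate gene expression with cis-eQTLs, coloc regions and eQTM links
#'
#' Mediator genes declared in \code{hotspot_spec} take the hotspot's latent
#' mediator as their expression (their TSS is placed next to the hotspot
#' SNP). Genes named in \code{coloc_spec} share the paired CpG's causal SNP
#' (shared = TRUE) or are driven by a nearby SNP in low LD with it
#' (r-squared < 0.05; shared = FALSE). Remaining genes receive a cis-eQTL
#' with probability \code{p_cis_eqtl}. \code{eqtm_spec} adds direct
#' CpG-to-expression effects. Total variance is 1 per gene.
#'
#' @param genotypes a \code{genotype_matrix}.
#' @param methylation a \code{cpg_matrix}.
#' @param config a \code{\link{sim_config}}.
#' @param truth the \code{truth_table} from \code{\link{simulate_methylation}};
#'   extended in place with the per-gene truth and returned.
#' @return list(expression = \code{expression_matrix}, truth = truth_table).
#' @export
simulate_expression <- function(genotypes, methylation, config, truth) {
  stopifnot(inherits(config, "sim_config"), inherits(truth, "truth_table"))
  set.seed(config$seed + 3L)
  dos <- genotypes$dosage
  smap <- genotypes$map
  n <- nrow(dos)
  ng <- config$n_genes
  g_var <- apply(dos, 2, stats::var)
  layout <- config$chrom_layout

  chrom_pick <- sample(layout$chrom, ng, replace = TRUE,
                       prob = layout$n_snps / sum(layout$n_snps))
  tss <- vapply(chrom_pick, function(cc) {
    sample.int(layout$span_bp[match(cc, layout$chrom)], 1L)
  }, numeric(1))
  gmap <- data.frame(gene_id = sprintf("GENE%04d", seq_len(ng)),
                     chrom = chrom_pick, tss = tss, stringsAsFactors = FALSE)

  causal_snp <- rep(NA_character_, ng); causal_idx <- rep(NA_integer_, ng)
  r2 <- rep(0, ng); role <- rep("plain", ng)

  # mediator genes sit on top of their hotspot SNP
  if (length(truth$mediators) > 0) {
    free <- setdiff(seq_len(ng),
                    c(if (!is.null(config$coloc_spec)) config$coloc_spec$gene_index,
                      if (!is.null(config$eqtm_spec)) config$eqtm_spec$gene_index))
    if (length(free) < length(truth$mediators)) {
      stop("generation error: not enough genes to host hotspot mediators")
    }
    for (h in seq_along(truth$mediators)) {
      gi <- free[h]
      si <- truth$mediators[[h]]$snp_index
      gmap$chrom[gi] <- smap$chrom[si]
      gmap$tss[gi] <- max(1, smap$pos[si] + sample(-5e4:5e4, 1L))
      causal_idx[gi] <- si; causal_snp[gi] <- smap$snp_id[si]
      r2[gi] <- config$hotspot_gene_r2
      role[gi] <- "mediator"
      truth$mediators[[h]]$gene_id <- gmap$gene_id[gi]
    }
  }

  cs <- config$coloc_spec
  if (!is.null(cs) && nrow(cs) > 0) {
    for (i in seq_len(nrow(cs))) {
      gi <- cs$gene_index[i]; ci <- cs$cpg_index[i]
      csnp <- truth$cpg$causal_snp[ci]
      if (is.na(csnp)) stop("generation error: coloc CpG has no causal SNP")
      k <- match(csnp, smap$snp_id)
      gmap$chrom[gi] <- smap$chrom[k]
      gmap$tss[gi] <- max(1, smap$pos[k] + sample(-2e5:2e5, 1L))
      if (isTRUE(cs$shared[i])) {
        causal_idx[gi] <- k
      } else {
        # the distinct variant must sit inside the CpG-centred coloc region
        # as well as in cis of the gene
        cand <- which(smap$chrom == gmap$chrom[gi] &
                        abs(smap$pos - gmap$tss[gi]) <= 1e6 &
                        abs(smap$pos - truth$cpg$pos[ci]) <= 8e5 & g_var > 0)
        cand <- setdiff(cand, k)
        ld <- vapply(cand, function(j) stats::cor(dos[, j], dos[, k])^2, numeric(1))
        cand <- cand[ld < 0.05]
        if (length(cand) == 0) {
          stop("generation error: no low-LD SNP available for a distinct coloc pair")
        }
        causal_idx[gi] <- if (length(cand) == 1L) cand else sample(cand, 1L)
      }
      causal_snp[gi] <- smap$snp_id[causal_idx[gi]]
      r2[gi] <- config$gene_cis_r2
      role[gi] <- if (isTRUE(cs$shared[i])) "coloc_shared" else "coloc_distinct"
    }
  }

  eq <- config$eqtm_spec
  eqtm_r2 <- rep(0, ng); eqtm_cpg <- rep(NA_integer_, ng)
  if (!is.null(eq) && nrow(eq) > 0) {
    eqtm_r2[eq$gene_index] <- eq$r2
    eqtm_cpg[eq$gene_index] <- eq$cpg_index
  }

  expr <- matrix(NA_real_, n, ng, dimnames = list(rownames(dos), gmap$gene_id))
  beta_g <- rep(NA_real_, ng)
  for (gi in seq_len(ng)) {
    if (role[gi] == "mediator") {
      h <- which(vapply(truth$mediators, function(m) identical(m$gene_id, gmap$gene_id[gi]),
                        logical(1)))
      expr[, gi] <- truth$mediators[[h]]$latent
      beta_g[gi] <- sqrt(r2[gi] / g_var[causal_idx[gi]])
      next
    }
    if (role[gi] == "plain" && is.na(causal_idx[gi]) &&
        stats::runif(1) < config$p_cis_eqtl) {
      cand <- which(smap$chrom == gmap$chrom[gi] &
                      abs(smap$pos - gmap$tss[gi]) <= 1e6 & g_var > 0)
      if (length(cand) > 0) {
        causal_idx[gi] <- if (length(cand) == 1L) cand else sample(cand, 1L)
        causal_snp[gi] <- smap$snp_id[causal_idx[gi]]
        r2[gi] <- config$gene_cis_r2
      }
    }
    e2 <- 1 - r2[gi] - eqtm_r2[gi]
    if (e2 <= 0) stop("generation error: gene variance fractions exceed 1")
    y <- sqrt(e2) * stats::rnorm(n)
    if (!is.na(causal_idx[gi])) {
      beta_g[gi] <- sqrt(r2[gi] / g_var[causal_idx[gi]])
      y <- y + beta_g[gi] * dos[, causal_idx[gi]]
    }
    if (eqtm_r2[gi] > 0) {
      y <- y + sqrt(eqtm_r2[gi]) * as.numeric(scale(methylation$beta[, eqtm_cpg[gi]]))
    }
    expr[, gi] <- y
  }

  truth$gene <- data.frame(gene_id = gmap$gene_id, chrom = gmap$chrom,
                           tss = gmap$tss, causal_snp = causal_snp,
                           r2_cis = r2, beta = beta_g, role = role,
                           eqtm_cpg = ifelse(is.na(eqtm_cpg), NA_character_,
                                             truth$cpg$cpg_id[eqtm_cpg]),
                           eqtm_r2 = eqtm_r2, stringsAsFactors = FALSE)
  ex <- list(expr = expr, map = gmap)
  class(ex) <- "expression_matrix"
  list(expression = ex, truth = truth)
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("expression_matrix:", nrow(x$expr), "samples x", ncol(x$expr), "genes\n")
  invisible(x)
}

#' Simulate outcome GWAS summary statistics from the recorded truth
#'
#' For each SNP-CpG row of the exposure summary the outcome effect is
#' Gamma_j = theta * gamma_j + alpha_j + eps_j, where gamma_j is the TRUE
#' marginal effect of the SNP on the CpG's beta values (causal effect
#' propagated through LD and the latent-to-beta slope), alpha_j is per-SNP
#' directional pleiotropy drawn Normal(pleiotropy_mean, pleiotropy_sd), and
#' eps_j has the standard error implied by the GWAS sample size and allele
#' frequency under a unit-variance trait. A configurable fraction of rows
#' is emitted with swapped effect/other alleles (and the sign of beta
#' flipped accordingly) so that harmonization is exercised.
#'
#' @param truth a \code{truth_table} (from the methylation generator).
#' @param meqtl_summary data.frame with at least snp_id and cpg_id columns
#'   (e.g. the exposure-side association table).
#' @param config a \code{\link{sim_config}}.
#' @return data.frame: snp_id, chrom, pos, effect_allele, other_allele,
#'   beta, se, p, n.
#' @export
simulate_outcome_gwas <- function(truth, meqtl_summary, config) {
  stopifnot(inherits(truth, "truth_table"))
  if (config$gwas_n < 10) stop("configuration error: gwas_n must be at least 10")
  set.seed(config$seed + 4L)
  dos <- truth$genotypes$dosage
  smap <- truth$genotypes$map
  j <- match(meqtl_summary$snp_id, smap$snp_id)
  if (anyNA(j)) stop("unknown SNP ids in meqtl_summary")
  ci <- match(meqtl_summary$cpg_id, truth$cpg$cpg_id)

  gamma_true <- numeric(nrow(meqtl_summary))
  for (r in seq_len(nrow(meqtl_summary))) {
    csnps <- truth$cpg$causal_snps[ci[r]]
    if (is.na(csnps)) next
    ks <- match(strsplit(csnps, ";")[[1]], smap$snp_id)
    bks <- as.numeric(strsplit(truth$cpg$betas_latent[ci[r]], ";")[[1]]) *
      truth$cpg$slope_bv[ci[r]]
    gamma_true[r] <- sum(bks * vapply(ks, function(k)
      stats::cov(dos[, j[r]], dos[, k]), numeric(1))) /
      stats::var(dos[, j[r]])
  }

  af <- colMeans(dos) / 2
  maf <- pmin(af, 1 - af)[j]
  se <- 1 / sqrt(2 * pmax(maf, 1e-4) * (1 - pmax(maf, 1e-4)) * config$gwas_n)
  alpha <- stats::rnorm(nrow(meqtl_summary), config$pleiotropy_mean,
                        config$pleiotropy_sd)
  beta <- truth$theta_causal * gamma_true + alpha + stats::rnorm(length(se), 0, se)

  ea <- smap$effect_allele[j]; oa <- smap$other_allele[j]
  swap <- stats::runif(length(j)) < config$allele_swap_frac
  out <- data.frame(snp_id = meqtl_summary$snp_id,
                    chrom = smap$chrom[j], pos = smap$pos[j],
                    effect_allele = ifelse(swap, oa, ea),
                    other_allele = ifelse(swap, ea, oa),
                    beta = ifelse(swap, -beta, beta), se = se,
                    p = 2 * stats::pnorm(-abs(beta / se)),
                    n = config$gwas_n, stringsAsFactors = FALSE)
  attr(out, "gamma_true") <- gamma_true
  attr(out, "swapped") <- swap
  out
}
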