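test_that("pedigree matrices carry the first-degree coefficients", {
  cfg <- sim_config(seed = 7, n_families = 1, sibs_per_family = c(2, 2),
                    n_unrelated = 0, n_snps = 10)
  ped <- simulate_pedigree(cfg)
  K <- ped$kinship
  ids <- rownames(K)
  fa <- ids[1]; mo <- ids[2]; s1 <- ids[3]; s2 <- ids[4]
  expect_equal(K[fa, s1], 0.5)
  expect_equal(K[mo, s2], 0.5)
  expect_equal(K[s1, s2], 0.5)
  expect_equal(K[fa, mo], 0)
  expect_equal(diag(K), setNames(rep(1, 4), ids))
  expect_true(isSymmetric(K))
  expect_true(all(ped$household == 1))

  # two families of 3 -> block-diagonal household with all-ones blocks
  cfg2 <- sim_config(seed = 1, n_families = 2, sibs_per_family = c(1, 1),
                     n_unrelated = 0, n_snps = 10)
  ped2 <- simulate_pedigree(cfg2)
  H <- ped2$household
  expect_equal(unname(H[1:3, 1:3]), matrix(1, 3, 3))
  expect_equal(unname(H[4:6, 4:6]), matrix(1, 3, 3))
  expect_equal(unname(H[1:3, 4:6]), matrix(0, 3, 3))

  # unrelated-only cohort -> identity matrices
  cfg3 <- sim_config(seed = 1, n_families = 0, n_unrelated = 5, n_snps = 10)
  ped3 <- simulate_pedigree(cfg3)
  expect_equal(unname(ped3$kinship), diag(5))
  expect_equal(unname(ped3$household), diag(5))

  # PSD after tiny ridge
  ev <- eigen(ped$kinship + diag(1e-8, 4), only.values = TRUE)$values
  expect_true(all(ev > 0))
  expect_error(simulate_pedigree(sim_config(n_families = 0, n_unrelated = 0,
                                            n_snps = 5)),
               "at least 2 samples")
})

test_that("founder haplotypes hit the adjacent-LD calibration target", {
  lay <- data.frame(chrom = "chr1", n_snps = 501, span_bp = 5e7)
  for (target in c(0, 0.6)) {
    cfg <- sim_config(seed = 11, n_families = 0, n_unrelated = 2000,
                      n_snps = 501, chrom_layout = lay,
                      adjacent_ld_r2 = target, maf_range = c(0.1, 0.45))
    g <- simulate_genotypes(cfg, simulate_pedigree(cfg))
    r2 <- vapply(1:500, function(k) {
      stats::cor(g$dosage[, k], g$dosage[, k + 1])^2
    }, numeric(1))
    if (target == 0) {
      expect_lt(mean(r2), 0.01)
    } else {
      expect_gt(mean(r2), 0.55)
      expect_lt(mean(r2), 0.65)
    }
    maf <- realized_maf(g)
    expect_true(all(maf > 0.05 & maf < 0.5))
  }
})

test_that("offspring dosages are Mendelian-consistent for all trios", {
  cfg <- sim_config(seed = 13, n_families = 40, sibs_per_family = c(2, 3),
                    n_unrelated = 0, n_snps = 80)
  ped <- simulate_pedigree(cfg)
  g <- simulate_genotypes(cfg, ped)
  pd <- ped$pedigree
  kids <- pd[!is.na(pd$father_id), ]
  for (r in seq_len(nrow(kids))) {
    child <- g$dosage[kids$sample_id[r], ]
    fa <- g$dosage[kids$father_id[r], ]
    mo <- g$dosage[kids$mother_id[r], ]
    lower <- (fa == 2) + (mo == 2)
    upper <- 2 - ((fa == 0) + (mo == 0))
    expect_true(all(child >= lower & child <= upper))
  }
  expect_true(all(g$dosage %in% 0:2))
})

test_that("latent methylation reproduces the configured covariance", {
  # null CpGs: sib correlation near zero
  co <- make_cohort(seed = 21, n_families = 200, sibs = c(2, 2),
                    n_cpgs = 6, p_cis_qtl = 0, h2 = c(0, 0), hh = c(0, 0))
  sp <- sib_pairs(co$ped)
  z <- co$truth$latent
  r_null <- mean(vapply(1:6, function(j) {
    stats::cor(z[sp[, 1], j], z[sp[, 2], j])
  }, numeric(1)))
  expect_lt(abs(r_null), 0.08)

  # h2 = 0.6: expected sib correlation 0.5 * h2 = 0.30
  co2 <- make_cohort(seed = 22, n_families = 400, sibs = c(2, 2),
                     n_cpgs = 8, p_cis_qtl = 0, h2 = c(0.6, 0.6),
                     hh = c(0, 0))
  sp2 <- sib_pairs(co2$ped)
  z2 <- co2$truth$latent
  r_h2 <- mean(vapply(1:8, function(j) {
    stats::cor(z2[sp2[, 1], j], z2[sp2[, 2], j])
  }, numeric(1)))
  expect_gt(r_h2, 0.22)
  expect_lt(r_h2, 0.38)

  # cis effect: R2 of latent on the causal dosage
  co3 <- make_cohort(seed = 23, n = 2000, n_snps = 60, n_cpgs = 10,
                     p_cis_qtl = 1, cis_effect_r2 = 0.10,
                     h2 = c(0.1, 0.1), hh = c(0, 0))
  r2s <- vapply(seq_len(10), function(j) {
    k <- co3$truth$cpg$causal_snp[j]
    if (is.na(k)) return(NA_real_)
    summary(stats::lm(co3$truth$latent[, j] ~ co3$geno$dosage[, k]))$r.squared
  }, numeric(1))
  r2s <- r2s[!is.na(r2s)]
  expect_gt(mean(r2s), 0.07)
  expect_lt(mean(r2s), 0.13)
})

test_that("recorded betas reproduce the configured variance fractions", {
  co <- make_cohort(seed = 31, n = 500, n_snps = 80, n_cpgs = 20,
                    p_cis_qtl = 1, cis_effect_r2 = 0.12)
  tc <- co$truth$cpg
  for (j in which(!is.na(tc$causal_snps))) {
    ks <- strsplit(tc$causal_snps[j], ";")[[1]]
    bks <- as.numeric(strsplit(tc$betas_latent[j], ";")[[1]])
    gv <- apply(co$geno$dosage[, ks, drop = FALSE], 2, stats::var)
    expect_equal(sum(bks^2 * gv), tc$r2_cis[j], tolerance = 1e-9)
  }
  expect_true(all(tc$h2 + tc$sigma2_h < 1))
  expect_true(all(co$meth$beta > 0.02 & co$meth$beta < 0.98))
})

test_that("generators are seed-deterministic", {
  co1 <- make_cohort(seed = 41, n = 100, n_snps = 40, n_cpgs = 10)
  co2 <- make_cohort(seed = 41, n = 100, n_snps = 40, n_cpgs = 10)
  expect_identical(co1$geno$dosage, co2$geno$dosage)
  expect_identical(co1$meth$beta, co2$meth$beta)
  expect_identical(co1$truth$cpg, co2$truth$cpg)
})

test_that("expression generator separates shared and distinct causal variants", {
  lay <- data.frame(chrom = "chr1", n_snps = 120, span_bp = 2e6)
  top_snp <- function(y, D) colnames(D)[which.max(abs(stats::cor(D, y)))]
  shared_hits <- 0; n_rep <- 12
  for (rep in seq_len(n_rep)) {
    cfg <- sim_config(seed = 500 + rep, n_families = 0, n_unrelated = 2000,
                      n_snps = 120, n_cpgs = 4, n_genes = 3,
                      chrom_layout = lay, p_cis_qtl = 1, cis_effect_r2 = 0.2,
                      gene_cis_r2 = 0.2, p_cis_eqtl = 0,
                      h2_additive_range = c(0.2, 0.2),
                      household_var_range = c(0, 0),
                      coloc_spec = data.frame(cpg_index = c(1, 2),
                                              gene_index = c(1, 2),
                                              shared = c(TRUE, FALSE)))
    ped <- simulate_pedigree(cfg)
    g <- simulate_genotypes(cfg, ped)
    sim <- simulate_methylation(g, ped$kinship, ped$household, cfg)
    ex <- simulate_expression(g, sim$methylation, cfg, sim$truth)
    tg <- ex$truth$gene
    # shared pair: same top associated variant for both traits
    ts_c <- top_snp(sim$methylation$beta[, 1], g$dosage)
    ts_g <- top_snp(ex$expression$expr[, 1], g$dosage)
    if (ts_c == ts_g) shared_hits <- shared_hits + 1
    # distinct pair: different causal SNPs in low LD by construction
    c2 <- sim$truth$cpg$causal_snp[2]
    g2 <- tg$causal_snp[2]
    expect_false(c2 == g2)
    expect_lt(stats::cor(g$dosage[, c2], g$dosage[, g2])^2, 0.05)
    # zero-effect gene: no regional association
    expect_lt(max(abs(stats::cor(g$dosage, ex$expression$expr[, 3]))), 0.1)
  }
  expect_gte(shared_hits / n_rep, 0.95)
})

test_that("outcome GWAS swaps alleles recoverably and flips IVW under no harmonization", {
  co <- cached("mr_cohort", make_cohort(
    seed = 61, n = 1500, n_snps = 300, n_cpgs = 6,
    chrom_layout = data.frame(chrom = "chr1", n_snps = 300, span_bp = 8e6),
    p_cis_qtl = 1, cis_effect_r2 = 0.2, n_causal_per_cpg = 5,
    theta_causal = 0.5, allele_swap_frac = 1, gwas_n = 50000))
  resid <- residualize_methylation(co$meth, NULL, co$ped$kinship)
  pre <- fast_linear_scan(resid, co$geno, scan_config())
  cis <- pre[pre$class == "cis", ]
  outc <- simulate_outcome_gwas(co$truth, cis, co$config)
  expect_true(all(attr(outc, "swapped")))
  cg <- names(which.max(table(cis$cpg_id)))
  rec <- cis[cis$cpg_id == cg, ]
  ivs <- select_ivs(rec, co$geno)
  expect_false(attr(ivs, "insufficient"))
  expo <- exposure_table(rec[match(ivs, rec$snp_id), ], co$geno)
  oc <- outc[match(ivs, outc$snp_id), ]
  # harmonized: estimate near +theta
  al <- harmonize(expo, oc)
  expect_true(all(al$harmonization_action %in% c("sign_flipped",
                                                 "dropped_palindromic")))
  th_harm <- ivw_mr(al)$theta
  # harmonization disabled (take outcome beta at face value): ~ -theta
  al_raw <- al
  al_raw$Gamma <- oc$beta[match(al$snp_id, oc$snp_id)]
  al_raw$kept <- TRUE
  th_raw <- ivw_mr(al_raw)$theta
  expect_gt(th_harm, 0)
  expect_lt(th_raw, 0)
  expect_equal(th_raw, -th_harm, tolerance = 1e-10)
  expect_error(simulate_outcome_gwas(co$truth, cis,
                                     sim_config(gwas_n = 5)),
               "gwas_n")
})

test_that("configuration validation rejects degenerate requests", {
  expect_error(sim_config(maf_range = c(0.2, 0.1)), "maf_range")
  expect_error(sim_config(adjacent_ld_r2 = 1), "adjacent_ld_r2")
  expect_error(sim_config(h2_additive_range = c(0.8, 0.8),
                          household_var_range = c(0.3, 0.3)),
               "below 1")
  cfg <- sim_config(seed = 1, n_families = 0, n_unrelated = 10, n_snps = 10,
                    maf_range = c(0.2, 0.2 + 1e-8))
  expect_error(simulate_genotypes(cfg, simulate_pedigree(cfg)),
               "degenerate maf_range")
})
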