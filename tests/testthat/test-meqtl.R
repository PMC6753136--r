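test_that("classify_pair partitions every pair into exactly one class", {
  cfg <- scan_config()
  expect_equal(classify_pair("chr1", 1e6, "chr1", 1.5e6, cfg), "cis")
  expect_equal(classify_pair("chr1", 1e6, "chr1", 4e6, cfg), "long_range_cis")
  expect_equal(classify_pair("chr1", 123, "chr2", 99, cfg), "trans_inter")
  expect_equal(classify_pair("chr1", 1, "chr1", 1 + 1e6, cfg), "cis") # inclusive
  expect_equal(classify_pair("chr1", 1, "chr1", 1 + 1e6 + 1, cfg),
               "long_range_cis")
  expect_equal(classify_pair("chr1", 1, "chr1", 1 + 5e6 + 1, cfg),
               "trans_intra")
  set.seed(3)
  cls <- classify_pair(sample(c("chr1", "chr2"), 500, TRUE),
                       sample.int(2e7, 500),
                       sample(c("chr1", "chr2"), 500, TRUE),
                       sample.int(2e7, 500), cfg)
  expect_true(all(cls %in% c("cis", "long_range_cis", "trans_intra",
                             "trans_inter")))
  expect_error(scan_config(cis_window = 5e6, long_range_limit = 1e6))
})

test_that("residualization collapses to OLS for unrelated samples and absorbs kinship", {
  co <- cached("unrel_cohort", make_cohort(seed = 51, n = 300, n_snps = 60,
                                           n_cpgs = 12))
  X <- cbind(age = stats::rnorm(300), sex = stats::rbinom(300, 1, 0.5))
  res <- residualize_methylation(co$meth, X, co$ped$kinship)
  expect_lt(max(abs(colMeans(res))), 1e-8)
  ols <- apply(co$meth$beta, 2, function(y) stats::lm.fit(cbind(1, X), y)$residuals)
  expect_lt(max(abs(res - ols)), 1e-6)

  # covariates that contain the CpG itself leave nothing
  res2 <- residualize_methylation(co$meth$beta[, 1, drop = FALSE],
                                  cbind(X, co$meth$beta[, 1]), co$ped$kinship)
  expect_lt(max(abs(res2)), 1e-8)

  # family cohort: kinship random effect shrinks sib-pair correlation
  fam <- cached("fam_cohort", make_cohort(seed = 52, n_families = 250,
                                          sibs = c(2, 2), n_cpgs = 10,
                                          n_snps = 20, p_cis_qtl = 0,
                                          h2 = c(0.5, 0.5), hh = c(0, 0)))
  sp <- sib_pairs(fam$ped)
  resf <- residualize_methylation(fam$meth, NULL, fam$ped$kinship)
  raw_cor <- mean(vapply(1:10, function(j)
    stats::cor(fam$meth$beta[sp[, 1], j], fam$meth$beta[sp[, 2], j]),
    numeric(1)))
  res_cor <- mean(vapply(1:10, function(j)
    stats::cor(resf[sp[, 1], j], resf[sp[, 2], j]), numeric(1)))
  expect_lt(res_cor, raw_cor)
})

test_that("the fast scan is calibrated under the null and catches planted effects", {
  # null: >= 1e6 permuted tests, prefilter pass rate at the cis threshold
  set.seed(7)
  n <- 500
  R <- matrix(stats::rnorm(n * 1000), n, 1000)
  D <- matrix(stats::rbinom(n * 1000, 2, 0.3), n, 1000)
  g <- as_genotypes(D)
  cmap <- data.frame(cpg_id = sprintf("cg%04d", 1:1000), chrom = "chr1",
                     pos = seq_len(1000) * 1000)
  attr(R, "cpg_map") <- cmap
  sc <- scan_config(prefilter_cis_p = 1e-6, prefilter_trans_p = 1e-6)
  pre <- fast_linear_scan(R, g, sc)
  expect_lte(nrow(pre) / 1e6, 6e-6)

  # planted r2 = 0.1 at n = 500 passes the cis prefilter almost surely
  hits <- vapply(1:20, function(r) {
    set.seed(100 + r)
    x <- stats::rbinom(n, 2, 0.3)
    y <- sqrt(0.1 / stats::var(x)) * x + stats::rnorm(n, 0, sqrt(0.9))
    Y <- matrix(y, ncol = 1)
    attr(Y, "cpg_map") <- data.frame(cpg_id = "cg1", chrom = "chr1", pos = 1000)
    p1 <- fast_linear_scan(Y, as_genotypes(matrix(x, ncol = 1)), sc)
    nrow(p1) == 1
  }, logical(1))
  expect_gte(mean(hits), 0.95)
  # default thresholds are the liberal prefilters
  expect_equal(scan_config()$prefilter_cis_p, 1e-6)
  expect_equal(scan_config()$prefilter_trans_p, 1e-10)
})

test_that("stage-two refit equals the direct joint regression on unrelated samples", {
  co <- cached("unrel_cohort", make_cohort(seed = 51, n = 300, n_snps = 60,
                                           n_cpgs = 12))
  X <- cbind(age = stats::rnorm(300))
  res <- residualize_methylation(co$meth, X, co$ped$kinship)
  pre <- fast_linear_scan(res, co$geno,
                          scan_config(prefilter_cis_p = 1e-2,
                                      prefilter_trans_p = 1e-2),
                          covariates = X)
  fin <- lme_refit(pre, co$meth, co$geno, X, co$ped$kinship)
  expect_gt(nrow(fin), 5)
  for (r in seq_len(min(nrow(fin), 30))) {
    y <- co$meth$beta[, fin$cpg_id[r]]
    x <- co$geno$dosage[, fin$snp_id[r]]
    sm <- summary(stats::lm(y ~ X + x))$coefficients
    expect_equal(fin$t[r], sm["x", "t value"], tolerance = 1e-6)
    expect_equal(pre$t[r], sm["x", "t value"], tolerance = 1e-6)
  }
  # sign preservation between stages
  expect_true(all(sign(fin$beta) == sign(pre$beta)))
})

test_that("the mixed-model refit deflates family-confounded associations", {
  worse <- vapply(1:20, function(r) {
    co <- make_cohort(seed = 600 + r, n_families = 120, sibs = c(2, 2),
                      n_cpgs = 1, n_snps = 40, p_cis_qtl = 0,
                      h2 = c(0.3, 0.3), hh = c(0.3, 0.3))
    # family-structured CpG scanned against all SNPs without adjustment
    Y <- co$meth$beta
    attr(Y, "cpg_map") <- co$meth$map
    pre <- fast_linear_scan(Y, co$geno,
                            scan_config(prefilter_cis_p = 1,
                                        prefilter_trans_p = 1))
    top <- pre[1, ]
    fin <- lme_refit(top, co$meth, co$geno, NULL, co$ped$kinship)
    fin$p[1] > top$p
  }, logical(1))
  expect_gte(mean(worse), 0.8)
})

test_that("final thresholds reproduce the Bonferroni arithmetic and hand filtering", {
  sc <- scan_config(alpha = 0.05)
  toy <- data.frame(snp_id = paste0("s", 1:10), cpg_id = paste0("c", 1:10),
                    chrom_snp = "chr1", pos_snp = 1:10,
                    chrom_cpg = "chr1", pos_cpg = 1:10,
                    beta = 1, se = 1, t = 1,
                    p = c(1e-12, 5e-11, 1e-3, 1e-8, 0.2,
                          1e-9, 1e-13, 1e-2, 1e-7, 1e-15),
                    class = c("cis", "cis", "cis", "trans_inter",
                              "trans_intra", "long_range_cis", "cis",
                              "trans_inter", "trans_intra", "trans_inter"),
                    stage = "final", stringsAsFactors = FALSE)
  out <- apply_significance(toy, sc, n_cis_tests = 2.5e9, n_trans_tests = 3.5e12)
  expect_equal(out$cis_threshold, 2e-11)
  expect_equal(out$trans_threshold, 0.05 / 3.5e12)
  # hand filter: cis pass if p < 2e-11 -> s1, s7; trans pass if p < 1.43e-14
  # -> s10; long-range excluded regardless
  expect_setequal(out$records$snp_id, c("s1", "s7", "s10"))
  out2 <- apply_significance(toy, scan_config(), n_cis_tests = 1,
                             n_trans_tests = 1)
  expect_equal(out2$cis_threshold, 0.05)
  expect_error(apply_significance(toy, scan_config()), "test counts")
})

test_that("ld_prune matches a brute-force greedy oracle and its output is independent", {
  set.seed(11)
  n <- 400
  # 20 SNPs: 4 correlated blocks of 5
  base <- matrix(stats::rbinom(n * 4, 2, 0.4), n, 4)
  D <- matrix(0, n, 20, dimnames = list(NULL, sprintf("s%03d", 1:20)))
  for (b in 1:4) for (k in 1:5) {
    flip <- stats::runif(n) < 0.08
    v <- base[, b]
    v[flip] <- stats::rbinom(sum(flip), 2, 0.4)
    D[, (b - 1) * 5 + k] <- v
  }
  g <- as_genotypes(D)
  p <- stats::runif(20)
  thr <- 0.2
  kept <- ld_prune(colnames(D), g, thr, p = p)
  # brute-force oracle re-implementation
  C2 <- stats::cor(D)^2
  ord <- order(p, g$map$pos, colnames(D))
  oracle <- integer(0)
  for (i in ord) {
    if (all(C2[i, oracle] < thr) || length(oracle) == 0) oracle <- c(oracle, i)
  }
  expect_identical(as.character(kept), colnames(D)[oracle])
  # output property: max pairwise r2 below threshold
  if (length(kept) > 1) {
    r2k <- stats::cor(D[, kept])^2
    expect_lt(max(r2k[upper.tri(r2k)]), thr)
  }
  # two SNPs r2 >= threshold: lower-p one kept
  k2 <- ld_prune(colnames(D)[1:2], g, 0.2, p = c(0.5, 0.01))
  expect_identical(as.character(k2), colnames(D)[2])
  # independent SNPs: all kept
  D0 <- matrix(stats::rbinom(n * 5, 2, 0.4), n, 5)
  expect_length(ld_prune(paste0("s00", 1:5), as_genotypes(D0), 0.2,
                         p = stats::runif(5)), 5)
  # missing SNPs dropped with a record
  km <- ld_prune(c(colnames(D)[1], "absent"), g, 0.2, p = c(0.1, 0.2))
  expect_identical(attr(km, "dropped_missing"), "absent")
})

test_that("genomic control matches its definition and scales with inflation", {
  set.seed(12)
  p <- stats::runif(1e6)
  expect_lt(abs(genomic_control(p) - 1), 0.005)
  expect_equal(suppressWarnings(genomic_control(rep(0.5, 100))), 1)
  chi_inflated <- stats::qchisq(p, 1, lower.tail = FALSE) * 1.2
  p_inf <- stats::pchisq(chi_inflated, 1, lower.tail = FALSE)
  lam <- genomic_control(p_inf)
  expect_gt(lam, 1.18); expect_lt(lam, 1.22)
  expect_error(genomic_control(c(0.5, 0)), "input error")
})

test_that("replication concordance counts matched directions and rates", {
  disc <- data.frame(snp_id = paste0("s", 1:6), cpg_id = paste0("c", 1:6),
                     beta = c(1, -1, 2, -2, 0.5, -0.5),
                     p = rep(1e-12, 6), stringsAsFactors = FALSE)
  expect_equal(replication_concordance(disc, disc)$directional_concordance, 100)
  neg <- disc; neg$beta <- -neg$beta
  expect_equal(replication_concordance(disc, neg)$directional_concordance, 0)
  empty <- disc[0, ]
  expect_warning(out <- replication_concordance(disc, empty), "no matched")
  expect_equal(out$n_matched, 0L)
})

test_that("discovery and a smaller replication split agree in direction for true pairs", {
  co <- make_cohort(seed = 71, n = 2000, n_snps = 120, n_cpgs = 40,
                    p_cis_qtl = 1, cis_effect_r2 = 0.15,
                    h2 = c(0.15, 0.15), hh = c(0, 0))
  sc <- scan_config(prefilter_cis_p = 1, prefilter_trans_p = 1e-300)
  scan_subset <- function(idx) {
    sub <- co$meth$beta[idx, , drop = FALSE]
    g <- co$geno; g$dosage <- g$dosage[idx, , drop = FALSE]
    pre <- fast_linear_scan(scale(sub, scale = FALSE), g, sc,
                            cpg_map = co$meth$map)
    pre[pre$class == "cis", ]
  }
  disc <- scan_subset(seq_len(1500))        # discovery cohort
  repl <- scan_subset(1501:2000)            # disjoint replication cohort
  tp <- co$truth$cpg[!is.na(co$truth$cpg$causal_snp), ]
  keyD <- paste(disc$snp_id, disc$cpg_id)
  mD <- disc[stats::na.omit(match(paste(tp$causal_snp, tp$cpg_id), keyD)), ]
  cc <- replication_concordance(mD, repl)
  expect_gt(cc$n_matched, 20)
  expect_gte(cc$directional_concordance, 95)
})
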