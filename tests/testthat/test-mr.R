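test_that("instrument selection prunes LD blocks down to index variants", {
  set.seed(21)
  n <- 500
  # 12 SNPs in three tight blocks of four
  base <- matrix(stats::rbinom(n * 3, 2, 0.4), n, 3)
  D <- matrix(0, n, 12, dimnames = list(NULL, sprintf("b%02d", 1:12)))
  for (b in 1:3) for (k in 1:4) {
    v <- base[, b]
    flip <- stats::runif(n) < 0.02
    v[flip] <- stats::rbinom(sum(flip), 2, 0.4)
    D[, (b - 1) * 4 + k] <- v
  }
  g <- as_genotypes(D)
  rec <- data.frame(snp_id = colnames(D), p = stats::runif(12, 1e-20, 1e-10))
  ivs <- select_ivs(rec, g)
  expect_length(ivs, 3)
  expect_false(attr(ivs, "insufficient"))
  # lowest-p member of each block is the one retained
  for (b in 1:3) {
    blk <- colnames(D)[(b - 1) * 4 + 1:4]
    expect_equal(intersect(ivs, blk), blk[which.min(rec$p[(b - 1) * 4 + 1:4])])
  }
  # one tight block -> single instrument -> insufficient
  rec1 <- rec[1:4, ]
  ivs1 <- select_ivs(rec1, g)
  expect_length(ivs1, 1)
  expect_true(attr(ivs1, "insufficient"))
  # independent SNPs all retained
  D0 <- matrix(stats::rbinom(n * 5, 2, 0.4), n, 5,
               dimnames = list(NULL, paste0("u", 1:5)))
  ivs0 <- select_ivs(data.frame(snp_id = paste0("u", 1:5),
                                p = stats::runif(5)), as_genotypes(D0))
  expect_length(ivs0, 5)
})

test_that("harmonization keeps, flips, and drops rows per the allele rules", {
  expo <- data.frame(snp_id = c("a", "b", "c", "d"),
                     effect_allele = c("A", "C", "A", "G"),
                     other_allele = c("G", "T", "T", "C"),
                     beta = c(0.5, 0.4, 0.3, 0.2), se = 0.05,
                     maf = c(0.3, 0.2, 0.5, 0.1), p = 1e-8,
                     stringsAsFactors = FALSE)
  outc <- data.frame(snp_id = c("a", "b", "c", "x"),
                     effect_allele = c("A", "T", "A", "A"),
                     other_allele = c("G", "C", "T", "G"),
                     beta = c(0.1, 0.2, 0.3, 0.4), se = 0.05,
                     stringsAsFactors = FALSE)
  al <- harmonize(expo, outc)
  expect_equal(al$harmonization_action,
               c("kept", "sign_flipped", "dropped_palindromic",
                 "dropped_unmatched"))
  expect_equal(al$Gamma[1:2], c(0.1, -0.2))
  # non-ambiguous palindromic SNP (maf far from 0.5) is kept
  expo2 <- expo[3, ]; expo2$maf <- 0.1
  expect_equal(harmonize(expo2, outc)$harmonization_action, "kept")
})

test_that("IVW reduces to the shared ratio and is an exact weighted regression", {
  tab <- iv_table(c(0.5, 0.4, 0.2), c(0.25, 0.20, 0.10), c(0.1, 0.1, 0.1))
  f <- ivw_mr(tab)
  expect_equal(f$theta, 0.5, tolerance = 1e-12)
  q <- cochran_q(tab, f$theta)
  expect_equal(q$q_stat, 0, tolerance = 1e-12)
  expect_equal(q$p_heter, 1)
  # identity with through-origin weighted least squares
  set.seed(31)
  for (r in 1:5) {
    tb <- iv_table(stats::runif(8, 0.1, 0.6), stats::rnorm(8, 0.1, 0.2),
                   stats::runif(8, 0.02, 0.2))
    wls <- stats::lm(Gamma ~ 0 + gamma, data = tb, weights = 1 / tb$se_Gamma^2)
    expect_equal(ivw_mr(tb)$theta, unname(stats::coef(wls)), tolerance = 1e-10)
    # invariance to ordering and simultaneous sign flips
    perm <- sample(8)
    expect_equal(ivw_mr(tb[perm, ])$theta, ivw_mr(tb)$theta)
    fl <- tb; fl$gamma <- -fl$gamma; fl$Gamma <- -fl$Gamma
    expect_equal(ivw_mr(fl)$theta, ivw_mr(tb)$theta, tolerance = 1e-12)
  }
  # zero-gamma instruments rejected pre-fit
  tb0 <- iv_table(c(0, 0.4, 0.3), c(0.1, 0.2, 0.15), rep(0.05, 3))
  expect_equal(ivw_mr(tb0)$J, 2)
  # null calibration of the estimate
  set.seed(32)
  sims <- replicate(500, {
    tb <- iv_table(stats::runif(6, 0.2, 0.6), stats::rnorm(6, 0, 0.05), 0.05)
    f <- ivw_mr(tb); c(f$theta, f$se_theta)
  })
  expect_lt(abs(mean(sims[1, ])), 2 * mean(sims[2, ]) / sqrt(500))
})

test_that("Cochran's Q matches hand arithmetic and is chi-square calibrated", {
  tab <- iv_table(c(1, 1, 1), c(0.5, 0.5, 1.5), c(0.5, 0.5, 0.5))
  th <- ivw_mr(tab)$theta
  expect_equal(th, (0.5 + 0.5 + 1.5) / 3)
  q <- cochran_q(tab, th)
  expect_equal(q$q_stat, 8 / 3, tolerance = 1e-12)   # 4*(2*(1/3)^2+(2/3)^2)
  expect_equal(q$p_heter, stats::pchisq(8 / 3, 2, lower.tail = FALSE))
  set.seed(41)
  rej <- replicate(1000, {
    tb <- iv_table(stats::runif(6, 0.2, 0.6),
                   0.3 * stats::runif(6, 0.2, 0.6), 0.05)
    tb$Gamma <- 0.3 * tb$gamma + stats::rnorm(6, 0, 0.05)
    f <- ivw_mr(tb)
    cochran_q(tb, f$theta)$p_heter < 0.05
  })
  expect_gte(mean(rej), 0.03)
  expect_lte(mean(rej), 0.07)
})

test_that("the Egger intercept recovers planted directional pleiotropy", {
  set.seed(51)
  ints <- replicate(200, {
    J <- 10
    gam <- stats::runif(J, 0.2, 0.6)
    seG <- stats::runif(J, 0.05, 0.1)
    Gam <- 0.3 * gam + 0.1 + stats::rnorm(J, 0, seG)
    egger_intercept(iv_table(gam, Gam, seG))$intercept
  })
  expect_gt(mean(ints), 0.07)
  expect_lt(mean(ints), 0.13)
  # null pleiotropy: mean intercept within 2 MC se of 0
  set.seed(52)
  ints0 <- replicate(200, {
    J <- 10
    gam <- stats::runif(J, 0.2, 0.6)
    Gam <- 0.3 * gam + stats::rnorm(J, 0, 0.05)
    egger_intercept(iv_table(gam, Gam, rep(0.05, J)))$intercept
  })
  expect_lt(abs(mean(ints0)), 2 * stats::sd(ints0) / sqrt(200))
  # equal outcome ses: weighted equals unweighted fit
  tb <- iv_table(c(0.2, 0.3, 0.5, 0.6), c(0.15, 0.2, 0.3, 0.33), rep(0.07, 4))
  eg <- egger_intercept(tb)
  un <- stats::lm(tb$Gamma ~ tb$gamma)
  expect_equal(eg$intercept, unname(stats::coef(un)[1]), tolerance = 1e-10)
  expect_error(egger_intercept(iv_table(c(0.3, 0.3, -0.3),
                                        c(0.1, 0.1, -0.1), rep(0.05, 3))),
               "collinearity")
})

test_that("stepwise refinement excludes the Q-dominant outlier first", {
  # clean table: no exclusions
  set.seed(61)
  gam <- stats::runif(8, 0.3, 0.6)
  tb <- iv_table(gam, 0.5 * gam + stats::rnorm(8, 0, 0.02), rep(0.02, 8))
  r <- stepwise_iv_refinement(tb, binary_outcome = FALSE)
  expect_equal(r$n_iv_final, r$n_iv_initial)
  expect_length(r$excluded_ivs, 0)
  expect_true(r$status %in% c("significant", "not_significant"))
  # a 10x-ratio outlier is removed first and the refit then passes
  set.seed(62)
  ok <- replicate(100, {
    gam <- stats::runif(10, 0.3, 0.6)
    Gam <- 0.5 * gam + stats::rnorm(10, 0, 0.02)
    Gam[7] <- 5 * gam[7]
    r <- stepwise_iv_refinement(iv_table(gam, Gam, rep(0.02, 10)),
                                binary_outcome = FALSE)
    length(r$excluded_ivs) >= 1 && r$excluded_ivs[1] == "iv7" &&
      r$p_heter > 0.05 && r$p_pleio > 0.05
  })
  expect_gte(mean(ok), 0.9)
  # four mutually inconsistent instruments can never end significant
  tb4 <- iv_table(c(0.5, 0.5, 0.5, 0.5), c(0.05, 0.6, -0.5, 1.2),
                  rep(0.01, 4))
  r4 <- stepwise_iv_refinement(tb4, binary_outcome = FALSE)
  expect_true(r4$status %in% c("diagnostics_failed", "insufficient_ivs"))
  expect_lte(length(r4$excluded_ivs), 4 - 3)
  expect_equal(r4$n_iv_initial - r4$n_iv_final, length(r4$excluded_ivs))
  # fewer than three instruments to begin with
  expect_equal(stepwise_iv_refinement(tb4[1:2, ])$status, "insufficient_ivs")
})

test_that("index-CpG pruning collapses correlated clusters by MR p-value", {
  pos <- data.frame(cpg_id = paste0("c", 1:2), chrom = "chr1",
                    pos = c(1e6, 2e6))
  cm <- matrix(c(1, sqrt(0.8), sqrt(0.8), 1), 2,
               dimnames = list(pos$cpg_id, pos$cpg_id))
  p <- c(c1 = 1e-8, c2 = 1e-5)
  out <- prune_cpgs(pos, cm, p)
  expect_true(out$kept[1]); expect_false(out$kept[2])
  expect_equal(out$index_cpg, c("c1", "c1"))
  # outside the window both survive regardless of correlation
  pos2 <- pos; pos2$pos <- c(1e6, 4.5e6)
  cm2 <- cm; cm2[1, 2] <- cm2[2, 1] <- sqrt(0.9)
  expect_true(all(prune_cpgs(pos2, cm2, p)$kept))
  # five CpGs with known blocks match a brute-force clustering oracle
  pos5 <- data.frame(cpg_id = paste0("c", 1:5), chrom = "chr1",
                     pos = c(1e6, 1.5e6, 2e6, 9e6, 9.5e6))
  r2m <- diag(5)
  r2m[1, 2] <- r2m[2, 1] <- 0.7
  r2m[2, 3] <- r2m[3, 2] <- 0.6
  r2m[4, 5] <- r2m[5, 4] <- 0.9
  cm5 <- sqrt(r2m)
  dimnames(cm5) <- list(pos5$cpg_id, pos5$cpg_id)
  p5 <- c(c1 = 1e-4, c2 = 1e-9, c3 = 1e-5, c4 = 1e-3, c5 = 1e-7)
  out5 <- prune_cpgs(pos5, cm5, p5)
  # clusters {c1,c2,c3} (chained) and {c4,c5}: keep c2 and c5
  expect_setequal(out5$cpg_id[out5$kept], c("c2", "c5"))
})

test_that("multivariable MR reduces to IVW and isolates the causal exposure", {
  tb <- iv_table(stats::runif(6, 0.2, 0.6), stats::rnorm(6, 0.1, 0.1),
                 rep(0.05, 6))
  mv <- multivariable_mr(matrix(tb$gamma, ncol = 1,
                                dimnames = list(NULL, "only")),
                         tb$Gamma, tb$se_Gamma)
  expect_equal(mv$theta, ivw_mr(tb)$theta, tolerance = 1e-10)
  set.seed(71)
  est <- replicate(100, {
    J <- 12
    g1 <- stats::runif(J, 0.2, 0.6)
    g2 <- 0.4 * g1 + stats::runif(J, 0.1, 0.4)  # correlated exposures
    Gam <- 0.4 * g1 + 0 * g2 + stats::rnorm(J, 0, 0.03)
    multivariable_mr(cbind(cpgA = g1, cpgB = g2), Gam, rep(0.03, J))$theta
  })
  expect_gt(mean(est[1, ]), 0.3); expect_lt(mean(est[1, ]), 0.5)
  expect_lt(abs(mean(est[2, ])), 0.1)
  expect_error(multivariable_mr(cbind(a = tb$gamma, b = tb$gamma),
                                tb$Gamma, tb$se_Gamma), "collinearity")
})

test_that("expression MR applies the 0.05/8 threshold and Wald fallback", {
  set.seed(81)
  n <- 800
  D <- matrix(stats::rbinom(n * 40, 2, 0.3), n, 40,
              dimnames = list(NULL, sprintf("e%02d", 1:40)))
  g <- as_genotypes(D)
  # protective gene: theta = -0.8
  hits <- replicate(30, {
    ivk <- sample(40, 5)
    gam <- stats::runif(5, 0.3, 0.6)
    outc <- data.frame(snp_id = colnames(D)[ivk], effect_allele = "A",
                       other_allele = "G",
                       beta = -0.8 * gam + stats::rnorm(5, 0, 0.03),
                       se = 0.03, stringsAsFactors = FALSE)
    rec <- data.frame(snp_id = colnames(D)[ivk], gene_id = "G1",
                      effect_allele = "A", other_allele = "G",
                      beta = gam, se = 0.02, p = 1e-12,
                      maf = 0.3, stringsAsFactors = FALSE)
    res <- mr_for_expression(rec, outc, g, n_genes_tested = 8)
    expect_equal(attr(res, "p_threshold"), 0.00625)
    res$or_value < 1 && res$p_mr < 0.00625
  })
  expect_gte(mean(hits), 0.9)
  # single instrument: Wald ratio formula
  rec1 <- data.frame(snp_id = "e01", gene_id = "G1", effect_allele = "A",
                     other_allele = "G", beta = 0.5, se = 0.02, p = 1e-10,
                     maf = 0.3, stringsAsFactors = FALSE)
  out1 <- data.frame(snp_id = "e01", effect_allele = "A", other_allele = "G",
                     beta = 0.2, se = 0.05, stringsAsFactors = FALSE)
  res1 <- mr_for_expression(rec1, out1, g, n_genes_tested = 8)
  expect_equal(res1$theta, 0.2 / 0.5)
  expect_equal(res1$se_theta, 0.05 / 0.5)
})
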