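#!/usr/bin/env Rscript
# Stage 4: two-sample MR of CpG methylation on the simulated outcome trait.
# Instruments are independent cis-meQTLs (LD r2 < 0.01, >= 3 per CpG);
# IVW with heterogeneity/pleiotropy diagnostics and stepwise refinement.

source("analysis/00_config.R")

co <- build_cohort()
scan <- two_step_scan(co)
cis <- scan$sig$records[scan$sig$records$class == "cis", ]
outcome <- simulate_outcome_gwas(co$truth, cis, co$cfg)
expo_all <- exposure_table(cis, co$geno)

rows <- list()
for (cg in unique(cis$cpg_id)) {
  rec <- cis[cis$cpg_id == cg, ]
  ivs <- select_ivs(rec, co$geno)
  if (attr(ivs, "insufficient")) next
  expo <- expo_all[expo_all$cpg_id == cg & expo_all$snp_id %in% ivs, ]
  oc <- outcome[match(expo$snp_id, outcome$snp_id), ]
  res <- stepwise_iv_refinement(harmonize(expo, oc), binary_outcome = FALSE)
  rows[[cg]] <- data.frame(
    exposure_id = cg, theta = res$theta, se = res$se_theta, p_mr = res$p_mr,
    q = res$q_stat, p_heter = res$p_heter,
    egger_intercept = res$egger_intercept, p_pleio = res$p_pleio,
    n_iv_initial = res$n_iv_initial, n_iv_final = res$n_iv_final,
    status = res$status,
    excluded_ivs = paste(res$excluded_ivs, collapse = ";"))
}
mr_tab <- do.call(rbind, rows)
if (is.null(mr_tab)) stop("no CpG reached the 3-instrument minimum")
mr_tab$p_bonf <- pmin(1, mr_tab$p_mr * nrow(mr_tab))
write_result_tsv(mr_tab, file.path(RESULTS_DIR, "mr_results.tsv"),
                 seed = STUDY_SEED)

cat(sprintf("MR run on %d CpGs with >= 3 independent instruments\n",
            nrow(mr_tab)))
cat(sprintf("true causal effect theta = %.2f; mean estimate %.3f (sd %.3f)\n",
            co$cfg$theta_causal, mean(mr_tab$theta), sd(mr_tab$theta)))
cat(sprintf("diagnostics-clean fits: %d; Bonferroni-significant: %d\n",
            sum(mr_tab$p_heter > 0.05 & mr_tab$p_pleio > 0.05),
            sum(mr_tab$p_bonf < 0.05)))
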