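# Shared study configuration for the analysis drivers.
# Sourced by every numbered script; regenerating the cohort from this seed
# is deterministic, so each stage can be run independently.

library(meqtlmr)

STUDY_SEED <- 20260920L
RESULTS_DIR <- "results"
dir.create(RESULTS_DIR, showWarnings = FALSE)

study_config <- function() {
  sim_config(
    seed = STUDY_SEED,
    n_families = 150, sibs_per_family = c(2, 3), n_unrelated = 150,
    n_snps = 600, n_cpgs = 120, n_genes = 12,
    chrom_layout = data.frame(chrom = c("chr1", "chr2"),
                              n_snps = c(300, 300), span_bp = c(3e7, 3e7)),
    adjacent_ld_r2 = 0.3, maf_range = c(0.05, 0.45),
    p_cis_qtl = 0.4, cis_effect_r2 = 0.2, n_causal_per_cpg = 3,
    h2_additive_range = c(0, 0.3), household_var_range = c(0, 0.1),
    hotspot_spec = data.frame(snp_index = 40, n_targets = 35,
                              mediation_r2 = 0.5),
    coloc_spec = data.frame(cpg_index = c(5, 6), gene_index = c(2, 3),
                            shared = c(TRUE, FALSE)),
    theta_causal = 0.5, gwas_n = 50000, allele_swap_frac = 0.2)
}

build_cohort <- function(cfg = study_config()) {
  ped <- simulate_pedigree(cfg)
  geno <- simulate_genotypes(cfg, ped)
  sim <- simulate_methylation(geno, ped$kinship, ped$household, cfg)
  ex <- simulate_expression(geno, sim$methylation, cfg, sim$truth)
  list(cfg = cfg, ped = ped, geno = geno, meth = sim$methylation,
       expr = ex$expression, truth = ex$truth)
}

two_step_scan <- function(co) {
  resid <- residualize_methylation(co$meth, NULL, co$ped$kinship)
  sc <- scan_config()
  pre <- fast_linear_scan(resid, co$geno, sc)
  nbc <- attr(pre, "n_tests_by_class")
  fin <- lme_refit(pre, co$meth, co$geno, NULL, co$ped$kinship)
  sig <- apply_significance(fin, sc,
                            n_cis_tests = max(1, nbc[["cis"]]),
                            n_trans_tests = max(1, nbc[["trans_intra"]] +
                                                  nbc[["trans_inter"]]))
  list(resid = resid, prefilter = pre, final = fin, sig = sig,
       n_tests = nbc)
}
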