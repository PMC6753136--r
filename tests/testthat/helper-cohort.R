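# Shared fixture builders. Everything is generated in code under fixed
# seeds; heavier cohorts are cached per test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# small unrelated cohort with planted cis effects
make_cohort <- function(seed, n = 400, n_snps = 100, n_cpgs = 30,
                        p_cis_qtl = 0.5, cis_effect_r2 = 0.1,
                        n_families = 0, sibs = c(2, 2), h2 = c(0, 0.2),
                        hh = c(0, 0.05), ...) {
  cfg <- sim_config(seed = seed, n_families = n_families,
                    sibs_per_family = sibs,
                    n_unrelated = if (n_families == 0) n else 0,
                    n_snps = n_snps, n_cpgs = n_cpgs, p_cis_qtl = p_cis_qtl,
                    cis_effect_r2 = cis_effect_r2, h2_additive_range = h2,
                    household_var_range = hh, ...)
  ped <- simulate_pedigree(cfg)
  geno <- simulate_genotypes(cfg, ped)
  sim <- simulate_methylation(geno, ped$kinship, ped$household, cfg)
  list(config = cfg, ped = ped, geno = geno, meth = sim$methylation,
       truth = sim$truth)
}

# dosage matrix wrapped as a genotype_matrix with a trivial map
as_genotypes <- function(D, chrom = "chr1", pos = NULL) {
  if (is.null(colnames(D))) colnames(D) <- sprintf("s%03d", seq_len(ncol(D)))
  if (is.null(rownames(D))) rownames(D) <- sprintf("i%04d", seq_len(nrow(D)))
  if (is.null(pos)) pos <- seq_len(ncol(D)) * 1000
  out <- list(dosage = D,
              map = data.frame(snp_id = colnames(D), chrom = chrom, pos = pos,
                               effect_allele = "A", other_allele = "G",
                               maf = pmin(colMeans(D) / 2, 1 - colMeans(D) / 2),
                               stringsAsFactors = FALSE))
  class(out) <- "genotype_matrix"
  out
}

# aligned IV table straight from numbers
iv_table <- function(gamma, Gamma, se_Gamma, se_gamma = 0.02, maf = 0.3,
                     snp_id = NULL) {
  if (is.null(snp_id)) snp_id <- paste0("iv", seq_along(gamma))
  data.frame(snp_id = snp_id, gamma = gamma, se_gamma = se_gamma,
             Gamma = Gamma, se_Gamma = se_Gamma, maf = maf,
             harmonization_action = "kept", kept = TRUE,
             stringsAsFactors = FALSE)
}

# sib pairs (sample-id matrix) of a pedigree
sib_pairs <- function(ped) {
  obs <- ped$pedigree[ped$pedigree$observed & ped$pedigree$role == "sib", ]
  do.call(rbind, lapply(split(obs$sample_id, obs$family_id), function(x) {
    if (length(x) >= 2) t(utils::combn(x, 2)) else NULL
  }))
}
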