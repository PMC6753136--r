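#' Simulation configuration for a synthetic family cohort
#'
#' Bundles every knob of the synthetic cohort generator: pedigree layout,
#' genotype LD structure, per-CpG variance decomposition, cis effects,
#' trans hotspots, colocalization regions and the outcome GWAS. Defaults
#' describe a mid-sized family cohort: per-CpG additive heritability
#' uniform on (0, 0.3) with mean 0.15 (whole-blood methylation heritability
#' is low on average, with a long upper tail), a modest shared-household
#' component, and cis-meQTL effects explaining 10% of latent variance.
#'
#' @param seed integer seed; every generator call is deterministic given it.
#' @param n_families number of families.
#' @param sibs_per_family integer range (min, max) of siblings per family.
#' @param n_unrelated number of singleton (unrelated) samples.
#' @param parents_observed if FALSE, families are sibships: parents are
#'   simulated for Mendelian transmission but dropped from all outputs.
#' @param n_snps,n_cpgs,n_genes marker/feature counts.
#' @param maf_range minor-allele-frequency range, within (0, 0.5).
#' @param adjacent_ld_r2 target squared correlation of adjacent SNPs.
#' @param chrom_layout data.frame(chrom, n_snps, span_bp); default splits
#'   \code{n_snps} over two 50 Mb chromosomes.
#' @param p_cis_qtl probability a CpG has cis causal SNP(s) within 1 Mb.
#' @param cis_effect_r2 latent variance fraction jointly explained by the
#'   causal SNP set (split equally across SNPs).
#' @param n_causal_per_cpg causal SNPs per cis-regulated CpG, chosen
#'   pairwise near-independent (r-squared < 0.05) within the window so a
#'   CpG can carry several independent instruments.
#' @param h2_additive_range,household_var_range uniform ranges for the
#'   per-CpG additive-genetic and shared-household variance fractions.
#' @param hotspot_spec data.frame(snp_index, n_targets, mediation_r2):
#'   each row plants a trans hotspot whose SNP drives a cis mediator gene
#'   (variance fraction \code{hotspot_gene_r2}) whose level in turn drives
#'   \code{n_targets} remote CpGs with variance fraction mediation_r2.
#' @param hotspot_gene_r2 SNP-to-mediator-gene variance fraction.
#' @param coloc_spec data.frame(cpg_index, gene_index, shared): shared
#'   pairs use one causal SNP for both traits; distinct pairs use two SNPs
#'   with pairwise r-squared below 0.05.
#' @param eqtm_spec data.frame(cpg_index, gene_index, r2): planted direct
#'   CpG-to-expression effects.
#' @param p_cis_eqtl,gene_cis_r2 probability and variance fraction of a
#'   gene's own cis-eQTL.
#' @param theta_causal true causal effect of designated CpGs on the outcome
#'   trait, per unit methylation.
#' @param pleiotropy_mean,pleiotropy_sd per-SNP direct (pleiotropic) effect
#'   on the outcome, drawn Normal(mean, sd).
#' @param gwas_n outcome GWAS sample size (drives outcome standard errors).
#' @param allele_swap_frac fraction of outcome GWAS rows emitted with
#'   effect/other alleles swapped, to exercise harmonization.
#' @param squash_scale latent-to-beta sigmoid scale; 0.35 keeps the squash
#'   close to linear (covariance attenuation below ~5%) while betas span a
#'   realistic (0.02, 0.98) range.
#' @return object of class \code{sim_config}.
#' @export
sim_config <- function(seed = 1L,
                       n_families = 100L,
                       sibs_per_family = c(2L, 4L),
                       n_unrelated = 100L,
                       parents_observed = TRUE,
                       n_snps = 500L,
                       n_cpgs = 100L,
                       n_genes = 20L,
                       maf_range = c(0.05, 0.45),
                       adjacent_ld_r2 = 0.3,
                       chrom_layout = NULL,
                       p_cis_qtl = 0.5,
                       cis_effect_r2 = 0.1,
                       n_causal_per_cpg = 1L,
                       h2_additive_range = c(0, 0.3),
                       household_var_range = c(0, 0.1),
                       hotspot_spec = NULL,
                       hotspot_gene_r2 = 0.5,
                       coloc_spec = NULL,
                       eqtm_spec = NULL,
                       p_cis_eqtl = 0.5,
                       gene_cis_r2 = 0.1,
                       theta_causal = 0,
                       pleiotropy_mean = 0,
                       pleiotropy_sd = 0,
                       gwas_n = 50000L,
                       allele_swap_frac = 0.2,
                       squash_scale = 0.35) {
  if (is.null(chrom_layout)) {
    n1 <- ceiling(n_snps / 2)
    chrom_layout <- data.frame(chrom = c("chr1", "chr2"),
                               n_snps = c(n1, n_snps - n1),
                               span_bp = c(5e7, 5e7),
                               stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(chrom_layout),
            all(c("chrom", "n_snps", "span_bp") %in% names(chrom_layout)))
  if (any(chrom_layout$span_bp <= 0)) stop("chrom_layout spans must be positive")
  if (sum(chrom_layout$n_snps) != n_snps) {
    n_snps <- sum(chrom_layout$n_snps)
  }
  if (maf_range[1] <= 0 || maf_range[2] >= 0.5 || maf_range[1] >= maf_range[2]) {
    stop("maf_range must be an increasing pair within (0, 0.5)")
  }
  if (adjacent_ld_r2 < 0 || adjacent_ld_r2 >= 1) stop("adjacent_ld_r2 must be in [0,1)")
  if (p_cis_qtl < 0 || p_cis_qtl > 1) stop("p_cis_qtl must be in [0,1]")
  if (max(h2_additive_range) + max(household_var_range) + cis_effect_r2 >= 1) {
    stop("h2 + household + cis effect fractions must stay below 1")
  }
  total_min <- n_families * (sibs_per_family[1] + if (parents_observed) 2L else 0L) +
    n_unrelated
  if (n_families < 0 || n_unrelated < 0 || total_min < 2) {
    stop("configuration error: at least 2 samples are required")
  }
  if (gwas_n < 10) stop("configuration error: gwas_n must be at least 10")
  cfg <- list(seed = as.integer(seed), n_families = as.integer(n_families),
              sibs_per_family = as.integer(sibs_per_family),
              n_unrelated = as.integer(n_unrelated),
              parents_observed = isTRUE(parents_observed),
              n_snps = as.integer(n_snps), n_cpgs = as.integer(n_cpgs),
              n_genes = as.integer(n_genes), maf_range = maf_range,
              adjacent_ld_r2 = adjacent_ld_r2, chrom_layout = chrom_layout,
              p_cis_qtl = p_cis_qtl, cis_effect_r2 = cis_effect_r2,
              n_causal_per_cpg = as.integer(n_causal_per_cpg),
              h2_additive_range = h2_additive_range,
              household_var_range = household_var_range,
              hotspot_spec = hotspot_spec, hotspot_gene_r2 = hotspot_gene_r2,
              coloc_spec = coloc_spec, eqtm_spec = eqtm_spec,
              p_cis_eqtl = p_cis_eqtl, gene_cis_r2 = gene_cis_r2,
              theta_causal = theta_causal, pleiotropy_mean = pleiotropy_mean,
              pleiotropy_sd = pleiotropy_sd, gwas_n = as.integer(gwas_n),
              allele_swap_frac = allele_swap_frac, squash_scale = squash_scale)
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  n_fam_members <- if (x$parents_observed) "parents + sibs" else "sibs only"
  cat("sim_config:", x$n_families, "families (", n_fam_members, "),",
      x$n_unrelated, "singletons;", x$n_snps, "SNPs,", x$n_cpgs, "CpGs,",
      x$n_genes, "genes; seed", x$seed, "\n")
  invisible(x)
}
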