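#!/usr/bin/env Rscript
# Stage 7: genomic-feature enrichment of meQTL CpGs (hypergeometric, fold
# gates 1.2 / 0.8, Bonferroni 0.05/10) and MAF-matched permutation
# enrichment of meQTL SNPs over synthetic chromatin-state intervals.

source("analysis/00_config.R")

co <- build_cohort()
scan <- two_step_scan(co)
cis_cpgs <- unique(scan$sig$records$cpg_id[scan$sig$records$class == "cis"])

ann <- list(island = co$meth$map$cpg_id[co$meth$map$island],
            promoter = co$meth$map$cpg_id[co$meth$map$promoter],
            enhancer = co$meth$map$cpg_id[co$meth$map$enhancer],
            body = co$meth$map$cpg_id[co$meth$map$body])
feat <- hypergeom_enrichment(cis_cpgs, co$meth$map$cpg_id, ann,
                             n_annotations = 10)
write_result_tsv(feat, file.path(RESULTS_DIR, "feature_enrichment.tsv"),
                 seed = STUDY_SEED)
print(feat[, c("annotation_id", "n_overlap", "fold", "p", "significant")])

# chromatin-state permutation: synthetic states tile 20% of each chromosome
set.seed(STUDY_SEED + 9L)
states <- list(
  active = data.frame(chrom = rep(c("chr1", "chr2"), each = 3),
                      start = rep(c(0, 1e7, 2e7), 2),
                      end = rep(c(2e6, 1.2e7, 2.2e7), 2)),
  quiescent = data.frame(chrom = rep(c("chr1", "chr2"), each = 2),
                         start = rep(c(5e6, 1.5e7), 2),
                         end = rep(c(7e6, 1.7e7), 2)))
maf <- realized_maf(co$geno)
snp_tab <- data.frame(snp_id = co$geno$map$snp_id, chrom = co$geno$map$chrom,
                      pos = co$geno$map$pos, maf = pmax(maf, 0.0101))
test_snps <- snp_tab[snp_tab$snp_id %in%
                       unique(scan$sig$records$snp_id), ]
pool <- snp_tab[!snp_tab$snp_id %in% test_snps$snp_id, ]
perm <- maf_matched_permutation(test_snps, pool, states, n_perm = 1000,
                                seed = STUDY_SEED)
write_result_tsv(perm, file.path(RESULTS_DIR, "state_enrichment.tsv"),
                 seed = STUDY_SEED)
print(perm[, c("annotation_id", "n_overlap", "fold", "p", "fdr",
               "significant")])
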