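#!/usr/bin/env Rscript
# Stage 5: Bayesian colocalization of the paired CpG-gene regions using
# per-SNP approximate Bayes factors and the primary priors
# (p1 = 2e-11, p2 = 1e-7, p12 = p1 * 10%).

source("analysis/00_config.R")

co <- build_cohort()
resid <- residualize_methylation(co$meth, NULL, co$ped$kinship)
pair_cpgs <- co$truth$cpg$cpg_id[co$cfg$coloc_spec$cpg_index]
sub <- resid[, pair_cpgs, drop = FALSE]
attr(sub, "cpg_map") <- co$meth$map[match(pair_cpgs, co$meth$map$cpg_id), ]
cis_full <- fast_linear_scan(sub, co$geno,
                             scan_config(prefilter_cis_p = 1,
                                         prefilter_trans_p = 1e-300))
eqtl <- eqtl_scan(scale(co$expr$expr, scale = FALSE), co$geno, co$expr$map)

rows <- lapply(seq_len(nrow(co$cfg$coloc_spec)), function(i) {
  cg <- co$truth$cpg$cpg_id[co$cfg$coloc_spec$cpg_index[i]]
  gn <- co$truth$gene$gene_id[co$cfg$coloc_spec$gene_index[i]]
  cc <- coloc_region(cg, gn, cis_full, eqtl)
  if (!inherits(cc, "coloc_result")) {
    cat(sprintf("%s-%s skipped (%s)\n", cg, gn, attr(cc, "skip_reason")))
    return(NULL)
  }
  data.frame(cpg_id = cg, gene_id = gn, truth_shared =
               co$cfg$coloc_spec$shared[i], n_snps = cc$n_snps,
             pp0 = cc$pp0, pp1 = cc$pp1, pp2 = cc$pp2, pp3 = cc$pp3,
             pp4 = cc$pp4, colocalized = call_colocalized(cc))
})
tab <- do.call(rbind, rows)
write_result_tsv(tab, file.path(RESULTS_DIR, "coloc.tsv"), seed = STUDY_SEED)
print(tab[, c("cpg_id", "gene_id", "truth_shared", "n_snps", "pp3", "pp4",
              "colocalized")])
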