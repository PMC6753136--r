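#!/usr/bin/env Rscript
# Stage 6: eQTM scan (CpG vs transcript) and trans-meQTL hotspot detection
# with cis-eGene linkage and eGene/target enrichment.

source("analysis/00_config.R")

co <- build_cohort()
scan <- two_step_scan(co)
expr_resid <- scale(co$expr$expr, scale = FALSE)

eq <- eqtm_scan(scan$resid, expr_resid, co$meth$map, co$expr$map)
write_result_tsv(eq[eq$significant, ],
                 file.path(RESULTS_DIR, "eqtm_significant.tsv"),
                 seed = STUDY_SEED)
cat(sprintf("eQTM scan: %d pairs, threshold %.3g, %d significant (%d cis)\n",
            attr(eq, "n_tests"), attr(eq, "threshold"),
            sum(eq$significant), sum(eq$significant & eq$cis_flag)))

trans <- scan$sig$records[scan$sig$records$class %in%
                            c("trans_intra", "trans_inter"), ]
hot <- detect_hotspots(trans, co$geno)
cat(sprintf("trans records: %d; hotspots detected: %d\n",
            nrow(trans), length(hot)))
if (length(hot) > 0) {
  eqtl <- eqtl_scan(expr_resid, co$geno, co$expr$map)
  eqtl_sig <- eqtl[eqtl$p < 0.05 / nrow(eqtl), ]
  tab <- do.call(rbind, lapply(hot, function(h) {
    eg <- link_hotspot_egenes(h, eqtl_sig, co$expr$map, co$geno)
    data.frame(hotspot_id = h$hotspot_id, index_snp = h$index_snp,
               n_members = length(h$member_snps), n_targets = h$n_targets,
               egenes = paste(eg, collapse = ";"))
  }))
  write_result_tsv(tab, file.path(RESULTS_DIR, "hotspots.tsv"),
                   seed = STUDY_SEED)
  print(tab)
  med <- co$truth$mediators[[1]]
  en <- egene_transcpg_enrichment(co$expr$expr[, med$gene_id, drop = FALSE],
                                  hot[[1]]$target_cpgs, scan$resid,
                                  co$meth$map)
  cat(sprintf("mediator eGene-target enrichment: fold %.2f, p %.3g\n",
              en$fold, en$p_hyper))
}
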