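#!/usr/bin/env Rscript
# Stage 1: generate the synthetic family cohort and export its inputs in
# the standard interchange formats (VCF with DS dosages, TSV matrices,
# BED annotations, truth table).

source("analysis/00_config.R")

co <- build_cohort()
out <- file.path(RESULTS_DIR, "cohort")
dir.create(out, showWarnings = FALSE)

write_genotypes_vcf(co$geno, file.path(out, "genotypes.vcf"))
write_result_tsv(data.frame(sample_id = rownames(co$meth$beta),
                            round(co$meth$beta, 6)),
                 file.path(out, "methylation_beta.tsv"), seed = STUDY_SEED)
write_result_tsv(data.frame(sample_id = rownames(co$expr$expr),
                            round(co$expr$expr, 6)),
                 file.path(out, "expression.tsv"), seed = STUDY_SEED)
write_result_tsv(co$ped$pedigree, file.path(out, "pedigree.tsv"),
                 seed = STUDY_SEED)
write_result_tsv(co$truth$cpg, file.path(out, "truth_cpg.tsv"),
                 seed = STUDY_SEED)
write_bed_points(data.frame(name = co$meth$map$cpg_id,
                            chrom = co$meth$map$chrom,
                            pos = co$meth$map$pos),
                 file.path(out, "cpg_positions.bed"))
write_bed_points(data.frame(name = co$expr$map$gene_id,
                            chrom = co$expr$map$chrom,
                            pos = co$expr$map$tss),
                 file.path(out, "gene_tss.bed"))

n_obs <- nrow(co$meth$beta)
cat(sprintf("cohort: %d observed samples (%d families + %d singletons)\n",
            n_obs, co$cfg$n_families, co$cfg$n_unrelated))
cat(sprintf("markers: %d SNPs, %d CpGs, %d genes; %d CpGs carry cis effects\n",
            ncol(co$geno$dosage), ncol(co$meth$beta), ncol(co$expr$expr),
            sum(!is.na(co$truth$cpg$causal_snp))))
cat("inputs written under", out, "\n")
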