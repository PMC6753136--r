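#' Run the full synthetic-cohort analysis pipeline
#'
#' Executes the stages in dependency order — simulate, heritability scan,
#' two-step meQTL scan, then Mendelian randomization, colocalization, eQTM
#' scan, hotspot detection and feature enrichment — on a synthetic cohort
#' drawn from \code{config}, writing one provenance-stamped TSV per stage
#' and returning every intermediate in memory. Stage toggles skip a stage's
#' outputs without disturbing the others (downstream stages that need a
#' skipped stage's inputs recompute them internally where possible).
#'
#' @param config a \code{\link{sim_config}}.
#' @param out_dir output directory (created if missing).
#' @param stages character subset of c("heritability", "meqtl", "mr",
#'   "coloc", "eqtm", "hotspots", "enrich").
#' @param scan a \code{\link{scan_config}}; NULL uses defaults with
#'   realized test counts.
#' @return named list of stage results (invisibly also written to
#'   \code{out_dir}).
#' @export
run_pipeline <- function(config, out_dir = tempfile("meqtlmr_run_"),
                         stages = c("heritability", "meqtl", "mr", "coloc",
                                    "eqtm", "hotspots", "enrich"),
                         scan = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ch <- config_hash(config)
  emit <- function(df, name) write_result_tsv(df, file.path(out_dir, name),
                                              seed = config$seed,
                                              config_hash = ch)
  res <- list(out_dir = out_dir)

  ped <- simulate_pedigree(config)
  geno <- simulate_genotypes(config, ped)
  sim <- simulate_methylation(geno, ped$kinship, ped$household, config)
  meth <- sim$methylation; truth <- sim$truth
  ex <- simulate_expression(geno, meth, config, truth)
  expr <- ex$expression; truth <- ex$truth
  res$pedigree <- ped; res$genotypes <- geno; res$methylation <- meth
  res$expression <- expr; res$truth <- truth
  emit(truth$cpg, "truth_cpg.tsv")
  emit(geno$map, "snp_map.tsv")

  if ("heritability" %in% stages) {
    hs <- heritability_scan(meth, NULL, ped$kinship, ped$household)
    res$heritability <- hs
    emit(hs$table, "heritability.tsv")
  }

  if (is.null(scan)) scan <- scan_config()
  resid <- residualize_methylation(meth, NULL, ped$kinship)
  res$residuals <- resid
  pre <- fast_linear_scan(resid, geno, scan)
  nbc <- attr(pre, "n_tests_by_class")
  fin <- lme_refit(pre, meth, geno, NULL, ped$kinship)
  sig <- apply_significance(fin, scan,
                            n_cis_tests = max(1, nbc[["cis"]]),
                            n_trans_tests = max(1, nbc[["trans_intra"]] +
                                                  nbc[["trans_inter"]]))
  res$meqtl <- list(prefilter = pre, final = fin, significant = sig$records,
                    cis_threshold = sig$cis_threshold,
                    trans_threshold = sig$trans_threshold)
  if ("meqtl" %in% stages) emit(fin, "meqtl_final.tsv")

  cis_sig <- sig$records[sig$records$class == "cis", , drop = FALSE]
  trans_sig <- sig$records[sig$records$class %in%
                             c("trans_intra", "trans_inter"), , drop = FALSE]

  if ("mr" %in% stages && nrow(cis_sig) > 0) {
    expo_all <- exposure_table(cis_sig, geno)
    outcome <- simulate_outcome_gwas(truth, cis_sig, config)
    mr_rows <- list()
    for (cg in unique(cis_sig$cpg_id)) {
      rec <- cis_sig[cis_sig$cpg_id == cg, , drop = FALSE]
      ivs <- select_ivs(rec, geno)
      if (attr(ivs, "insufficient")) next
      expo <- expo_all[expo_all$cpg_id == cg &
                         expo_all$snp_id %in% ivs, , drop = FALSE]
      aligned <- harmonize(expo, outcome)
      r <- stepwise_iv_refinement(aligned, binary_outcome = FALSE)
      mr_rows[[cg]] <- data.frame(exposure_id = cg, theta = r$theta,
                                  se = r$se_theta, p_mr = r$p_mr,
                                  q = r$q_stat, p_heter = r$p_heter,
                                  egger_intercept = r$egger_intercept,
                                  p_pleio = r$p_pleio,
                                  n_iv_initial = r$n_iv_initial,
                                  n_iv_final = r$n_iv_final,
                                  status = r$status,
                                  excluded_ivs = paste(r$excluded_ivs,
                                                       collapse = ";"),
                                  stringsAsFactors = FALSE)
    }
    if (length(mr_rows) > 0) {
      mr_tab <- do.call(rbind, mr_rows)
      res$mr <- mr_tab
      emit(mr_tab, "mr_results.tsv")
    }
  }

  expr_resid <- scale(expr$expr, scale = FALSE)
  eqtl <- eqtl_scan(expr_resid, geno, expr$map)
  res$eqtl <- eqtl

  if ("coloc" %in% stages && !is.null(config$coloc_spec) &&
      nrow(config$coloc_spec) > 0) {
    # full (unfiltered) cis statistics for the paired CpGs: eligibility
    # gates the region, but all regional SNPs enter the posterior sums
    pair_cpgs <- truth$cpg$cpg_id[config$coloc_spec$cpg_index]
    sub <- resid[, pair_cpgs, drop = FALSE]
    attr(sub, "cpg_map") <- meth$map[match(pair_cpgs, meth$map$cpg_id), ]
    cis_full <- fast_linear_scan(sub, geno,
                                 scan_config(prefilter_cis_p = 1,
                                             prefilter_trans_p = 1e-300))
    cl_rows <- list()
    for (i in seq_len(nrow(config$coloc_spec))) {
      cg <- truth$cpg$cpg_id[config$coloc_spec$cpg_index[i]]
      gn <- truth$gene$gene_id[config$coloc_spec$gene_index[i]]
      cc <- coloc_region(cg, gn, cis_full, eqtl)
      if (!inherits(cc, "coloc_result")) next
      cl_rows[[length(cl_rows) + 1L]] <-
        data.frame(cpg_id = cg, gene_id = gn, n_snps = cc$n_snps,
                   pp0 = cc$pp0, pp1 = cc$pp1, pp2 = cc$pp2, pp3 = cc$pp3,
                   pp4 = cc$pp4, colocalized = cc$colocalized,
                   stringsAsFactors = FALSE)
    }
    if (length(cl_rows) > 0) {
      cl_tab <- do.call(rbind, cl_rows)
      res$coloc <- cl_tab
      emit(cl_tab, "coloc.tsv")
    }
  }

  if ("eqtm" %in% stages) {
    eq <- eqtm_scan(resid, expr_resid, meth$map,
                    stats::setNames(expr$map, c("gene_id", "chrom", "tss")))
    res$eqtm <- eq
    emit(eq[eq$significant, , drop = FALSE], "eqtm_significant.tsv")
  }

  if ("hotspots" %in% stages) {
    hot <- detect_hotspots(trans_sig, geno)
    res$hotspots <- hot
    if (length(hot) > 0) {
      eqtl_sig <- eqtl[eqtl$p < 0.05 / max(1, nrow(eqtl)), , drop = FALSE]
      hot_tab <- do.call(rbind, lapply(hot, function(h) {
        eg <- link_hotspot_egenes(h, eqtl_sig,
                                  stats::setNames(expr$map,
                                                  c("gene_id", "chrom", "tss")),
                                  geno)
        data.frame(hotspot_id = h$hotspot_id, index_snp = h$index_snp,
                   n_members = length(h$member_snps),
                   n_targets = h$n_targets,
                   egenes = paste(eg, collapse = ";"),
                   stringsAsFactors = FALSE)
      }))
      emit(hot_tab, "hotspots.tsv")
      res$hotspot_table <- hot_tab
    }
  }

  if ("enrich" %in% stages && nrow(cis_sig) > 0) {
    fg <- unique(cis_sig$cpg_id)
    ann <- list(island = meth$map$cpg_id[meth$map$island],
                promoter = meth$map$cpg_id[meth$map$promoter],
                enhancer = meth$map$cpg_id[meth$map$enhancer],
                body = meth$map$cpg_id[meth$map$body])
    en <- hypergeom_enrichment(fg, meth$map$cpg_id, ann, n_annotations = 10)
    res$enrichment <- en
    emit(en, "enrichment.tsv")
  }

  invisible(res)
}
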