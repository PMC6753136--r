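#' Write a results table as TSV with a provenance header
#'
#' Tab-delimited, one header line, '.' for missing values, preceded by
#' comment lines carrying the package version, seed and a config hash.
#'
#' @param df data.frame.
#' @param path output path.
#' @param seed seed recorded in the header.
#' @param config_hash hash string recorded in the header.
#' @export
write_result_tsv <- function(df, path, seed = NA, config_hash = "") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# meqtlmr %s | seed=%s | config=%s",
                     as.character(utils::packageVersion("meqtlmr")),
                     seed, config_hash), con)
  df2 <- df
  for (j in seq_along(df2)) df2[[j]][is.na(df2[[j]])] <- "."
  utils::write.table(df2, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by \code{\link{write_result_tsv}}
#' @param path file path.
#' @return data.frame.
#' @export
read_result_tsv <- function(path) {
  utils::read.delim(path, comment.char = "#", na.strings = ".",
                    stringsAsFactors = FALSE)
}

# FNV-1a style hash of a config's deparsed form, for output headers.
config_hash <- function(config) {
  txt <- paste(deparse(config[!vapply(config, is.function, logical(1))]),
               collapse = "")
  h <- 7
  for (v in utf8ToInt(txt)) h <- (h * 31 + v) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Write genotype dosages as VCF 4.2 with a DS FORMAT field
#'
#' @param genotypes a \code{genotype_matrix}.
#' @param path output .vcf path.
#' @export
write_genotypes_vcf <- function(genotypes, path) {
  dos <- genotypes$dosage
  map <- genotypes$map
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Estimated alternate allele dosage\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", rownames(dos)), collapse = "\t")), con)
  for (k in seq_len(nrow(map))) {
    writeLines(paste(c(map$chrom[k], map$pos[k], map$snp_id[k],
                       map$other_allele[k], map$effect_allele[k], ".", "PASS",
                       ".", "DS", format(dos[, k], trim = TRUE)),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Read genotype dosages from VCF (FORMAT DS) or a TSV matrix
#'
#' VCF input must carry a DS FORMAT field (the ALT allele is the effect
#' allele); TSV input is a sample x SNP matrix with a header row of SNP ids
#' and a sidecar map TSV (snp_id, chrom, pos, effect_allele, other_allele).
#' SNPs below \code{maf_min} are dropped (count in the \code{n_maf_dropped}
#' attribute).
#'
#' @param path .vcf or .tsv path.
#' @param maf_min minor-allele-frequency filter.
#' @param map_path sidecar map path for TSV input.
#' @return a \code{genotype_matrix}.
#' @export
read_genotypes <- function(path, maf_min = 0.01, map_path = NULL) {
  if (grepl("\\.vcf(\\.gz)?$", path)) {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fmt <- v@gt[, "FORMAT"]
    if (!all(grepl("DS", fmt))) stop("format error: VCF lacks the DS FORMAT field")
    ds <- vcfR::extract.gt(v, element = "DS", as.numeric = TRUE)
    dos <- t(ds)
    fx <- v@fix
    map <- data.frame(snp_id = fx[, "ID"], chrom = fx[, "CHROM"],
                      pos = as.integer(fx[, "POS"]),
                      effect_allele = fx[, "ALT"], other_allele = fx[, "REF"],
                      stringsAsFactors = FALSE)
  } else {
    dos <- as.matrix(utils::read.delim(path, row.names = 1, check.names = FALSE))
    if (is.null(map_path)) stop("format error: TSV genotypes need a sidecar map")
    map <- utils::read.delim(map_path, stringsAsFactors = FALSE)
    map <- map[match(colnames(dos), map$snp_id), ]
  }
  if (any(dos < 0 | dos > 2, na.rm = TRUE)) {
    stop("parse error: dosages outside [0, 2]")
  }
  af <- colMeans(dos) / 2
  maf <- pmin(af, 1 - af)
  keep <- maf >= maf_min
  out <- list(dosage = dos[, keep, drop = FALSE],
              map = cbind(map[keep, , drop = FALSE],
                          maf = maf[keep])[, union(names(map), "maf")])
  rownames(out$map) <- NULL
  class(out) <- "genotype_matrix"
  attr(out, "n_maf_dropped") <- sum(!keep)
  out
}

#' Convert BED intervals (0-based half-open) to 1-based point annotations
#'
#' CpG and TSS annotations arrive as single-base BED features; internal
#' coordinates are 1-based inclusive points, so pos = start + 1.
#'
#' @param path BED path (chrom, start, end, name ...).
#' @return data.frame: name, chrom, pos.
#' @export
read_bed_points <- function(path) {
  bed <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  names(bed)[1:3] <- c("chrom", "start", "end")
  nm <- if (ncol(bed) >= 4) bed[[4]] else sprintf("feat%d", seq_len(nrow(bed)))
  data.frame(name = nm, chrom = bed$chrom, pos = bed$start + 1L,
             stringsAsFactors = FALSE)
}

#' Write 1-based points as single-base BED intervals
#' @param df data.frame with name, chrom, pos (1-based).
#' @param path output path.
#' @export
write_bed_points <- function(df, path) {
  utils::write.table(data.frame(df$chrom, df$pos - 1L, df$pos, df$name),
                     path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Cis-eQTL scan of expression residuals against SNP dosages
#'
#' Simple regression of each gene on every SNP within the cis window of
#' its TSS; all window SNPs are returned (filtering is left to callers
#' such as the colocalization region builder, which gates on p < 1e-4).
#'
#' @param expr_resid samples x genes residual matrix.
#' @param genotypes a \code{genotype_matrix}.
#' @param tss_map data.frame: gene_id, chrom, tss.
#' @param cis_window_bp window around the TSS (1 Mb).
#' @return data.frame: snp_id, gene_id, pos_snp, beta, se, t, p.
#' @export
eqtl_scan <- function(expr_resid, genotypes, tss_map, cis_window_bp = 1e6) {
  E <- as.matrix(expr_resid)
  n <- nrow(E)
  G <- genotypes$dosage
  smap <- genotypes$map
  rows <- list()
  for (j in seq_len(ncol(E))) {
    g_ok <- smap$chrom == tss_map$chrom[j] &
      abs(smap$pos - tss_map$tss[j]) <= cis_window_bp
    idx <- which(g_ok)
    if (length(idx) == 0) next
    y <- E[, j] - mean(E[, j])
    sy <- sqrt(sum(y^2))
    if (sy == 0) next
    Gc <- scale(G[, idx, drop = FALSE], scale = FALSE)
    sg <- sqrt(colSums(Gc^2))
    ok <- sg > 0
    if (!any(ok)) next
    r <- drop(crossprod(Gc[, ok, drop = FALSE], y)) / (sg[ok] * sy)
    r <- pmin(pmax(r, -1 + 1e-12), 1 - 1e-12)
    df <- n - 2L
    tv <- r * sqrt(df / (1 - r^2))
    beta <- r * sy / sg[ok]
    rows[[length(rows) + 1L]] <- data.frame(
      snp_id = smap$snp_id[idx[ok]], gene_id = tss_map$gene_id[j],
      pos_snp = smap$pos[idx[ok]], beta = beta, se = beta / tv, t = tv,
      p = 2 * stats::pt(-abs(tv), df = df), stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) {
    return(data.frame(snp_id = character(0), gene_id = character(0),
                      pos_snp = numeric(0), beta = numeric(0),
                      se = numeric(0), t = numeric(0), p = numeric(0)))
  }
  do.call(rbind, rows)
}

#' Build an exposure summary table for MR from association records
#'
#' Joins effect/other alleles and realized MAF from the genotype map onto
#' the per-SNP exposure effects.
#'
#' @param records association records (snp_id, beta, se, p).
#' @param genotypes a \code{genotype_matrix}.
#' @return data.frame ready for \code{\link{harmonize}}.
#' @export
exposure_table <- function(records, genotypes) {
  i <- match(records$snp_id, genotypes$map$snp_id)
  maf <- realized_maf(genotypes)[i]
  data.frame(snp_id = records$snp_id,
             cpg_id = if ("cpg_id" %in% names(records)) records$cpg_id else NA,
             effect_allele = genotypes$map$effect_allele[i],
             other_allele = genotypes$map$other_allele[i],
             beta = records$beta, se = records$se, p = records$p, maf = maf,
             stringsAsFactors = FALSE)
}
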