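#' Simulate LD-structured genotype dosages down a pedigree
#'
#' Founder haplotypes follow a first-order Markov chain along each
#' chromosome: adjacent alleles are drawn with correlation
#' \code{sqrt(adjacent_ld_r2)} (truncated at the Frechet feasibility bound
#' implied by the two allele frequencies), so adjacent-SNP squared dosage
#' correlation matches \code{adjacent_ld_r2} and long-range LD decays
#' geometrically. Allele frequencies follow a reflected random walk inside
#' \code{maf_range}, keeping neighbouring frequencies similar (as in real
#' data) and the LD target feasible. Offspring receive parental haplotypes
#' by Mendelian transmission with Haldane recombination at 1 cM/Mb.
#'
#' @param config a \code{\link{sim_config}}.
#' @param pedigree result of \code{\link{simulate_pedigree}}.
#' @return object of class \code{genotype_matrix}: list with \code{dosage}
#'   (observed samples x SNPs, values 0/1/2 counting the effect allele) and
#'   \code{map} (snp_id, chrom, pos, effect_allele, other_allele, maf).
#' @export
simulate_genotypes <- function(config, pedigree) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  ped <- pedigree$pedigree
  founders <- ped$sample_id[is.na(ped$father_id)]
  children <- ped$sample_id[!is.na(ped$father_id)]

  layout <- config$chrom_layout
  map <- do.call(rbind, lapply(seq_len(nrow(layout)), function(i) {
    s <- layout$n_snps[i]
    data.frame(chrom = layout$chrom[i],
               pos = sort(sample.int(layout$span_bp[i], s)),
               stringsAsFactors = FALSE)
  }))
  map$snp_id <- sprintf("rs%06d", seq_len(nrow(map)))
  # reflected random walk of minor-allele frequencies within maf_range
  lo <- config$maf_range[1]; hi <- config$maf_range[2]
  if (hi - lo < 1e-6) stop("configuration error: degenerate maf_range")
  p <- numeric(nrow(map))
  for (i in seq_len(nrow(map))) {
    if (i == 1 || map$chrom[i] != map$chrom[i - 1]) {
      p[i] <- stats::runif(1, lo, hi)
    } else {
      step <- p[i - 1] + stats::rnorm(1, 0, 0.02)
      while (step < lo || step > hi) {
        if (step < lo) step <- 2 * lo - step
        if (step > hi) step <- 2 * hi - step
      }
      p[i] <- step
    }
  }
  map$maf <- p
  bases <- c("A", "C", "G", "T")
  map$effect_allele <- sample(bases, nrow(map), replace = TRUE)
  map$other_allele <- vapply(map$effect_allele, function(a) {
    sample(setdiff(bases, a), 1L)
  }, character(1))
  map <- map[, c("snp_id", "chrom", "pos", "effect_allele", "other_allele", "maf")]

  n_hap <- 2L * length(founders)
  r_target <- sqrt(config$adjacent_ld_r2)
  Hmat <- matrix(0L, n_hap, nrow(map))
  for (i in seq_len(nrow(map))) {
    if (i == 1 || map$chrom[i] != map$chrom[i - 1]) {
      Hmat[, i] <- stats::rbinom(n_hap, 1L, p[i])
    } else {
      pk <- p[i - 1]; qk <- p[i]
      rmax <- min(sqrt(pk * (1 - qk) / (qk * (1 - pk))),
                  sqrt(qk * (1 - pk) / (pk * (1 - qk))))
      r <- min(r_target, 0.999 * rmax)
      p11 <- pk * qk + r * sqrt(pk * (1 - pk) * qk * (1 - qk))
      pr <- ifelse(Hmat[, i - 1] == 1L, p11 / pk, (qk - p11) / (1 - pk))
      Hmat[, i] <- stats::rbinom(n_hap, 1L, pmin(pmax(pr, 0), 1))
    }
  }
  hap_of <- stats::setNames(seq_along(founders) * 2L - 1L, founders)

  # per-chromosome recombination probabilities between adjacent SNPs
  chroms <- unique(map$chrom)
  chrom_idx <- lapply(chroms, function(cc) which(map$chrom == cc))
  names(chrom_idx) <- chroms
  rec_prob <- lapply(chrom_idx, function(idx) {
    d <- diff(map$pos[idx])
    0.5 * (1 - exp(-2 * d * 1e-8))
  })

  gamete <- function(h1, h2) {
    out <- integer(nrow(map))
    for (cc in chroms) {
      idx <- chrom_idx[[cc]]
      cross <- stats::rbinom(length(idx) - 1L, 1L, rec_prob[[cc]])
      phase <- (cumsum(c(stats::rbinom(1L, 1L, 0.5), cross))) %% 2L
      out[idx] <- ifelse(phase == 0L, h1[idx], h2[idx])
    }
    out
  }

  all_ids <- ped$sample_id
  haps <- matrix(0L, 2L * length(all_ids), nrow(map))
  row_of <- stats::setNames(seq_along(all_ids) * 2L - 1L, all_ids)
  for (id in founders) {
    haps[row_of[id], ] <- Hmat[hap_of[id], ]
    haps[row_of[id] + 1L, ] <- Hmat[hap_of[id] + 1L, ]
  }
  for (id in children) {
    k <- which(ped$sample_id == id)
    fa <- ped$father_id[k]; mo <- ped$mother_id[k]
    haps[row_of[id], ] <- gamete(haps[row_of[fa], ], haps[row_of[fa] + 1L, ])
    haps[row_of[id] + 1L, ] <- gamete(haps[row_of[mo], ], haps[row_of[mo] + 1L, ])
  }
  dos <- haps[seq(1, nrow(haps), 2), , drop = FALSE] +
    haps[seq(2, nrow(haps), 2), , drop = FALSE]
  rownames(dos) <- all_ids
  colnames(dos) <- map$snp_id
  obs_ids <- ped$sample_id[ped$observed]
  out <- list(dosage = dos[obs_ids, , drop = FALSE], map = map,
              parent_dosage = if (config$parents_observed) NULL else
                dos[setdiff(all_ids, obs_ids), , drop = FALSE])
  class(out) <- "genotype_matrix"
  out
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$dosage), "samples x", ncol(x$dosage),
      "SNPs on", length(unique(x$map$chrom)), "chromosome(s)\n")
  invisible(x)
}

#' Realized minor allele frequencies of a genotype matrix
#' @param genotypes a \code{genotype_matrix}.
#' @return named numeric vector of per-SNP minor allele frequencies.
#' @export
realized_maf <- function(genotypes) {
  af <- colMeans(genotypes$dosage) / 2
  pmin(af, 1 - af)
}
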