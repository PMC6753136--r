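#' Wakefield log approximate Bayes factor for one association
#'
#' With V = se^2, z = beta/se and r = prior_sd^2 / (prior_sd^2 + V), the
#' log ABF is 0.5 log(1 - r) + 0.5 z^2 r — the exact Bayes factor of a
#' Gaussian effect prior N(0, prior_sd^2) against the point null given the
#' Gaussian estimate. Vectorized over beta and se.
#'
#' @param beta,se effect estimate and standard error (se > 0).
#' @param prior_sd prior standard deviation of the true effect (0.15 is
#'   the conventional default for quantitative traits).
#' @return log approximate Bayes factor(s).
#' @export
wakefield_labf <- function(beta, se, prior_sd = 0.15) {
  if (any(se <= 0)) stop("input error: standard errors must be positive")
  if (prior_sd < 0) stop("input error: prior_sd must be non-negative")
  V <- se^2
  r <- prior_sd^2 / (prior_sd^2 + V)
  z <- beta / se
  0.5 * log1p(-r) + 0.5 * z^2 * r
}

#' Default colocalization priors
#'
#' p1 = 2e-11 (SNP associated with methylation only), p2 = 1e-7
#' (expression only), p12 = p1 * 10% (both). The alternative preset
#' \code{"conventional"} uses p1 = p2 = 1e-4 and p12 = 1e-5.
#'
#' @param preset "primary" or "conventional".
#' @return named list(p1, p2, p12).
#' @export
coloc_priors <- function(preset = c("primary", "conventional")) {
  preset <- match.arg(preset)
  if (preset == "primary") list(p1 = 2e-11, p2 = 1e-7, p12 = 2e-12)
  else list(p1 = 1e-4, p2 = 1e-4, p12 = 1e-5)
}

#' Posterior probabilities of the five colocalization hypotheses
#'
#' Computes PP0..PP4 for: no causal variant; causal for trait 1 only;
#' trait 2 only; two distinct causal variants; one shared causal variant.
#' Sums over per-SNP Bayes factors are accumulated with log-sum-exp; the
#' two-distinct-variant sum excludes same-SNP configurations and is
#' clamped at zero if floating error drives it negative.
#'
#' @param labf1,labf2 per-SNP log ABFs for trait 1 (methylation) and
#'   trait 2 (expression), same SNPs in the same order.
#' @param p1,p2,p12 prior probabilities (defaults = \code{coloc_priors()}).
#' @return object of class \code{coloc_result}: pp0..pp4, n_snps,
#'   colocalized flag (pp4 >= 0.8).
#' @export
coloc_posterior <- function(labf1, labf2, p1 = NULL, p2 = NULL, p12 = NULL) {
  if (length(labf1) != length(labf2)) {
    stop("input error: labf vectors must have equal length")
  }
  pri <- coloc_priors()
  if (is.null(p1)) p1 <- pri$p1
  if (is.null(p2)) p2 <- pri$p2
  if (is.null(p12)) p12 <- pri$p12
  lse <- function(x) { m <- max(x); m + log(sum(exp(x - m))) }
  l1 <- lse(labf1)                      # log sum exp(labf1)
  l2 <- lse(labf2)
  l12 <- lse(labf1 + labf2)
  # log-scale unnormalized sums
  s0 <- 0
  s1 <- log(p1) + l1
  s2 <- log(p2) + l2
  s4 <- log(p12) + l12
  # S3 = p1 p2 (sum_i e^a_i sum_j e^b_j - sum_i e^(a_i+b_i))
  if (length(labf1) > 1) {
    m <- max(l1 + l2, l12)
    diff <- exp(l1 + l2 - m) - exp(l12 - m)
    if (diff < 0) diff <- 0 # floating error clamp
    s3 <- if (diff > 0) log(p1) + log(p2) + m + log(diff) else -Inf
  } else {
    s3 <- -Inf
  }
  ls <- c(s0, s1, s2, s3, s4)
  mx <- max(ls)
  pp <- exp(ls - mx) / sum(exp(ls - mx))
  structure(list(pp0 = pp[1], pp1 = pp[2], pp2 = pp[3], pp3 = pp[4],
                 pp4 = pp[5], n_snps = length(labf1),
                 colocalized = pp[5] >= 0.8), class = "coloc_result")
}

#' @export
print.coloc_result <- function(x, ...) {
  cat(sprintf("coloc_result (%d SNPs): PP0=%.3f PP1=%.3f PP2=%.3f PP3=%.3f PP4=%.3f %s\n",
              x$n_snps, x$pp0, x$pp1, x$pp2, x$pp3, x$pp4,
              if (x$colocalized) "[colocalized]" else ""))
  invisible(x)
}

#' Assemble per-SNP region statistics for one CpG-gene pair
#'
#' Intersects the meQTL and eQTL association records within a window
#' around the CpG; the region is eligible only if the methylation side has
#' at least one SNP at p < 1e-6 and the expression side at least one at
#' p < 1e-4 (filters gate region admission; all intersected SNPs enter the
#' posterior sums unless \code{filter_snps} is set).
#'
#' @param cpg_id,gene_id identifiers.
#' @param meqtl_records SNP-CpG association records (snp_id, cpg_id, p,
#'   beta, se, pos_snp).
#' @param eqtl_records SNP-gene association records (snp_id, gene_id, p,
#'   beta, se).
#' @param window_bp region width centred on the CpG (2 Mb total: +/- 1 Mb).
#' @param dnam_p,expr_p eligibility filters.
#' @param filter_snps if TRUE, only filter-passing SNPs enter the region.
#' @return region data.frame (snp_id, beta1, se1, p1, beta2, se2, p2);
#'   ineligible regions come back with zero rows and attribute
#'   \code{skip_reason}.
#' @export
build_region <- function(cpg_id, gene_id, meqtl_records, eqtl_records,
                         window_bp = 2e6, dnam_p = 1e-6, expr_p = 1e-4,
                         filter_snps = FALSE) {
  m <- meqtl_records[meqtl_records$cpg_id == cpg_id, , drop = FALSE]
  e <- eqtl_records[eqtl_records$gene_id == gene_id, , drop = FALSE]
  if ("pos_cpg" %in% names(m) && "pos_snp" %in% names(m) && nrow(m) > 0) {
    m <- m[abs(m$pos_snp - m$pos_cpg) <= window_bp / 2, , drop = FALSE]
  }
  common <- intersect(m$snp_id, e$snp_id)
  skip <- function(reason) {
    out <- data.frame(snp_id = character(0), beta1 = numeric(0),
                      se1 = numeric(0), p1 = numeric(0), beta2 = numeric(0),
                      se2 = numeric(0), p2 = numeric(0))
    attr(out, "skip_reason") <- reason
    out
  }
  if (length(common) == 0) return(skip("empty_intersection"))
  m <- m[match(common, m$snp_id), ]
  e <- e[match(common, e$snp_id), ]
  if (!any(m$p < dnam_p)) return(skip("dnam_filter"))
  if (!any(e$p < expr_p)) return(skip("expr_filter"))
  if (filter_snps) {
    keep <- m$p < dnam_p | e$p < expr_p
    m <- m[keep, , drop = FALSE]; e <- e[keep, , drop = FALSE]
  }
  data.frame(snp_id = m$snp_id, beta1 = m$beta, se1 = m$se, p1 = m$p,
             beta2 = e$beta, se2 = e$se, p2 = e$p, stringsAsFactors = FALSE)
}

#' Colocalization call from posterior probabilities
#'
#' TRUE iff PP4 (one shared causal variant) is at least 0.80, the
#' inclusive boundary used for reporting colocalized CpG-mRNA pairs.
#'
#' @param result a \code{coloc_result}.
#' @return logical flag.
#' @export
call_colocalized <- function(result) {
  stopifnot(inherits(result, "coloc_result"))
  result$pp4 >= 0.80
}

#' Run colocalization for one CpG-gene region
#'
#' Convenience wrapper: builds the region, computes Wakefield log ABFs on
#' both sides and returns the posterior.
#'
#' @inheritParams build_region
#' @param prior_sd effect-size prior sd for both traits.
#' @param priors list(p1, p2, p12).
#' @return \code{coloc_result}, or an empty list with attribute
#'   \code{skip_reason} if the region is ineligible.
#' @export
coloc_region <- function(cpg_id, gene_id, meqtl_records, eqtl_records,
                         window_bp = 2e6, prior_sd = 0.15,
                         priors = coloc_priors()) {
  reg <- build_region(cpg_id, gene_id, meqtl_records, eqtl_records, window_bp)
  if (nrow(reg) == 0) {
    return(structure(list(), skip_reason = attr(reg, "skip_reason")))
  }
  coloc_posterior(wakefield_labf(reg$beta1, reg$se1, prior_sd),
                  wakefield_labf(reg$beta2, reg$se2, prior_sd),
                  priors$p1, priors$p2, priors$p12)
}
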