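#' @keywords internal
#' Precompute the solvable structure of a set of covariance matrices.
#' One random component is handled by eigen-rotation (all later algebra is
#' diagonal); several components are decomposed into independent blocks
#' found from the joint sparsity pattern (families), falling back to one
#' dense block when the matrices are dense (e.g. a GRM).
vc_structure <- function(vcov_list) {
  m <- length(vcov_list)
  if (is.null(names(vcov_list)) || any(names(vcov_list) == "")) {
    names(vcov_list) <- paste0("V", seq_len(m))
  }
  n <- nrow(vcov_list[[1]])
  for (V in vcov_list) {
    if (!isSymmetric(unname(V), tol = 1e-8)) stop("matrix error: vcov not symmetric")
  }
  if (m == 1L) {
    E <- eigen((vcov_list[[1]] + t(vcov_list[[1]])) / 2, symmetric = TRUE)
    return(structure(list(mode = "rotation", U = E$vectors,
                          d = pmax(E$values, 0), n = n,
                          names = names(vcov_list)), class = "vc_structure"))
  }
  A <- Reduce(`+`, lapply(vcov_list, abs))
  nz <- A > 1e-12
  if (mean(nz) > 0.25) {
    blocks <- list(seq_len(n))
  } else {
    parent <- seq_len(n)
    find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
    ij <- which(nz & upper.tri(nz), arr.ind = TRUE)
    for (r in seq_len(nrow(ij))) {
      a <- find(ij[r, 1]); b <- find(ij[r, 2])
      if (a != b) parent[b] <- a
    }
    roots <- vapply(seq_len(n), find, integer(1))
    blocks <- split(seq_len(n), roots)
  }
  blocks <- lapply(blocks, function(idx) {
    list(idx = idx,
         V = lapply(vcov_list, function(V) V[idx, idx, drop = FALSE]))
  })
  structure(list(mode = "blocks", blocks = blocks, n = n,
                 names = names(vcov_list)), class = "vc_structure")
}

# Gram matrix of the covariance basis (components + identity); a rank
# deficiency means the variance split is unidentifiable.
vc_identifiable <- function(struct) {
  if (struct$mode == "rotation") {
    basis <- cbind(struct$d, 1)
    G <- crossprod(basis)
  } else {
    m <- length(struct$names)
    G <- matrix(0, m + 1L, m + 1L)
    for (b in struct$blocks) {
      mats <- c(b$V, list(diag(1, length(b$idx))))
      for (i in seq_len(m + 1L)) {
        for (j in i:(m + 1L)) {
          G[i, j] <- G[i, j] + sum(mats[[i]] * mats[[j]])
        }
      }
    }
    G <- G + t(G) - diag(diag(G))
  }
  ev <- eigen(G, symmetric = TRUE, only.values = TRUE)$values
  ev[length(ev)] / ev[1] > 1e-10
}

#' REML variance-component decomposition of a methylation trait
#'
#' Fits y ~ N(Xb, sigma2_A * K + sigma2_h * H + sigma2_e * I) by restricted
#' maximum likelihood: 20 expectation-maximization warm-start iterations
#' followed by average-information updates with step-halving, all variance
#' components constrained non-negative (proposals below zero are clamped to
#' a small floor and flagged "boundary"). Heritability is the additive
#' fraction sigma2_A / (sigma2_A + sigma2_h + sigma2_e) and the household
#' effect the analogous sigma2_h fraction. Degenerate inputs in which the
#' covariance basis is rank-deficient (e.g. K = I with H absent) are
#' detected up front and returned flagged "unidentifiable" rather than
#' fitted to an arbitrary split.
#'
#' @param y numeric response (methylation beta values of one CpG).
#' @param X fixed-covariate matrix (intercept added if absent); NULL means
#'   intercept only.
#' @param vcov_list named list of PSD covariance matrices, e.g.
#'   \code{list(A = kinship, H = household)}; the residual identity
#'   component is implicit.
#' @param max_iter,tol iteration cap and convergence tolerance (max
#'   absolute component change on the variance-standardized scale; the fit
#'   also stops when the relative restricted log-likelihood change drops
#'   below 1e-8).
#' @param structure optional precomputed \code{vc_structure}; pass it when
#'   fitting many traits against the same matrices.
#' @return object of class \code{vc_fit}: sigma2 (named, last element
#'   "residual"), h2, household_effect, converged, n_iter, loglik, boundary,
#'   note, beta.
#' @export
fit_variance_components <- function(y, X = NULL, vcov_list, max_iter = 200L,
                                    tol = 1e-6, structure = NULL) {
  n <- length(y)
  if (is.null(X)) X <- matrix(1, n, 1, dimnames = list(NULL, "intercept"))
  X <- as.matrix(X)
  if (!any(apply(X, 2, function(col) all(col == col[1]) && col[1] != 0))) {
    X <- cbind(intercept = 1, X)
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) stop("rank error: singular covariate matrix")
  if (n <= qrX$rank + 2) stop("rank error: too few samples for the model")
  if (is.null(structure)) structure <- vc_structure(vcov_list)
  m <- length(structure$names)
  comp_names <- c(structure$names, "residual")

  vy <- stats::var(y)
  if (vy <= 0) stop("input error: zero-variance response")
  ys <- (y - mean(y)) / sqrt(vy)

  if (!vc_identifiable(structure)) {
    return(structure(list(sigma2 = stats::setNames(rep(NA_real_, m + 1L), comp_names),
                          h2 = NA_real_, household_effect = NA_real_,
                          converged = FALSE, n_iter = 0L, loglik = NA_real_,
                          boundary = FALSE, note = "unidentifiable",
                          beta = NULL), class = "vc_fit"))
  }

  if (structure$mode == "rotation") {
    U <- structure$U
    yr <- drop(crossprod(U, ys)); Xr <- crossprod(U, X)
    dlist <- list(structure$d, rep(1, n))
    evalfn <- function(theta) {
      v <- theta[1] * dlist[[1]] + theta[2]
      if (any(v <= 0)) return(NULL)
      w <- 1 / v
      WX <- Xr * w
      XtVX <- crossprod(Xr, WX)
      bet <- tryCatch(solve(XtVX, crossprod(WX, yr)), error = function(e) NULL)
      if (is.null(bet)) return(NULL)
      r <- yr - Xr %*% bet
      Py <- w * r
      yPy <- sum(r * Py)
      ll <- -0.5 * (sum(log(v)) + determinant(XtVX)$modulus[1] + yPy)
      XtVXi <- solve(XtVX)
      trPV <- numeric(2); yPVPy <- numeric(2); ulist <- vector("list", 2)
      for (i in 1:2) {
        di <- dlist[[i]]
        trPV[i] <- sum(w * di) - sum(XtVXi * crossprod(WX, di * WX))
        u <- di * Py
        ulist[[i]] <- u
        yPVPy[i] <- sum(Py * u)
      }
      Pu <- lapply(ulist, function(u) {
        w * u - WX %*% solve(XtVX, crossprod(Xr, w * u))
      })
      AI <- matrix(0, 2, 2)
      for (i in 1:2) for (j in i:2) {
        AI[i, j] <- AI[j, i] <- 0.5 * sum(ulist[[i]] * Pu[[j]])
      }
      list(ll = ll, trPV = trPV, yPVPy = yPVPy, AI = AI, beta = bet)
    }
  } else {
    p <- ncol(X)
    # batch blocks with identical covariance sub-matrices and covariate
    # rows (e.g. same-size families under an intercept-only model): the
    # per-block algebra then collapses to a handful of matrix products
    sig <- vapply(structure$blocks, function(b) {
      paste(c(length(b$idx),
              sprintf("%.12g", unlist(b$V)),
              sprintf("%.12g", X[b$idx, , drop = FALSE])), collapse = ",")
    }, character(1))
    groups <- lapply(split(seq_along(structure$blocks), sig), function(ks) {
      b1 <- structure$blocks[[ks[1]]]
      bs <- length(b1$idx)
      list(V = b1$V, X = X[b1$idx, , drop = FALSE], n_g = length(ks),
           Y = vapply(ks, function(k) ys[structure$blocks[[k]]$idx],
                      numeric(bs)),
           bs = bs)
    })
    for (g in seq_along(groups)) {
      if (is.null(dim(groups[[g]]$Y))) {
        groups[[g]]$Y <- matrix(groups[[g]]$Y, nrow = groups[[g]]$bs)
      }
    }
    evalfn <- function(theta) {
      XtVX <- matrix(0, p, p); Xty <- numeric(p); logdet <- 0
      pre <- vector("list", length(groups))
      for (g in seq_along(groups)) {
        gr <- groups[[g]]
        Vb <- diag(theta[m + 1L], gr$bs)
        for (i in seq_len(m)) Vb <- Vb + theta[i] * gr$V[[i]]
        cb <- tryCatch(chol(Vb), error = function(e) NULL)
        if (is.null(cb)) return(NULL)
        Vinv <- chol2inv(cb)
        WX <- Vinv %*% gr$X
        logdet <- logdet + 2 * sum(log(diag(cb))) * gr$n_g
        XtVX <- XtVX + gr$n_g * crossprod(gr$X, WX)
        Xty <- Xty + rowSums(crossprod(WX, gr$Y))
        pre[[g]] <- list(Vinv = Vinv, WX = WX)
      }
      bet <- tryCatch(solve(XtVX, Xty), error = function(e) NULL)
      if (is.null(bet)) return(NULL)
      XtVXi <- solve(XtVX)
      yPy <- 0; trPV <- numeric(m + 1L); yPVPy <- numeric(m + 1L)
      corr <- lapply(seq_len(m + 1L), function(i) matrix(0, p, p))
      avec <- matrix(0, p, m + 1L)
      PyG <- vector("list", length(groups))
      UG <- vector("list", length(groups))
      for (g in seq_along(groups)) {
        gr <- groups[[g]]; pr <- pre[[g]]
        Rg <- gr$Y - drop(gr$X %*% bet)
        Py <- pr$Vinv %*% Rg
        yPy <- yPy + sum(Rg * Py)
        PyG[[g]] <- Py
        UG[[g]] <- vector("list", m + 1L)
        for (i in seq_len(m + 1L)) {
          Vi <- if (i <= m) gr$V[[i]] else diag(1, gr$bs)
          trPV[i] <- trPV[i] + gr$n_g * sum(pr$Vinv * Vi)
          corr[[i]] <- corr[[i]] + gr$n_g * crossprod(pr$WX, Vi %*% pr$WX)
          U <- if (i <= m) Vi %*% Py else Py
          UG[[g]][[i]] <- U
          yPVPy[i] <- yPVPy[i] + sum(Py * U)
          avec[, i] <- avec[, i] + rowSums(crossprod(pr$WX, U))
        }
      }
      for (i in seq_len(m + 1L)) trPV[i] <- trPV[i] - sum(XtVXi * corr[[i]])
      ll <- -0.5 * (logdet + determinant(XtVX)$modulus[1] + yPy)
      AI <- matrix(0, m + 1L, m + 1L)
      coef_a <- solve(XtVX, avec)
      for (g in seq_along(groups)) {
        pr <- pre[[g]]
        for (j in seq_len(m + 1L)) {
          Puj <- pr$Vinv %*% UG[[g]][[j]] - drop(pr$WX %*% coef_a[, j])
          for (i in seq_len(m + 1L)) {
            AI[i, j] <- AI[i, j] + 0.5 * sum(UG[[g]][[i]] * Puj)
          }
        }
      }
      AI <- (AI + t(AI)) / 2
      list(ll = ll, trPV = trPV, yPVPy = yPVPy, AI = AI, beta = bet)
    }
  }

  lb <- 1e-10
  theta <- rep(1 / (m + 1L), m + 1L)
  ev <- evalfn(theta)
  if (is.null(ev)) stop("matrix error: initial variance model is singular")
  boundary <- FALSE
  n_iter <- 0L
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    n_iter <- it
    if (it <= 20L) { # EM warm start
      theta_new <- theta + theta^2 * (ev$yPVPy - ev$trPV) / n
      theta_new <- pmax(theta_new, lb)
      ev_new <- evalfn(theta_new)
      if (is.null(ev_new)) break
    } else { # average-information updates with step halving and active set
      score <- -0.5 * (ev$trPV - ev$yPVPy)
      # components pinned at the floor whose gradient points outward are
      # fixed there; the AI system is solved over the free components
      free <- !(theta <= lb * 1.01 & score < 0)
      if (!any(free)) { converged <- TRUE; break }
      step <- rep(0, m + 1L)
      sol <- tryCatch(solve(ev$AI[free, free, drop = FALSE] +
                              diag(1e-12, sum(free)), score[free]),
                      error = function(e) NULL)
      if (is.null(sol)) sol <- (theta^2 * (ev$yPVPy - ev$trPV) / n)[free]
      step[free] <- sol
      ok <- FALSE
      for (h in 0:25) {
        theta_new <- pmax(theta + step / 2^h, lb)
        ev_new <- evalfn(theta_new)
        if (!is.null(ev_new) && ev_new$ll >= ev$ll - 1e-12) { ok <- TRUE; break }
      }
      if (!ok) { converged <- TRUE; break } # no uphill step left
    }
    delta <- max(abs(theta_new - theta))
    dll <- abs(ev_new$ll - ev$ll) / (abs(ev$ll) + 1)
    theta <- theta_new; ev <- ev_new
    if (it > 20L && (delta < tol || dll < 1e-8)) { converged <- TRUE; break }
  }
  boundary <- any(theta <= lb * 1.01)
  sigma2 <- stats::setNames(theta * vy, comp_names)
  total <- sum(sigma2)
  h2 <- if ("A" %in% comp_names) unname(sigma2["A"] / total) else
    unname(sigma2[1] / total)
  hh <- if ("H" %in% comp_names) unname(sigma2["H"] / total) else NA_real_
  structure(list(sigma2 = sigma2, h2 = h2, household_effect = hh,
                 converged = converged, n_iter = n_iter, loglik = ev$ll,
                 boundary = boundary, note = if (boundary) "boundary" else "",
                 beta = drop(ev$beta)), class = "vc_fit")
}

#' @export
print.vc_fit <- function(x, ...) {
  cat("vc_fit: sigma2 =", paste(sprintf("%s=%.4g", names(x$sigma2), x$sigma2),
                                collapse = ", "),
      sprintf("| h2=%.3f household=%.3f %s (%d iter)\n", x$h2,
              x$household_effect, if (x$converged) "converged" else "NOT converged",
              x$n_iter))
  invisible(x)
}

#' Heritability scan over a set of CpGs
#'
#' Decomposes every CpG into additive-genetic, household and residual
#' variance against shared kinship and household matrices, and summarizes
#' the scan with the standard bin counts at heritability 0.1 / 0.3 / 0.6
#' and household effect 0.1. Per-CpG failures are flagged rows, never an
#' aborted scan.
#'
#' @param cpgs a \code{cpg_matrix} or plain sample-by-CpG matrix.
#' @param covariates fixed-covariate matrix or NULL.
#' @param K,H kinship and household matrices.
#' @param max_iter REML iteration cap per CpG.
#' @return list(table = per-CpG data.frame, counts = named bin counts).
#' @export
heritability_scan <- function(cpgs, covariates = NULL, K, H, max_iter = 100L) {
  M <- if (inherits(cpgs, "cpg_matrix")) cpgs$beta else as.matrix(cpgs)
  if (ncol(M) < 1) stop("input error: no CpGs to scan")
  struct <- vc_structure(list(A = K, H = H))
  rows <- lapply(seq_len(ncol(M)), function(j) {
    fit <- tryCatch(fit_variance_components(M[, j], covariates,
                                            list(A = K, H = H),
                                            max_iter = max_iter,
                                            structure = struct),
                    error = function(e) NULL)
    if (is.null(fit)) {
      data.frame(cpg_id = colnames(M)[j], sigma2_A = NA_real_, sigma2_h = NA_real_,
                 sigma2_e = NA_real_, h2 = NA_real_, household = NA_real_,
                 converged = FALSE, note = "error", stringsAsFactors = FALSE)
    } else {
      data.frame(cpg_id = colnames(M)[j], sigma2_A = unname(fit$sigma2["A"]),
                 sigma2_h = unname(fit$sigma2["H"]),
                 sigma2_e = unname(fit$sigma2["residual"]), h2 = fit$h2,
                 household = fit$household_effect, converged = fit$converged,
                 note = fit$note, stringsAsFactors = FALSE)
    }
  })
  tab <- do.call(rbind, rows)
  counts <- c(h2_gt_0.1 = sum(tab$h2 > 0.1, na.rm = TRUE),
              h2_gt_0.3 = sum(tab$h2 > 0.3, na.rm = TRUE),
              h2_gt_0.6 = sum(tab$h2 > 0.6, na.rm = TRUE),
              household_gt_0.1 = sum(tab$household > 0.1, na.rm = TRUE))
  list(table = tab, counts = counts)
}

#' Genomic relationship matrix from SNP dosages
#'
#' Standard GRM: G_ij = (1/m) sum_k (g_ik - 2 p_k)(g_jk - 2 p_k) /
#' (2 p_k (1 - p_k)), with p_k the sample allele frequency. Monomorphic
#' SNPs are skipped (count recorded in the \code{n_skipped} attribute).
#'
#' @param genotypes a \code{genotype_matrix} or plain dosage matrix.
#' @param snp_ids optional subset of SNP ids (columns).
#' @return symmetric matrix of class \code{grm} with attributes
#'   \code{n_snps_used}, \code{n_skipped}.
#' @export
grm_from_snps <- function(genotypes, snp_ids = NULL) {
  dos <- if (inherits(genotypes, "genotype_matrix")) genotypes$dosage else
    as.matrix(genotypes)
  if (!is.null(snp_ids)) {
    missing <- setdiff(snp_ids, colnames(dos))
    if (length(missing) > 0) stop("input error: unknown SNP ids: ",
                                  paste(utils::head(missing, 3), collapse = ", "))
    dos <- dos[, snp_ids, drop = FALSE]
  }
  p <- colMeans(dos) / 2
  poly <- p > 0 & p < 1
  n_skipped <- sum(!poly)
  dos <- dos[, poly, drop = FALSE]
  p <- p[poly]
  if (ncol(dos) == 0) stop("input error: no polymorphic SNPs left")
  Z <- sweep(dos, 2, 2 * p, `-`)
  Z <- sweep(Z, 2, sqrt(2 * p * (1 - p)), `/`)
  G <- tcrossprod(Z) / ncol(Z)
  attr(G, "n_snps_used") <- ncol(Z)
  attr(G, "n_skipped") <- n_skipped
  class(G) <- c("grm", class(G))
  G
}

#' Proportion of a CpG's variance explained by a SNP set
#'
#' REML fit of y ~ N(Xb, sigma2_g * G + sigma2_e * I) on (nominally
#' unrelated) samples; returns sigma2_g / (sigma2_g + sigma2_e). A
#' non-converged fit is returned with attribute \code{flagged = TRUE}.
#'
#' @param y methylation values.
#' @param grm GRM from \code{\link{grm_from_snps}}.
#' @param covariates fixed covariates or NULL.
#' @return proportion in [0, 1] with attributes \code{converged}, \code{flagged}.
#' @export
meqtl_variance_explained <- function(y, grm, covariates = NULL) {
  G <- unclass(grm)
  attr(G, "n_snps_used") <- NULL; attr(G, "n_skipped") <- NULL
  fit <- fit_variance_components(y, covariates, list(G = G))
  out <- unname(fit$sigma2[1] / sum(fit$sigma2))
  attr(out, "converged") <- fit$converged
  attr(out, "flagged") <- !fit$converged || fit$note == "unidentifiable"
  out
}
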