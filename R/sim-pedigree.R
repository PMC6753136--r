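#' Simulate a pedigree with kinship and household matrices
#'
#' Families are nuclear: two founder parents and a sampled number of
#' siblings. The familial relatedness (co-ancestry) matrix uses coefficient
#' 0.5 between parent and offspring and between siblings, 0 between all
#' other individuals and 1 on the diagonal; the shared-household matrix is
#' 1 within a family (diagonal included) and 0 elsewhere. When
#' \code{parents_observed} is FALSE the parent rows are retained in the
#' pedigree table (flagged unobserved, they are still needed for Mendelian
#' genotype transmission) but excluded from both matrices.
#'
#' @param config a \code{\link{sim_config}}.
#' @return list with \code{pedigree} (data.frame: sample_id, family_id,
#'   father_id, mother_id, role, observed), \code{kinship} and
#'   \code{household} (square matrices over observed samples).
#' @export
simulate_pedigree <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  rows <- list()
  for (f in seq_len(config$n_families)) {
    fid <- sprintf("F%04d", f)
    fa <- paste0(fid, "_P1"); mo <- paste0(fid, "_P2")
    ns <- if (config$sibs_per_family[1] == config$sibs_per_family[2]) {
      config$sibs_per_family[1]
    } else {
      sample(seq(config$sibs_per_family[1], config$sibs_per_family[2]), 1L)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      sample_id = c(fa, mo, sprintf("%s_S%d", fid, seq_len(ns))),
      family_id = fid,
      father_id = c(NA, NA, rep(fa, ns)),
      mother_id = c(NA, NA, rep(mo, ns)),
      role = c("father", "mother", rep("sib", ns)),
      observed = c(rep(config$parents_observed, 2L), rep(TRUE, ns)),
      stringsAsFactors = FALSE)
  }
  if (config$n_unrelated > 0) {
    rows[[length(rows) + 1L]] <- data.frame(
      sample_id = sprintf("U%04d", seq_len(config$n_unrelated)),
      family_id = sprintf("U%04d", seq_len(config$n_unrelated)),
      father_id = NA_character_, mother_id = NA_character_,
      role = "singleton", observed = TRUE, stringsAsFactors = FALSE)
  }
  ped <- do.call(rbind, rows)
  obs <- ped[ped$observed, ]
  n <- nrow(obs)
  if (n < 2) stop("configuration error: fewer than 2 observed samples")
  K <- diag(1, n); H <- diag(1, n)
  dimnames(K) <- dimnames(H) <- list(obs$sample_id, obs$sample_id)
  for (fid in unique(obs$family_id[obs$role != "singleton"])) {
    idx <- which(obs$family_id == fid)
    H[idx, idx] <- 1
    roles <- obs$role[idx]
    for (a in seq_along(idx)) {
      for (b in seq_along(idx)) {
        if (a == b) next
        first_degree <-
          (roles[a] == "sib" && roles[b] == "sib") ||
          (roles[a] %in% c("father", "mother") && roles[b] == "sib") ||
          (roles[a] == "sib" && roles[b] %in% c("father", "mother"))
        if (first_degree) K[idx[a], idx[b]] <- 0.5
      }
    }
  }
  list(pedigree = ped, kinship = K, household = H)
}

#' Select one individual per family plus all singletons
#'
#' Deterministic given the seed: family members are sampled uniformly,
#' singletons are always kept, so families and singletons together yield an
#' unrelated subset (one per family).
#'
#' @param pedigree pedigree data.frame from \code{\link{simulate_pedigree}}.
#' @param seed integer seed.
#' @return character vector of selected sample ids, in pedigree order.
#' @export
select_unrelated <- function(pedigree, seed = 1L) {
  obs <- pedigree[pedigree$observed, ]
  set.seed(seed)
  keep <- unlist(lapply(split(obs$sample_id, obs$family_id), function(ids) {
    if (length(ids) == 1L) ids else sample(ids, 1L)
  }), use.names = FALSE)
  obs$sample_id[obs$sample_id %in% keep]
}
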