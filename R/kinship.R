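#' Pedigree-derived kinship matrix
#'
#' Expected additive genetic similarity from family relationships: 1 for
#' monozygotic co-twins, 1/2 for dizygotic co-twins and full siblings
#' (including a twin and a non-twin sibling in the same family), 0 for
#' members of different families. The diagonal is 1 (self-similarity),
#' which the covariance model requires.
#'
#' @param pedigree An `"scfc_pedigree"`.
#' @return Symmetric numeric matrix with subject IDs as dimnames, in
#'   pedigree row order.
#' @export
kinship_matrix <- function(pedigree) {
  pedigree <- validate_pedigree(as.data.frame(pedigree))
  n <- nrow(pedigree)
  K <- matrix(0, n, n,
              dimnames = list(pedigree$subject_id, pedigree$subject_id))
  fam <- pedigree$family_id
  for (f in unique(fam)) {
    idx <- which(fam == f)
    K[idx, idx] <- 0.5
  }
  is_mz <- pedigree$relationship == "MZ_twin"
  for (tp in unique(pedigree$twin_pair_id[is_mz])) {
    idx <- which(!is.na(pedigree$twin_pair_id) &
                   pedigree$twin_pair_id == tp)
    K[idx, idx] <- 1
  }
  diag(K) <- 1
  K
}

#' Pedigree-derived shared-environment matrix
#'
#' Indicator of shared rearing environment: 1 when two subjects have the
#' same parents (same family), 0 otherwise; diagonal 1.
#'
#' @inheritParams kinship_matrix
#' @return Symmetric 0/1 matrix in pedigree row order.
#' @export
shared_env_matrix <- function(pedigree) {
  pedigree <- validate_pedigree(as.data.frame(pedigree))
  n <- nrow(pedigree)
  L <- matrix(0, n, n,
              dimnames = list(pedigree$subject_id, pedigree$subject_id))
  fam <- pedigree$family_id
  for (f in unique(fam)) {
    idx <- which(fam == f)
    L[idx, idx] <- 1
  }
  diag(L) <- 1
  L
}

#' Measurement-to-subject expansion matrix
#'
#' The 0/1 incidence matrix mapping stacked repeated measurements to
#' subjects: one row per measurement with a single 1 in its subject's
#' column, so column i sums to that subject's number of repeated
#' measures.
#'
#' @param phenotypes An `"scfc_phenotypes"` table (rows define the
#'   measurement stacking order), or a vector of subject IDs, one per
#'   measurement row.
#' @param subjects Optional character vector fixing subject (column)
#'   order; defaults to order of first appearance.
#' @return Numeric 0/1 matrix, `n_total` rows by `n_subj` columns.
#' @export
expansion_matrix <- function(phenotypes, subjects = NULL) {
  ids <- if (inherits(phenotypes, "scfc_phenotypes") ||
             is.data.frame(phenotypes)) {
    as.character(phenotypes$subject_id)
  } else {
    as.character(phenotypes)
  }
  if (is.null(subjects)) subjects <- unique(ids)
  j <- match(ids, subjects)
  if (anyNA(j)) stop_scfc("measurement rows reference unknown subjects")
  T_mat <- matrix(0, length(ids), length(subjects),
                  dimnames = list(NULL, subjects))
  T_mat[cbind(seq_along(ids), j)] <- 1
  T_mat
}
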