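#' Functional connectivity from regional time series
#'
#' Pearson correlation between every pair of regional average time
#' series, giving a functional connectome with unit diagonal.
#'
#' @param timeseries Numeric matrix, timepoints by regions (T >= 3).
#' @param subject_id,measurement Metadata for the resulting connectome.
#' @return An `"scfc_connectome"` with modality `"FC"`.
#' @export
functional_connectivity <- function(timeseries, subject_id = "subj",
                                    measurement = 1L) {
  if (!is.matrix(timeseries) || nrow(timeseries) < 3L) {
    stop_scfc("timeseries must be a matrix with at least 3 timepoints")
  }
  sds <- apply(timeseries, 2, stats::sd)
  if (any(sds == 0)) {
    bad <- which(sds == 0)
    nm <- if (is.null(colnames(timeseries))) as.character(bad) else
      colnames(timeseries)[bad]
    stop_scfc("constant time series for region(s): ",
              paste(nm, collapse = ", "))
  }
  fc <- stats::cor(timeseries)
  dimnames(fc) <- NULL
  connectome(fc, "FC", subject_id, measurement)
}

# shared engine: per-region Spearman over a variant-specific partner set.
# partner_sets[[i]] holds the column indices correlated for region i
# (self already excluded). Regions with < min_pairs partners or a
# zero-variance rank vector are flagged undefined (NA), never zeroed.
#' @noRd
coupling_engine <- function(sc, fc, partner_sets, variant, subject_id,
                            min_pairs = 3L) {
  n <- nrow(sc)
  values <- rep(NA_real_, n)
  n_pairs <- integer(n)
  for (i in seq_len(n)) {
    idx <- partner_sets[[i]]
    n_pairs[i] <- length(idx)
    if (length(idx) < min_pairs) next
    x <- sc[i, idx]
    y <- fc[i, idx]
    if (length(unique(x)) < 2L || length(unique(y)) < 2L) next
    values[i] <- stats::cor(x, y, method = "spearman")
  }
  structure(
    data.frame(region = seq_len(n), value = values, n_pairs = n_pairs),
    subject_id = subject_id, variant = variant,
    class = c("scfc_coupling", "data.frame")
  )
}

#' @noRd
check_pair <- function(sc, fc) {
  if (nrow(sc) != nrow(fc)) {
    stop_scfc("SC and FC connectomes have different dimensions")
  }
  if (nrow(sc) < 3L) stop_scfc("coupling needs at least 3 regions")
}

#' Regional structure-function coupling
#'
#' For each region, the Spearman rank correlation between its row of the
#' structural connectome and the corresponding row of the functional
#' connectome, over the n-1 off-diagonal entries (self-connection
#' excluded). Ties — abundant in sparse SC rows — receive average ranks.
#' Regions whose SC (or FC) row is entirely tied (e.g. all zeros) get a
#' missing value, not a silent zero.
#'
#' @param sc,fc Structural and functional `"scfc_connectome"` objects on
#'   the same parcellation.
#' @return A data frame of class `"scfc_coupling"` with columns `region`
#'   (1-based position in parcellation order), `value` (Spearman rho or
#'   `NA` if undefined) and `n_pairs` (partners used), plus attributes
#'   `subject_id` and `variant`.
#' @export
regional_coupling <- function(sc, fc) {
  check_pair(sc, fc)
  n <- nrow(sc)
  partners <- lapply(seq_len(n), function(i) setdiff(seq_len(n), i))
  coupling_engine(sc, fc, partners, "whole_brain",
                  attr(sc, "subject_id") %||% "subj")
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Within- or between-network coupling
#'
#' As [regional_coupling()], but the partner set for each region is
#' restricted to regions in the same network (`mode = "within"`) or to
#' regions outside its network (`mode = "between"`). Regions with fewer
#' than 3 partners after restriction are flagged undefined — a real
#' caveat for small networks, whose restricted coupling is noisy.
#'
#' @inheritParams regional_coupling
#' @param parcellation Parcellation supplying network labels.
#' @param mode `"within"` or `"between"`.
#' @export
network_coupling <- function(sc, fc, parcellation,
                             mode = c("within", "between")) {
  mode <- match.arg(mode)
  check_pair(sc, fc)
  n <- nrow(sc)
  if (nrow(parcellation) != n) {
    stop_scfc("parcellation size does not match connectome dimension")
  }
  net <- parcellation$network
  partners <- lapply(seq_len(n), function(i) {
    same <- which(net == net[i])
    if (mode == "within") setdiff(same, i) else setdiff(seq_len(n), same)
  })
  coupling_engine(sc, fc, partners,
                  paste0(mode, "_network"),
                  attr(sc, "subject_id") %||% "subj")
}

#' Single-hemisphere coupling
#'
#' As [regional_coupling()] but restricted to partners in the region's own
#' hemisphere, a sensitivity variant for the known underestimation of
#' cross-hemisphere structural connections by tractography.
#'
#' @inheritParams network_coupling
#' @export
intra_hemisphere_coupling <- function(sc, fc, parcellation) {
  check_pair(sc, fc)
  n <- nrow(sc)
  if (nrow(parcellation) != n) {
    stop_scfc("parcellation size does not match connectome dimension")
  }
  hemi <- parcellation$hemisphere
  partners <- lapply(seq_len(n), function(i) {
    setdiff(which(hemi == hemi[i]), i)
  })
  coupling_engine(sc, fc, partners, "intra_hemisphere",
                  attr(sc, "subject_id") %||% "subj")
}

#' Distance-partialled coupling
#'
#' Partial Spearman correlation between a region's SC and FC rows with the
#' Euclidean distance between region centroids as a covariate: all three
#' vectors are rank-transformed (average ranks), the two connectivity rank
#' vectors are residualized on the distance ranks by least squares, and
#' the residuals are Pearson-correlated. Controls for the tendency of
#' tractography weights and functional correlations to both decay with
#' distance.
#'
#' @inheritParams network_coupling
#' @export
partial_coupling_distance <- function(sc, fc, parcellation) {
  check_pair(sc, fc)
  n <- nrow(sc)
  if (nrow(parcellation) != n) {
    stop_scfc("parcellation size does not match connectome dimension")
  }
  xyz <- as.matrix(parcellation[, c("x", "y", "z")])
  dist_mat <- as.matrix(stats::dist(xyz))
  values <- rep(NA_real_, n)
  n_pairs <- integer(n)
  warned <- FALSE
  for (i in seq_len(n)) {
    idx <- setdiff(seq_len(n), i)
    n_pairs[i] <- length(idx)
    x <- sc[i, idx]
    y <- fc[i, idx]
    d <- dist_mat[i, idx]
    if (length(unique(x)) < 2L || length(unique(y)) < 2L) next
    rx <- rank(x)
    ry <- rank(y)
    if (length(unique(d)) < 2L) {
      # degenerate covariate: residualization is a no-op up to centering
      if (!warned) {
        warning("constant centroid distance; falling back to plain Spearman",
                call. = FALSE)
        warned <- TRUE
      }
      values[i] <- stats::cor(rx, ry)
      next
    }
    rd <- rank(d)
    qx <- stats::lm.fit(cbind(1, rd), cbind(rx, ry))$residuals
    values[i] <- stats::cor(qx[, 1], qx[, 2])
  }
  structure(
    data.frame(region = seq_len(n), value = values, n_pairs = n_pairs),
    subject_id = attr(sc, "subject_id") %||% "subj",
    variant = "partial_distance",
    class = c("scfc_coupling", "data.frame")
  )
}

#' Node strength of a connectome
#'
#' Row sums excluding the diagonal; for functional connectomes the l1 norm
#' of the row (sum of absolute values) so that anticorrelations add, not
#' cancel.
#'
#' @param conn An `"scfc_connectome"`.
#' @return Numeric vector of per-region strengths (always >= 0 for both
#'   modalities).
#' @export
node_strength <- function(conn) {
  mat <- unclass(conn)
  if (identical(attr(conn, "modality"), "FC")) mat <- abs(mat)
  rowSums(mat) - diag(mat)
}

#' Fisher r-to-z transform
#'
#' `atanh(rho)`, the variance-stabilizing transform applied to coupling
#' values before Gaussian linear modelling. Missing values pass through.
#'
#' @param rho Correlations with `|rho| < 1`.
#' @return `atanh(rho)`.
#' @export
fisher_z <- function(rho) {
  if (any(abs(rho) >= 1, na.rm = TRUE)) {
    stop_scfc("fisher_z requires |rho| < 1")
  }
  atanh(rho)
}

#' Average functional connectomes entrywise
#'
#' Averages repeated FC measurements entrywise on the Pearson scale (not
#' z-transformed), the convention used before computing coupling for all
#' analyses except heritability, which uses the measurements separately.
#'
#' @param fc_list List of `"scfc_connectome"` objects with modality `"FC"`
#'   and identical dimension.
#' @return One `"scfc_connectome"` of modality `"FC"`.
#' @export
average_fc <- function(fc_list) {
  if (!length(fc_list)) stop_scfc("empty FC list")
  n <- nrow(fc_list[[1]])
  acc <- matrix(0, n, n)
  for (fc in fc_list) {
    if (nrow(fc) != n) stop_scfc("FC matrices differ in dimension")
    acc <- acc + unclass(fc)
  }
  connectome(acc / length(fc_list), "FC",
             attr(fc_list[[1]], "subject_id") %||% "subj", 1L)
}

#' @export
print.scfc_coupling <- function(x, ...) {
  v <- x$value
  cat(sprintf(
    "Regional coupling (%s), subject %s: %d regions, %d undefined\n",
    attr(x, "variant"), attr(x, "subject_id"), nrow(x), sum(is.na(v))))
  cat(sprintf("  mean %.3f, range [%.3f, %.3f]\n",
              mean(v, na.rm = TRUE), min(v, na.rm = TRUE),
              max(v, na.rm = TRUE)))
  invisible(x)
}
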