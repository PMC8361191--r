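# Repeated-measures variance-components model
#
#   y = X beta + T g + T c + T e + eps
#   g ~ N(0, sA2 K),  c ~ N(0, sC2 Lambda),  e ~ N(0, sE2 I_subj),
#   eps ~ N(0, sM2 I_total)
#   cov[y] = sA2 T K T' + sC2 T Lambda T' + sE2 T T' + sM2 I
#
# The covariance is block diagonal over families, and families with the
# same (kinship pattern, measurement counts) share identical blocks, so
# one Cholesky per unique pattern whitens every family in that group.

# ---- structure preparation --------------------------------------------------

# derive family blocks and pattern groups from K, Lambda and the
# measurement->subject map; reusable across phenotypes on the same pedigree
#' @noRd
reml_prepare <- function(K, Lambda, subject_idx, n_subj = ncol(K)) {
  n_total <- length(subject_idx)
  # family membership: connected components of the nonzero pattern
  comp <- covariance_blocks(K, Lambda)
  # rows per subject, preserving original measurement order
  rows_by_subject <- split(seq_len(n_total), factor(subject_idx,
                                                    levels = seq_len(n_subj)))
  m_i <- lengths(rows_by_subject)
  if (any(m_i == 0L)) {
    stop_scfc("subject(s) without any measurement row")
  }
  fam_keys <- character(max(comp))
  fam_info <- vector("list", max(comp))
  for (f in seq_len(max(comp))) {
    subj <- which(comp == f)
    Kf <- K[subj, subj, drop = FALSE]
    Lf <- Lambda[subj, subj, drop = FALSE]
    mv <- m_i[subj]
    fam_keys[f] <- paste(c(mv, round(4 * Kf), Lf), collapse = ",")
    fam_info[[f]] <- list(subj = subj, Kf = Kf, Lf = Lf, mv = mv,
                          rows = unlist(rows_by_subject[subj],
                                        use.names = FALSE))
  }
  groups <- lapply(split(seq_along(fam_keys), fam_keys), function(fs) {
    info <- fam_info[[fs[1]]]
    mv <- info$mv
    b <- sum(mv)
    sub_of_row <- rep(seq_along(info$subj), mv)
    A <- info$Kf[sub_of_row, sub_of_row, drop = FALSE]
    C <- info$Lf[sub_of_row, sub_of_row, drop = FALSE]
    E <- outer(sub_of_row, sub_of_row, "==") * 1
    rows_mat <- vapply(fs, function(f) fam_info[[f]]$rows, integer(b))
    list(A = A, C = C, E = E, b = b, k = length(fs),
         rows = as.vector(rows_mat))
  })
  # identifiability of the pedigree
  within_kin <- unlist(lapply(fam_info, function(fi) {
    if (length(fi$subj) > 1L) fi$Kf[upper.tri(fi$Kf)] else numeric(0)
  }), use.names = FALSE)
  list(groups = groups, n_total = n_total, n_subj = n_subj, m_i = m_i,
       n_families = max(comp),
       all_singletons = length(within_kin) == 0L,
       kin_levels = sort(unique(within_kin)))
}

# ---- restricted likelihood --------------------------------------------------

# whitened sufficient statistics for variance vector v = (A, C, E, M);
# returns -Inf style NULL on a non-PD block
#' @noRd
reml_suffstats <- function(v, struct, D_list, p) {
  logdetV <- 0
  XtX <- matrix(0, p, p)
  Xty <- numeric(p)
  yty <- 0
  for (gi in seq_along(struct$groups)) {
    g <- struct$groups[[gi]]
    V <- v[1] * g$A + v[2] * g$C + v[3] * g$E
    diag(V) <- diag(V) + v[4]
    R <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(R)) return(NULL)
    W <- backsolve(R, D_list[[gi]], transpose = TRUE)
    # columns are variable-major: k columns of y, then k per covariate
    k <- g$k
    Wy <- as.vector(W[, seq_len(k), drop = FALSE])
    Wx <- matrix(W[, -seq_len(k), drop = FALSE], nrow = g$b * k)
    XtX <- XtX + crossprod(Wx)
    Xty <- Xty + crossprod(Wx, Wy)[, 1]
    yty <- yty + sum(Wy^2)
    logdetV <- logdetV + 2 * k * sum(log(diag(R)))
  }
  list(logdetV = logdetV, XtX = XtX, Xty = Xty, yty = yty)
}

#' @noRd
reml_loglik_from_stats <- function(ss, n_total, p) {
  cXX <- tryCatch(chol(ss$XtX), error = function(e) NULL)
  if (is.null(cXX)) return(NULL)
  beta <- backsolve(cXX, backsolve(cXX, ss$Xty, transpose = TRUE))
  yPy <- ss$yty - sum(ss$Xty * beta)
  ll <- -0.5 * ((n_total - p) * log(2 * pi) + ss$logdetV +
                  2 * sum(log(diag(cXX))) + yPy)
  list(loglik = ll, beta = beta, cXX = cXX)
}

# pack data [y | X] per group in variable-major column order
#' @noRd
reml_pack_data <- function(y, X, struct) {
  lapply(struct$groups, function(g) {
    rows <- g$rows
    Ymat <- matrix(y[rows], nrow = g$b)        # b x k
    Xarr <- X[rows, , drop = FALSE]            # (b*k) x p, family-major rows
    D <- cbind(Ymat, matrix(Xarr, nrow = g$b)) # b x (k*(1+p))
    D
  })
}

# ---- fitting ----------------------------------------------------------------

#' Fit the variance-components model by restricted maximum likelihood
#'
#' Estimates the four variance components of the repeated-measures model
#' — additive genetic (`sigma2_A`, kernel `K`), common environment
#' (`sigma2_C`, kernel `Lambda`), unique subject environment (`sigma2_E`)
#' and intra-subject measurement error (`sigma2_M`) — by maximizing the
#' restricted log-likelihood, with fixed effects profiled out by
#' generalized least squares. Variances are log-parameterized (hence
#' never negative) and optimized by bounded quasi-Newton search from
#' three starts (equal split, measurement-dominant, genetic-dominant) so
#' boundary solutions are reachable. The likelihood factorizes over
#' family blocks, and families with identical kinship/measurement
#' patterns share one Cholesky factor per evaluation.
#'
#' Model reduction and identifiability: with a single measurement per
#' subject, `sigma2_M` is inseparable from `sigma2_E` and is dropped with
#' a warning; with an all-singleton pedigree (`K` and `Lambda` diagonal)
#' the A/C/E split is unidentified — the total inter-subject variance is
#' still estimated (reported in `sigma2_E`) but `sigma2_A`, `sigma2_C`
#' and the heritability are flagged undefined. A pedigree with only one
#' level of within-family kinship (only MZ pairs, or only DZ/sib pairs)
#' cannot separate A from C and is flagged.
#'
#' @param y Stacked phenotype vector (all subjects, all repeated
#'   measurements).
#' @param X Fixed-effects design matrix, `length(y)` rows, full column
#'   rank.
#' @param K Kinship matrix from [kinship_matrix()].
#' @param Lambda Shared-environment matrix from [shared_env_matrix()].
#' @param T_mat Expansion matrix from [expansion_matrix()] mapping
#'   measurement rows to subjects; alternatively give `subject_idx`.
#' @param subject_idx Integer vector (length `length(y)`) of subject
#'   column indices into `K`; used instead of `T_mat`.
#' @param struct Optional precomputed structure from an earlier fit on
#'   the same pedigree/measurement layout (internal reuse).
#' @param control List: `tol` (log-likelihood improvement tolerance,
#'   default 1e-8), `maxit`.
#' @return An object of class `"scfc_vc"`: list with `sigma2` (named
#'   vector A, C, E, M), `h2`, `beta`, `beta_cov`, `loglik` (restricted),
#'   `converged`, `boundary` (named logical, variances pinned at the
#'   lower bound), `flags` (character), `n_total`, `n_subj`,
#'   `n_families`.
#' @seealso [ace_reml()] for the formula interface, [heritability()].
#' @export
reml_fit <- function(y, X, K, Lambda, T_mat = NULL, subject_idx = NULL,
                     struct = NULL, control = list()) {
  tol <- control$tol %||% 1e-8
  maxit <- control$maxit %||% 500L
  y <- as.numeric(y)
  X <- as.matrix(X)
  if (is.null(subject_idx)) {
    if (is.null(T_mat)) stop_scfc("give either T_mat or subject_idx")
    subject_idx <- max.col(T_mat, ties.method = "first")
  }
  n_total <- length(y)
  if (nrow(X) != n_total || length(subject_idx) != n_total) {
    stop_scfc("y, X and the measurement map differ in length")
  }
  p <- ncol(X)
  if (qr(X)$rank < p) stop_scfc("fixed-effects design is rank deficient")
  if (n_total <= p + 4L) {
    stop_scfc("too few measurements to estimate 4 variance components")
  }
  if (is.null(struct)) struct <- reml_prepare(K, Lambda, subject_idx)

  flags <- character(0)
  estim <- c(A = TRUE, C = TRUE, E = TRUE, M = TRUE)
  if (all(struct$m_i == 1L)) {
    warning(paste("single measurement per subject: sigma2_M is not",
                  "separable from sigma2_E and is dropped"), call. = FALSE)
    flags <- c(flags, "sigma2_M_dropped")
    estim["M"] <- FALSE
  }
  if (struct$all_singletons) {
    flags <- c(flags, "ace_inseparable")
    estim["A"] <- estim["C"] <- FALSE
  } else if (length(struct$kin_levels) == 1L) {
    flags <- c(flags,
               if (struct$kin_levels == 1) "ac_confounded_no_dz_sib" else
                 "ac_confounded_no_mz")
  }

  vtot <- stats::var(y)
  if (!is.finite(vtot) || vtot < .Machine$double.eps) {
    # degenerate: constant phenotype
    beta <- qr.coef(qr(X), y)
    out <- structure(list(
      sigma2 = c(A = 0, C = 0, E = 0, M = 0), h2 = NA_real_,
      beta = beta, beta_cov = matrix(NA_real_, p, p),
      loglik = NA_real_, converged = FALSE,
      boundary = c(A = TRUE, C = TRUE, E = TRUE, M = TRUE),
      flags = c(flags, "degenerate_constant_phenotype"),
      n_total = n_total, n_subj = struct$n_subj,
      n_families = struct$n_families, struct = struct
    ), class = "scfc_vc")
    return(out)
  }

  D_list <- reml_pack_data(y, X, struct)
  act <- which(estim)
  n_act <- length(act)
  lower <- log(vtot) - 20
  upper <- log(vtot) + 6

  objective <- function(par) {
    v <- c(A = 0, C = 0, E = 0, M = 0)
    v[act] <- exp(par)
    ss <- reml_suffstats(v, struct, D_list, p)
    if (is.null(ss)) return(1e10)
    fit <- reml_loglik_from_stats(ss, n_total, p)
    if (is.null(fit) || !is.finite(fit$loglik)) return(1e10)
    -fit$loglik
  }

  starts <- list(equal = rep(vtot / n_act, n_act))
  wts_m <- rep(0.3 / max(1, n_act - 1), n_act)
  nm <- names(estim)[act]
  if ("M" %in% nm) wts_m[nm == "M"] <- 0.7 else wts_m <- rep(1 / n_act, n_act)
  starts$measurement <- vtot * wts_m
  wts_g <- rep(0.3 / max(1, n_act - 1), n_act)
  if ("A" %in% nm) wts_g[nm == "A"] <- 0.7 else wts_g <- rep(1 / n_act, n_act)
  starts$genetic <- vtot * wts_g

  best <- NULL
  for (s in starts) {
    par0 <- pmin(pmax(log(s), lower), upper)
    opt <- tryCatch(
      stats::optim(par0, objective, method = "L-BFGS-B",
                   lower = lower, upper = upper,
                   control = list(maxit = maxit,
                                  factr = tol / .Machine$double.eps)),
      error = function(e) NULL)
    if (!is.null(opt) && (is.null(best) || opt$value < best$value)) {
      best <- opt
    }
  }
  if (is.null(best)) stop_scfc("restricted-likelihood optimization failed")

  v_hat <- c(A = 0, C = 0, E = 0, M = 0)
  v_hat[act] <- exp(best$par)
  # snap variances at the optimization floor to exact zero
  at_floor <- v_hat > 0 & v_hat <= exp(lower) * (1 + 1e-6)
  v_hat[at_floor] <- 0
  boundary <- c(A = FALSE, C = FALSE, E = FALSE, M = FALSE)
  boundary[names(estim)[act]] <- at_floor[act]

  v_eval <- v_hat
  if (sum(v_eval) <= 0) v_eval["E"] <- vtot * 1e-10
  ss <- reml_suffstats(v_eval, struct, D_list, p)
  if (is.null(ss)) {
    v_eval["M"] <- max(v_eval["M"], vtot * 1e-10)
    ss <- reml_suffstats(v_eval, struct, D_list, p)
  }
  fit <- reml_loglik_from_stats(ss, n_total, p)
  beta <- fit$beta
  names(beta) <- colnames(X)
  beta_cov <- chol2inv(fit$cXX)
  dimnames(beta_cov) <- list(colnames(X), colnames(X))

  sigma2 <- v_hat
  if (struct$all_singletons) {
    sigma2["A"] <- NA_real_
    sigma2["C"] <- NA_real_
  }
  h2 <- if (anyNA(sigma2[c("A", "C", "E")])) {
    NA_real_
  } else if (sum(sigma2[c("A", "C", "E")]) > 0) {
    unname(sigma2["A"] / sum(sigma2[c("A", "C", "E")]))
  } else {
    flags <- c(flags, "h2_undefined_zero_intersubject_variance")
    NA_real_
  }

  structure(list(
    sigma2 = sigma2, h2 = h2, beta = beta, beta_cov = beta_cov,
    loglik = fit$loglik, converged = best$convergence == 0,
    boundary = boundary, flags = flags,
    n_total = n_total, n_subj = struct$n_subj,
    n_families = struct$n_families, struct = struct
  ), class = "scfc_vc")
}

#' Heritability of the stable inter-subject variation
#'
#' The genetic fraction of stable (non-transient) between-person
#' variance: `sigma2_A / (sigma2_A + sigma2_C + sigma2_E)`. Measurement
#' error is excluded from the denominator, so this is the heritability of
#' the trait itself, not of a single noisy measurement of it. Undefined
#' (NA) when all three inter-subject variances are zero or when the A/C/E
#' split is unidentified.
#'
#' @param x An `"scfc_vc"` / `"ace_reml"` fit, or a numeric vector of at
#'   least three variances `(sigma2_A, sigma2_C, sigma2_E)`.
#' @return Heritability in \[0, 1\], or `NA` if undefined.
#' @export
heritability <- function(x) {
  if (inherits(x, "scfc_vc")) return(x$h2)
  v <- as.numeric(x)[1:3]
  if (any(v < 0, na.rm = TRUE)) stop_scfc("variances must be >= 0")
  if (anyNA(v) || sum(v) <= 0) return(NA_real_)
  v[1] / sum(v)
}

#' @export
print.scfc_vc <- function(x, digits = 4, ...) {
  cat("Variance components (ReML)\n")
  cat(sprintf("  measurements: %d, subjects: %d, families: %d\n",
              x$n_total, x$n_subj, x$n_families))
  s <- x$sigma2
  lab <- c(A = "additive genetic   (A)", C = "common environment (C)",
           E = "unique environment (E)", M = "measurement error  (M)")
  for (k in names(s)) {
    cat(sprintf("  %s: %s%s\n", lab[[k]],
                formatC(s[[k]], digits = digits, format = "fg"),
                if (isTRUE(x$boundary[[k]])) " (boundary)" else ""))
  }
  cat(sprintf("  heritability h2 = %s\n",
              formatC(x$h2, digits = digits, format = "fg")))
  cat(sprintf("  restricted log-likelihood = %.4f (%s)\n", x$loglik,
              if (x$converged) "converged" else "NOT converged"))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' @export
logLik.scfc_vc <- function(object, ...) {
  structure(object$loglik, df = sum(!is.na(object$sigma2)) +
              length(object$beta), class = "logLik")
}

#' @export
coef.scfc_vc <- function(object, ...) object$beta

#' @export
vcov.scfc_vc <- function(object, ...) object$beta_cov
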