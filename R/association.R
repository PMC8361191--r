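#' @noRd
DESIGN_TERMS <- c("age", "sex", "education", "cognition", "icv", "motion",
                  "age_x_cognition", "sex_x_cognition",
                  "education_x_cognition", "icv_x_motion")

#' Build the regional-model design matrix
#'
#' Ten covariate columns plus an intercept: the six main effects (age,
#' sex, years of education, total cognition score, intracranial volume,
#' in-scanner motion) and four two-way interactions (age x cognition,
#' sex x cognition, education x cognition, ICV x motion). Sex is coded
#' female = 0, male = 1. Interactions are elementwise products of the
#' main-effect columns; by default these are not centered first
#' (`center = TRUE` mean-centers main effects before forming products,
#' which changes the interpretation of main-effect coefficients only).
#'
#' @param cohort An `"scfc_cohort"` data frame.
#' @param center Center main effects before forming interaction products?
#' @return Numeric matrix, subjects by 11 columns (`intercept` first),
#'   with subject IDs as row names.
#' @export
build_design <- function(cohort, center = FALSE) {
  needed <- c("age", "sex", "education", "cognition", "icv", "motion")
  for (col in needed) {
    if (!col %in% names(cohort)) {
      stop_scfc("cohort is missing required column '", col, "'")
    }
    if (anyNA(cohort[[col]])) {
      stop_scfc("cohort column '", col, "' has missing values")
    }
  }
  sex <- ifelse(cohort$sex == "male", 1, 0)
  main <- cbind(age = cohort$age, sex = sex,
                education = cohort$education, cognition = cohort$cognition,
                icv = cohort$icv, motion = cohort$motion)
  prod_base <- if (center) scale(main, scale = FALSE) else main
  X <- cbind(
    intercept = 1,
    main,
    age_x_cognition = prod_base[, "age"] * prod_base[, "cognition"],
    sex_x_cognition = prod_base[, "sex"] * prod_base[, "cognition"],
    education_x_cognition =
      prod_base[, "education"] * prod_base[, "cognition"],
    icv_x_motion = prod_base[, "icv"] * prod_base[, "motion"]
  )
  rownames(X) <- cohort$subject_id
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    dropped <- colnames(X)[qr_x$pivot[(qr_x$rank + 1L):ncol(X)]]
    stop_scfc("design matrix is rank deficient; collinear column(s): ",
              paste(dropped, collapse = ", "))
  }
  X
}

#' Per-region linear models of coupling on covariates
#'
#' Regresses the Fisher r-to-z transform of each region's coupling values
#' on the design matrix by ordinary least squares (Gaussian model,
#' identity link), one model per region. Coefficient t-tests use
#' `n - ncol(X)` degrees of freedom with two-sided p-values.
#' Benjamini-Hochberg q-values are computed across regions separately for
#' each covariate, matching per-covariate significance maps.
#'
#' Regions with missing coupling for some subjects are fitted on the
#' complete cases, with degrees of freedom adjusted accordingly.
#'
#' @param coupling Numeric matrix, subjects by regions (row names =
#'   subject IDs), of coupling values in (-1, 1); or an
#'   `"scfc_phenotypes"` table with a single measurement per subject.
#' @param design Design matrix from [build_design()].
#' @param alpha FDR level for the significance flag.
#' @param transform `"fisher_z"` (default, for correlations) or
#'   `"identity"` (phenotypes already on a linear scale).
#' @return Data frame of class `"scfc_glm"`: one row per (region,
#'   covariate) with `beta`, `t`, `p`, `q`, `significant`, `df`.
#' @export
fit_regional_glm <- function(coupling, design, alpha = 0.05,
                             transform = c("fisher_z", "identity")) {
  transform <- match.arg(transform)
  Y <- phenotype_matrix(coupling)
  if (!is.null(rownames(Y)) && !is.null(rownames(design))) {
    if (!setequal(rownames(Y), rownames(design))) {
      stop_scfc("subjects differ between coupling and design")
    }
    Y <- Y[rownames(design), , drop = FALSE]
  } else if (nrow(Y) != nrow(design)) {
    stop_scfc("row counts differ between coupling and design")
  }
  if (nrow(design) <= ncol(design)) {
    stop_scfc("need more subjects than design columns")
  }
  if (transform == "fisher_z") Y <- fisher_z(Y)
  p_cov <- ncol(design)
  n_reg <- ncol(Y)
  beta <- t_stat <- p_val <- matrix(NA_real_, n_reg, p_cov,
                                    dimnames = list(NULL, colnames(design)))
  df_used <- integer(n_reg)
  complete <- !anyNA(Y)
  if (complete) {
    fit <- stats::lm.fit(design, Y)
    res <- as.matrix(fit$residuals)
    df <- nrow(design) - p_cov
    sigma2 <- colSums(res^2) / df
    xtx_inv <- xtx_inverse(design)
    se <- sqrt(outer(sigma2, diag(xtx_inv)))
    beta[] <- t(as.matrix(fit$coefficients))
    t_stat[] <- beta / se
    p_val[] <- 2 * stats::pt(abs(t_stat), df, lower.tail = FALSE)
    df_used[] <- df
  } else {
    warning("missing coupling values; region-wise listwise deletion applied",
            call. = FALSE)
    for (k in seq_len(n_reg)) {
      ok <- !is.na(Y[, k])
      df <- sum(ok) - p_cov
      if (df < 1L) next
      Xk <- design[ok, , drop = FALSE]
      fit <- stats::lm.fit(Xk, Y[ok, k])
      sigma2 <- sum(fit$residuals^2) / df
      xtx_inv <- xtx_inverse(Xk)
      beta[k, ] <- fit$coefficients
      t_stat[k, ] <- beta[k, ] / sqrt(sigma2 * diag(xtx_inv))
      p_val[k, ] <- 2 * stats::pt(abs(t_stat[k, ]), df, lower.tail = FALSE)
      df_used[k] <- df
    }
  }
  out <- do.call(rbind, lapply(seq_len(p_cov), function(j) {
    covariate <- colnames(design)[j]
    p <- p_val[, j]
    if (covariate == "intercept") {
      q <- rep(NA_real_, n_reg)
      rej <- rep(NA, n_reg)
    } else {
      fdr <- bh_fdr(p, alpha)
      q <- fdr$q
      rej <- fdr$reject
    }
    data.frame(region = seq_len(n_reg), covariate = covariate,
               beta = beta[, j], t = t_stat[, j], p = p, q = q,
               significant = rej, df = df_used,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  structure(out, alpha = alpha, class = c("scfc_glm", "data.frame"))
}

# (X'X)^-1 via the QR factorization of X; raw cross products of
# mm^3-scale covariates overflow double-precision conditioning
#' @noRd
xtx_inverse <- function(X) {
  R <- qr.R(qr(X))
  out <- chol2inv(R)
  dimnames(out) <- list(colnames(X), colnames(X))
  out
}

#' @noRd
phenotype_matrix <- function(x) {
  if (inherits(x, "scfc_phenotypes")) {
    if (anyDuplicated(x$subject_id)) {
      stop_scfc("phenotype table has repeated measurements; ",
                "average or select one before regression")
    }
    m <- as.matrix(x[, setdiff(names(x), c("subject_id", "measurement")),
                     drop = FALSE])
    rownames(m) <- x$subject_id
    m
  } else if (is.matrix(x)) {
    x
  } else {
    as.matrix(x)
  }
}

#' Benjamini-Hochberg false discovery rate control
#'
#' Step-up adjustment with monotone q-values; rejection at `q <= alpha`.
#' Missing p-values propagate as missing.
#'
#' @param p Vector of p-values in \[0, 1\].
#' @param alpha FDR level.
#' @return List with `q` (adjusted p-values) and `reject` (logical).
#' @export
bh_fdr <- function(p, alpha = 0.05) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop_scfc("p-values must lie in [0, 1]")
  }
  q <- stats::p.adjust(p, method = "BH")
  list(q = q, reject = q <= alpha)
}
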