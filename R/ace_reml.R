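#' Repeated-measures ACE + measurement-error model
#'
#' Formula interface to the variance-components model fitted by
#' [reml_fit()]. The phenotype is decomposed into fixed covariate
#' effects, an additive genetic effect (covariance proportional to the
#' pedigree kinship matrix), a common-environment effect (shared by
#' subjects with the same parents), a unique subject effect, and
#' intra-subject measurement error estimated from repeated measures.
#' Heritability is the genetic share of the stable inter-subject
#' variance.
#'
#' @param formula Model formula for the fixed effects, e.g.
#'   `value ~ age + sex + handedness`.
#' @param data Data frame with one row per (subject, measurement),
#'   containing the response, the covariates and a `subject_id` column.
#' @param pedigree An `"scfc_pedigree"` covering every subject in `data`.
#' @param standardize Z-score the response over all measurement rows
#'   before fitting (the convention for regional phenotypes)?
#' @param control Passed to [reml_fit()].
#' @return An object of classes `"ace_reml"` and `"scfc_vc"`; see
#'   [reml_fit()] for the fields. Supports `print()`, `summary()`,
#'   `coef()`, `vcov()`, `logLik()`, `fitted()`, `residuals()` and
#'   `simulate()`.
#' @examples
#' ped <- generate_pedigree(family_composition(20, 20, 40, 10), seed = 1)
#' cov <- generate_covariates(ped, seed = 2)
#' phen <- simulate_ace_phenotypes(ped, true_variances(0.4, 0.2, 0.4, 0.25),
#'                                 cov, n_measurements = 4, seed = 3)
#' d <- stack_phenotype(phen, region = 1, cohort = cov)
#' fit <- ace_reml(value ~ age + sex, d, ped)
#' fit
#' @export
ace_reml <- function(formula, data, pedigree, standardize = FALSE,
                     control = list()) {
  if (!"subject_id" %in% names(data)) {
    stop_scfc("'data' needs a subject_id column")
  }
  pedigree <- validate_pedigree(as.data.frame(pedigree))
  missing_sub <- setdiff(unique(data$subject_id), pedigree$subject_id)
  if (length(missing_sub)) {
    stop_scfc("subject(s) absent from pedigree: ",
              paste(utils::head(missing_sub, 5), collapse = ", "))
  }
  ped_use <- pedigree[pedigree$subject_id %in% data$subject_id, ,
                      drop = FALSE]
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  if (standardize) y <- as.numeric(scale(y))
  X <- stats::model.matrix(formula, mf)
  K <- kinship_matrix(ped_use)
  Lambda <- shared_env_matrix(ped_use)
  subject_idx <- match(data$subject_id, ped_use$subject_id)
  fit <- reml_fit(y, X, K, Lambda, subject_idx = subject_idx,
                  control = control)
  fit$call <- match.call()
  fit$formula <- formula
  fit$X <- X
  fit$y <- y
  fit$subject_idx <- subject_idx
  fit$K <- K
  fit$Lambda <- Lambda
  class(fit) <- c("ace_reml", class(fit))
  fit
}

#' @export
print.ace_reml <- function(x, ...) {
  cat("Call: ")
  print(x$call)
  NextMethod()
}

#' @export
summary.ace_reml <- function(object, ...) {
  s2 <- object$sigma2
  total <- sum(s2, na.rm = TRUE)
  se <- sqrt(diag(object$beta_cov))
  zval <- object$beta / se
  coefs <- cbind(Estimate = object$beta, `Std. Error` = se, `z value` = zval,
                 `Pr(>|z|)` = 2 * stats::pnorm(abs(zval), lower.tail = FALSE))
  out <- list(call = object$call, sigma2 = s2,
              fractions = s2 / total, h2 = object$h2,
              coefficients = coefs, loglik = object$loglik,
              converged = object$converged, flags = object$flags,
              n_total = object$n_total, n_subj = object$n_subj)
  class(out) <- "summary.ace_reml"
  out
}

#' @export
print.summary.ace_reml <- function(x, digits = 4, ...) {
  cat("Repeated-measures ACE + measurement-error model (ReML)\n\nCall: ")
  print(x$call)
  cat(sprintf("\n%d measurements on %d subjects\n", x$n_total, x$n_subj))
  tab <- cbind(`variance` = x$sigma2, `fraction of total` = x$fractions)
  print(round(tab, digits))
  cat(sprintf("\nHeritability of stable inter-subject variance: h2 = %s\n",
              formatC(x$h2, digits = digits, format = "fg")))
  cat("\nFixed effects:\n")
  stats::printCoefmat(x$coefficients, digits = digits)
  cat(sprintf("\nRestricted log-likelihood: %.4f (%s)\n", x$loglik,
              if (x$converged) "converged" else "NOT converged"))
  if (length(x$flags)) cat("Flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' @export
fitted.ace_reml <- function(object, ...) {
  drop(object$X %*% object$beta)
}

#' @export
residuals.ace_reml <- function(object, ...) {
  object$y - fitted(object)
}

#' @export
simulate.ace_reml <- function(object, nsim = 1, seed = NULL, ...) {
  s2 <- object$sigma2
  s2[is.na(s2)] <- 0
  mu <- fitted(object)
  draw <- function() {
    gamma <- draw_family_effects(object$K, object$Lambda,
                                 s2[["A"]], s2[["C"]], s2[["E"]])
    mu + gamma[object$subject_idx] +
      stats::rnorm(length(mu), 0, sqrt(s2[["M"]]))
  }
  sims <- if (is.null(seed)) {
    replicate(nsim, draw())
  } else {
    with_seed(seed, replicate(nsim, draw()))
  }
  as.data.frame(sims)
}

#' Stack one region of a phenotype table for model fitting
#'
#' Extracts one region's column from a phenotype table into the long
#' layout [ace_reml()] expects, merging in subject-level covariates.
#'
#' @param phenotypes An `"scfc_phenotypes"` table.
#' @param region Region column: 1-based position or column name.
#' @param cohort Optional cohort table; its columns are joined by
#'   `subject_id`.
#' @return Data frame with `subject_id`, `measurement`, `value` and any
#'   cohort covariates.
#' @export
stack_phenotype <- function(phenotypes, region, cohort = NULL) {
  region_cols <- setdiff(names(phenotypes), c("subject_id", "measurement"))
  col <- if (is.numeric(region)) region_cols[region] else region
  if (is.na(col) || !col %in% region_cols) {
    stop_scfc("unknown region column")
  }
  out <- data.frame(subject_id = phenotypes$subject_id,
                    measurement = phenotypes$measurement,
                    value = phenotypes[[col]],
                    stringsAsFactors = FALSE)
  if (!is.null(cohort)) {
    out <- merge(out, as.data.frame(cohort), by = "subject_id", sort = FALSE)
  }
  out[order(match(out$subject_id, unique(phenotypes$subject_id)),
            out$measurement), , drop = FALSE]
}

#' Regional heritability map
#'
#' Fits the ACE + measurement-error model region by region over a
#' phenotype table. Each region's phenotype is z-standardized across all
#' stacked measurements, cohort covariates named in `covariates` enter as
#' fixed effects (sex coded female = 0, male = 1), and optional
#' region-wise covariate tables (e.g. SC and FC node strength for the
#' coupling model) contribute the matching region column. Regions with
#' any undefined phenotype value are skipped with a message.
#'
#' @param phenotypes An `"scfc_phenotypes"` table (rows = subject x
#'   measurement, columns = regions).
#' @param cohort Cohort covariate table.
#' @param pedigree Pedigree covering all subjects.
#' @param covariates Character vector of cohort columns used as fixed
#'   effects.
#' @param region_covariates Named list of `"scfc_phenotypes"` tables; for
#'   each, the current region's column is added as a fixed-effect
#'   covariate (z-standardized). Tables with a single measurement per
#'   subject are recycled across the phenotype's measurements.
#' @param standardize Z-score each region's phenotype before fitting.
#' @param control Passed to [reml_fit()].
#' @return Data frame with one row per region: variance components,
#'   `h2`, per-component fractions of total variance, `loglik`,
#'   `converged`, `flags`.
#' @export
regional_heritability <- function(phenotypes, cohort, pedigree,
                                  covariates = c("age", "sex", "handedness"),
                                  region_covariates = NULL,
                                  standardize = TRUE, control = list()) {
  pedigree <- validate_pedigree(as.data.frame(pedigree))
  region_cols <- setdiff(names(phenotypes), c("subject_id", "measurement"))
  cohort <- as.data.frame(cohort)
  miss_cov <- setdiff(covariates, names(cohort))
  if (length(miss_cov)) {
    stop_scfc("cohort is missing covariate column(s): ",
              paste(miss_cov, collapse = ", "))
  }
  ped_use <- pedigree[pedigree$subject_id %in% phenotypes$subject_id, ,
                      drop = FALSE]
  K <- kinship_matrix(ped_use)
  Lambda <- shared_env_matrix(ped_use)
  subject_idx <- match(phenotypes$subject_id, ped_use$subject_id)
  if (anyNA(subject_idx)) stop_scfc("subject(s) absent from pedigree")
  struct <- reml_prepare(K, Lambda, subject_idx)

  ci <- match(phenotypes$subject_id, cohort$subject_id)
  if (anyNA(ci)) stop_scfc("subject(s) absent from cohort")
  Xbase <- cbind(intercept = rep(1, nrow(phenotypes)))
  for (cv in covariates) {
    colv <- cohort[[cv]][ci]
    if (anyNA(colv)) stop_scfc("cohort column '", cv, "' has missing values")
    if (cv == "sex") colv <- ifelse(colv == "male", 1, 0)
    Xbase <- cbind(Xbase, colv)
    colnames(Xbase)[ncol(Xbase)] <- cv
  }

  region_cov_vals <- NULL
  if (!is.null(region_covariates)) {
    region_cov_vals <- lapply(region_covariates, function(tab) {
      if (ncol(tab) - 2L != length(region_cols)) {
        stop_scfc("region covariate table has mismatched region count")
      }
      key_t <- paste(tab$subject_id, tab$measurement)
      key_p <- paste(phenotypes$subject_id, phenotypes$measurement)
      idx <- match(key_p, key_t)
      if (anyNA(idx)) {
        # single-measurement covariate (e.g. SC strength): recycle by subject
        idx <- match(phenotypes$subject_id, tab$subject_id)
        if (anyNA(idx)) stop_scfc("region covariate misses subject(s)")
      }
      list(tab = tab, idx = idx)
    })
  }

  res <- vector("list", length(region_cols))
  for (k in seq_along(region_cols)) {
    yk <- phenotypes[[region_cols[k]]]
    if (anyNA(yk)) {
      message("region ", region_cols[k],
              " skipped: undefined phenotype values")
      res[[k]] <- NULL
      next
    }
    if (standardize) yk <- as.numeric(scale(yk))
    Xk <- Xbase
    if (!is.null(region_cov_vals)) {
      for (nm in names(region_cov_vals)) {
        rc <- region_cov_vals[[nm]]
        v <- rc$tab[[region_cols[k] ]][rc$idx]
        if (anyNA(v)) {
          stop_scfc("region covariate '", nm, "' undefined for region ",
                    region_cols[k])
        }
        Xk <- cbind(Xk, as.numeric(scale(v)))
        colnames(Xk)[ncol(Xk)] <- nm
      }
    }
    fit <- suppressWarnings(
      reml_fit(yk, Xk, K, Lambda, subject_idx = subject_idx,
               struct = struct, control = control))
    total <- sum(fit$sigma2, na.rm = TRUE)
    res[[k]] <- data.frame(
      region = region_cols[k],
      sigma2_A = fit$sigma2[["A"]], sigma2_C = fit$sigma2[["C"]],
      sigma2_E = fit$sigma2[["E"]], sigma2_M = fit$sigma2[["M"]],
      h2 = fit$h2,
      frac_A = fit$sigma2[["A"]] / total,
      frac_C = fit$sigma2[["C"]] / total,
      frac_E = fit$sigma2[["E"]] / total,
      frac_M = fit$sigma2[["M"]] / total,
      loglik = fit$loglik, converged = fit$converged,
      flags = paste(fit$flags, collapse = ";"),
      stringsAsFactors = FALSE)
  }
  skipped <- vapply(res, is.null, logical(1))
  out <- do.call(rbind, res[!skipped])
  if (any(skipped)) {
    skipped_rows <- data.frame(
      region = region_cols[skipped], sigma2_A = NA_real_,
      sigma2_C = NA_real_, sigma2_E = NA_real_, sigma2_M = NA_real_,
      h2 = NA_real_, frac_A = NA_real_, frac_C = NA_real_,
      frac_E = NA_real_, frac_M = NA_real_, loglik = NA_real_,
      converged = NA, flags = "skipped_undefined_phenotype",
      stringsAsFactors = FALSE)
    out <- rbind(out, skipped_rows)
  }
  out <- out[match(region_cols, out$region), , drop = FALSE]
  rownames(out) <- NULL
  out
}
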