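make_cohort <- function(n, seed = 1) {
  ped <- generate_pedigree(family_composition(0, 0, 0, n), seed = seed)
  generate_covariates(ped, seed = seed + 1)
}

test_that("the design matrix has the ten specified covariate columns", {
  cohort <- make_cohort(30)
  X <- build_design(cohort)
  expect_equal(ncol(X), 11L)
  expect_equal(colnames(X)[1], "intercept")
  expect_setequal(colnames(X)[-1],
                  c("age", "sex", "education", "cognition", "icv", "motion",
                    "age_x_cognition", "sex_x_cognition",
                    "education_x_cognition", "icv_x_motion"))
  # sex coding and uncentered products, checked by hand on 5 subjects
  small <- cohort[1:5, ]
  Xs <- X[1:5, ]
  expect_equal(Xs[, "sex"], ifelse(small$sex == "male", 1, 0),
               ignore_attr = TRUE)
  expect_equal(Xs[, "age_x_cognition"], small$age * small$cognition,
               ignore_attr = TRUE)
  expect_equal(Xs[, "education_x_cognition"],
               small$education * small$cognition, ignore_attr = TRUE)
  expect_equal(Xs[, "icv_x_motion"], small$icv * small$motion,
               ignore_attr = TRUE)
})

test_that("collinear designs are rejected with the offending columns", {
  cohort <- make_cohort(30)
  cohort$cognition <- 2  # constant: age*cognition is collinear with age
  expect_error(build_design(cohort), "collinear")
})

test_that("noiseless coefficients are recovered exactly", {
  cohort <- make_cohort(40)
  X <- build_design(cohort)
  z <- 0.3 + 2 * cohort$motion
  Y <- matrix(tanh(z), ncol = 1)
  rownames(Y) <- cohort$subject_id
  fit <- fit_regional_glm(Y, X)
  beta <- fit$beta[fit$region == 1]
  names(beta) <- fit$covariate[fit$region == 1]
  expect_equal(beta[["motion"]], 2, tolerance = 1e-10)
  expect_equal(beta[["intercept"]], 0.3, tolerance = 1e-10)
  others <- setdiff(names(beta), c("motion", "intercept"))
  expect_true(all(abs(beta[others]) < 1e-10))

  # constant response: only the intercept survives
  Yc <- matrix(tanh(0.25), nrow = 40, ncol = 1)
  rownames(Yc) <- cohort$subject_id
  fitc <- fit_regional_glm(Yc, X)
  bc <- fitc$beta
  names(bc) <- fitc$covariate
  expect_equal(bc[["intercept"]], 0.25, tolerance = 1e-10)
  expect_true(all(abs(bc[names(bc) != "intercept"]) < 1e-10))
})

test_that("coefficients match the normal-equations oracle", {
  set.seed(4)
  cohort <- make_cohort(30, seed = 9)
  X <- build_design(cohort)
  Y <- tanh(matrix(rnorm(30 * 4, sd = 0.3), 30, 4))
  rownames(Y) <- cohort$subject_id
  fit <- fit_regional_glm(Y, X)
  Z <- atanh(Y)
  B_oracle <- oracle_normal_equations(X, Z)
  for (k in 1:4) {
    beta_k <- fit$beta[fit$region == k]
    expect_equal(beta_k, unname(B_oracle[, k]), tolerance = 1e-10)
  }
  # residual orthogonality to every design column (scaled by column
  # norm: raw covariates span nine orders of magnitude)
  for (k in 1:4) {
    beta_k <- fit$beta[fit$region == k]
    res <- Z[, k] - X %*% beta_k
    expect_true(max(abs(crossprod(X, res)) / sqrt(colSums(X^2))) < 1e-8)
  }
})

test_that("subject reordering leaves the fit unchanged", {
  set.seed(5)
  cohort <- make_cohort(25, seed = 3)
  X <- build_design(cohort)
  Y <- tanh(matrix(rnorm(25 * 3, sd = 0.3), 25, 3))
  rownames(Y) <- cohort$subject_id
  fit1 <- fit_regional_glm(Y, X)
  perm <- sample(25)
  fit2 <- fit_regional_glm(Y[perm, , drop = FALSE], X[perm, , drop = FALSE])
  expect_equal(fit1$beta, fit2$beta, tolerance = 1e-10)
  expect_equal(fit1$p, fit2$p, tolerance = 1e-10)
})

test_that("Benjamini-Hochberg step-up rejects per the hand-worked rule", {
  # largest k with p(k) <= k * alpha / m is k = 2
  res <- bh_fdr(c(0.01, 0.02, 0.04, 0.50), alpha = 0.05)
  expect_identical(res$reject, c(TRUE, TRUE, FALSE, FALSE))
  expect_true(all(res$q >= c(0.01, 0.02, 0.04, 0.50)))

  expect_identical(bh_fdr(rep(1, 5))$reject, rep(FALSE, 5))

  single <- bh_fdr(0.04, alpha = 0.05)
  expect_equal(single$q, 0.04)
  expect_true(single$reject)

  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")
})

test_that("the false discovery proportion is controlled under a global null", {
  set.seed(6)
  cohort <- make_cohort(60, seed = 13)
  X <- build_design(cohort)
  n_rep <- 500L
  alpha <- 0.05
  fdp <- vapply(seq_len(n_rep), function(r) {
    Y <- tanh(matrix(rnorm(60 * 392, sd = 0.2), 60, 392))
    rownames(Y) <- cohort$subject_id
    fit <- fit_regional_glm(Y, X, alpha = alpha)
    mot <- fit[fit$covariate == "motion", ]
    n_rej <- sum(mot$significant)
    if (n_rej == 0) 0 else n_rej / n_rej  # all discoveries are false
  }, numeric(1))
  mc_se <- stats::sd(fdp) / sqrt(n_rep)
  expect_lte(mean(fdp), alpha + 3 * mc_se)
})

test_that("missing coupling triggers listwise deletion with df adjustment", {
  set.seed(7)
  cohort <- make_cohort(40, seed = 17)
  X <- build_design(cohort)
  Y <- tanh(matrix(rnorm(40 * 2, sd = 0.3), 40, 2))
  rownames(Y) <- cohort$subject_id
  Y[1:3, 1] <- NA
  expect_warning(fit <- fit_regional_glm(Y, X), "listwise")
  expect_equal(unique(fit$df[fit$region == 1]), 40 - 3 - 11)
  expect_equal(unique(fit$df[fit$region == 2]), 40 - 11)
  # region 2 must equal its complete-data fit
  fit_full <- fit_regional_glm(Y[, 2, drop = FALSE], X)
  expect_equal(fit$beta[fit$region == 2], fit_full$beta,
               tolerance = 1e-12)
})
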