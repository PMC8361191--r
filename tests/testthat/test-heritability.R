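test_that("pedigree kernels encode the relationship classes", {
  ped <- generate_pedigree(family_composition(1, 1, 3, 2), seed = 2)
  K <- kinship_matrix(ped)
  L <- shared_env_matrix(ped)
  expect_true(isSymmetric(K))
  expect_equal(diag(K), rep(1, nrow(ped)), ignore_attr = TRUE)
  mz <- which(ped$relationship == "MZ_twin")
  dz <- which(ped$relationship == "DZ_twin")
  sib <- which(ped$relationship == "full_sibling")
  expect_equal(K[mz[1], mz[2]], 1)
  expect_equal(K[dz[1], dz[2]], 0.5)
  expect_equal(K[sib[1], sib[2]], 0.5)
  expect_equal(L[mz[1], mz[2]], 1)
  expect_equal(L[sib[1], sib[2]], 1)
  # cross-family entries vanish
  expect_equal(K[mz[1], dz[1]], 0)
  expect_equal(L[mz[1], sib[1]], 0)
  expect_true(all(K %in% c(0, 0.5, 1)))
  expect_true(all(L %in% c(0, 1)))

  two_singles <- generate_pedigree(family_composition(0, 0, 0, 2), seed = 1)
  expect_equal(kinship_matrix(two_singles), diag(2), ignore_attr = TRUE)
  expect_equal(shared_env_matrix(two_singles), diag(2), ignore_attr = TRUE)
})

test_that("the expansion matrix is a measurement-to-subject incidence", {
  ids <- c("a", "a", "b", "c", "c", "c", "c")
  Tm <- expansion_matrix(ids, c("a", "b", "c"))
  expect_equal(dim(Tm), c(7L, 3L))
  expect_equal(rowSums(Tm), rep(1, 7), ignore_attr = TRUE)
  expect_equal(colSums(Tm), c(a = 2, b = 1, c = 4))
})

test_that("ReML matches dense maximization of the restricted likelihood", {
  ped <- tiny_pedigree()  # 2 MZ pairs, 1 DZ pair, 2 singletons
  cov <- generate_covariates(ped, seed = 6)
  tr <- true_variances(0.5, 0.3, 0.4, 0.3,
                       beta = c(intercept = 1, age = 0.05))
  phen <- simulate_ace_phenotypes(ped, tr, cov, n_measurements = 2, seed = 7)
  d <- stack_phenotype(phen, 1, cov)
  fit <- ace_reml(value ~ age, d, ped,
                  control = list(tol = 1e-12, maxit = 2000))

  K <- kinship_matrix(ped)
  L <- shared_env_matrix(ped)
  Tm <- expansion_matrix(d$subject_id, ped$subject_id)
  X <- cbind(1, d$age)
  oracle <- dense_reml_fit(d$value, X, K, L, Tm)
  expect_equal(unname(fit$sigma2), oracle$sigma2, tolerance = 1e-4)
  expect_equal(fit$loglik, oracle$loglik, tolerance = 1e-6)
  # the dense likelihood evaluated at the package optimum agrees too
  expect_equal(dense_reml_loglik(fit$sigma2, d$value, X, K, L, Tm),
               fit$loglik, tolerance = 1e-8)
})

test_that("the optimum beats the simulation truth in restricted likelihood", {
  ped <- tiny_pedigree()
  cov <- generate_covariates(ped, seed = 6)
  truth_v <- c(0.5, 0.3, 0.4, 0.3)
  tr <- true_variances(truth_v[1], truth_v[2], truth_v[3], truth_v[4])
  phen <- simulate_ace_phenotypes(ped, tr, cov, n_measurements = 3, seed = 8)
  d <- stack_phenotype(phen, 1, cov)
  fit <- ace_reml(value ~ 1, d, ped)
  K <- kinship_matrix(ped)
  L <- shared_env_matrix(ped)
  Tm <- expansion_matrix(d$subject_id, ped$subject_id)
  ll_truth <- dense_reml_loglik(truth_v, d$value, matrix(1, nrow(d)), K, L,
                                Tm)
  expect_gte(fit$loglik, ll_truth - 1e-6)
})

test_that("estimates are invariant to consistent subject permutation", {
  ped <- generate_pedigree(family_composition(2, 2, 4, 2), seed = 31)
  cov <- generate_covariates(ped, seed = 32)
  tr <- true_variances(0.4, 0.2, 0.4, 0.25)
  phen <- simulate_ace_phenotypes(ped, tr, cov, n_measurements = 3,
                                  seed = 33)
  d <- stack_phenotype(phen, 1, cov)
  fit1 <- ace_reml(value ~ age, d, ped)
  set.seed(34)
  perm <- sample(nrow(ped))
  ped2 <- ped[perm, , drop = FALSE]
  fit2 <- ace_reml(value ~ age, d, ped2)
  expect_equal(fit1$sigma2, fit2$sigma2, tolerance = 1e-5)
  expect_equal(fit1$loglik, fit2$loglik, tolerance = 1e-7)
  expect_equal(fit1$h2, fit2$h2, tolerance = 1e-5)
})

test_that("degenerate and reduced models are flagged, not mis-fitted", {
  ped <- tiny_pedigree()
  cov <- generate_covariates(ped, seed = 6)
  # constant phenotype
  d <- data.frame(subject_id = rep(ped$subject_id, each = 2),
                  measurement = rep(1:2, nrow(ped)), value = 1)
  fit <- ace_reml(value ~ 1, d, ped)
  expect_false(fit$converged)
  expect_true("degenerate_constant_phenotype" %in% fit$flags)
  expect_equal(unname(fit$sigma2), rep(0, 4))

  # single measurement per subject: sigma2_M dropped with a warning
  tr <- true_variances(0.4, 0.2, 0.4, 0)
  phen <- simulate_ace_phenotypes(ped, tr, n_measurements = 1, seed = 9)
  d1 <- stack_phenotype(phen, 1)
  expect_warning(fit1 <- ace_reml(value ~ 1, d1, ped), "sigma2_M")
  expect_true("sigma2_M_dropped" %in% fit1$flags)
  expect_equal(fit1$sigma2[["M"]], 0)

  # all singletons: A/C/E inseparable but total vs M still estimable
  ped_s <- generate_pedigree(family_composition(0, 0, 0, 60), seed = 10)
  tr2 <- true_variances(0.3, 0.2, 0.3, 0.4)
  phen2 <- simulate_ace_phenotypes(ped_s, tr2, n_measurements = 4,
                                   seed = 11)
  d2 <- stack_phenotype(phen2, 1)
  fit2 <- ace_reml(value ~ 1, d2, ped_s)
  expect_true("ace_inseparable" %in% fit2$flags)
  expect_true(is.na(fit2$h2))
  expect_true(is.na(fit2$sigma2[["A"]]))
  # subject-level total (A + C + E = 0.8) is recovered in sigma2_E
  expect_lt(abs(fit2$sigma2[["E"]] - 0.8), 0.35)
  expect_lt(abs(fit2$sigma2[["M"]] - 0.4), 0.2)
})

test_that("heritability is the genetic share of stable variance", {
  expect_equal(heritability(c(0, 0.3, 0.7)), 0)
  expect_equal(heritability(c(0.5, 0, 0)), 1)
  expect_equal(heritability(c(0.4, 0.2, 0.4)), 0.4)
  expect_true(is.na(heritability(c(0, 0, 0))))
  expect_error(heritability(c(-0.1, 0.2, 0.4)), ">= 0")
})

test_that("regional heritability recovers region-wise truth", {
  ped <- generate_pedigree(family_composition(40, 30, 60, 20), seed = 41)
  cov <- generate_covariates(ped, seed = 42)
  set.seed(43)
  h2_true <- runif(12, 0.2, 0.8)
  tr <- true_variances(h2_true, 0, 1 - h2_true, 0.25)
  phen <- simulate_ace_phenotypes(ped, tr, cov, n_measurements = 4,
                                  seed = 44)
  res <- regional_heritability(phen, cov, ped,
                               covariates = c("age", "sex", "handedness"))
  expect_equal(nrow(res), 12L)
  expect_true(all(res$h2 >= 0 & res$h2 <= 1))
  expect_gt(cor(res$h2, h2_true, method = "spearman"), 0.5)
  expect_true(all(res$sigma2_A >= 0 & res$sigma2_M >= 0))

  # undefined phenotypes are skipped with a message, others still fitted
  phen$r3[5] <- NA
  expect_message(
    res2 <- regional_heritability(phen, cov, ped,
                                  covariates = c("age", "sex")),
    "skipped")
  expect_true(is.na(res2$h2[res2$region == "r3"]))
  expect_false(is.na(res2$h2[res2$region == "r1"]))
})

test_that("an all-singleton pedigree flags every region inseparable", {
  ped <- generate_pedigree(family_composition(0, 0, 0, 40), seed = 51)
  cov <- generate_covariates(ped, seed = 52)
  tr <- true_variances(c(0.4, 0.3), 0.1, 0.3, 0.3)
  phen <- simulate_ace_phenotypes(ped, tr, cov, n_measurements = 3,
                                  seed = 53)
  res <- regional_heritability(phen, cov, ped, covariates = "age")
  expect_true(all(grepl("ace_inseparable", res$flags)))
  expect_true(all(is.na(res$h2)))
})

test_that("model methods expose fit components coherently", {
  ped <- generate_pedigree(family_composition(5, 5, 10, 5), seed = 61)
  cov <- generate_covariates(ped, seed = 62)
  tr <- true_variances(0.4, 0.2, 0.4, 0.25,
                       beta = c(intercept = 0.5, age = 0.02))
  phen <- simulate_ace_phenotypes(ped, tr, cov, n_measurements = 3,
                                  seed = 63)
  d <- stack_phenotype(phen, 1, cov)
  fit <- ace_reml(value ~ age, d, ped)
  expect_named(coef(fit), c("(Intercept)", "age"))
  expect_equal(dim(vcov(fit)), c(2L, 2L))
  expect_s3_class(summary(fit), "summary.ace_reml")
  expect_equal(length(residuals(fit)), nrow(d))
  expect_equal(fitted(fit) + residuals(fit), d$value, ignore_attr = TRUE)
  expect_output(print(fit), "heritability")
  sims <- simulate(fit, nsim = 2, seed = 1)
  expect_equal(dim(sims), c(nrow(d), 2L))
  expect_identical(sims, simulate(fit, nsim = 2, seed = 1))
})
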