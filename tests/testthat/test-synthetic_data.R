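test_that("generated pedigrees honour the composition and are reproducible", {
  comp <- family_composition()
  ped <- generate_pedigree(comp, seed = 1)
  expect_equal(nrow(ped), 2 * 116 + 2 * 61 + 455 + 132)
  expect_equal(sum(ped$relationship == "MZ_twin"), 232L)
  expect_equal(sum(ped$relationship == "DZ_twin"), 122L)
  expect_equal(sum(ped$relationship == "full_sibling"), 455L)
  expect_equal(sum(ped$relationship == "singleton"), 132L)
  sib_sizes <- table(ped$family_id[ped$relationship == "full_sibling"])
  expect_true(all(sib_sizes >= 2 & sib_sizes <= 4))

  expect_identical(ped, generate_pedigree(comp, seed = 1))
  expect_false(identical(ped, generate_pedigree(comp, seed = 2)))

  solo <- generate_pedigree(family_composition(1, 0, 0, 0), seed = 1)
  expect_equal(nrow(solo), 2L)
  expect_equal(unique(solo$relationship), "MZ_twin")
  expect_equal(length(unique(solo$family_id)), 1L)
})

test_that("covariates match their configured distributions", {
  ped <- generate_pedigree(family_composition(), seed = 1)
  cohort <- generate_covariates(ped, seed = 2)
  expect_true(all(cohort$age >= 22 & cohort$age <= 37))
  expect_lt(abs(mean(cohort$age) - 28.67), 0.5)
  expect_lt(abs(mean(cohort$sex == "male") - 441 / 941), 0.06)
  expect_true(all(cohort$motion > 0))
  expect_identical(cohort, generate_covariates(ped, seed = 2))
})

test_that("phenotypes with zero variances reduce to the fixed effects", {
  ped <- tiny_pedigree()
  cov <- generate_covariates(ped, seed = 2)
  tr <- true_variances(0, 0, 0, 0, beta = c(intercept = 2, age = 0.1))
  phen <- simulate_ace_phenotypes(ped, tr, cov, n_measurements = 3, seed = 3)
  mu <- 2 + 0.1 * cov$age[match(phen$subject_id, cov$subject_id)]
  expect_equal(phen$r1, mu, tolerance = 1e-12)
})

test_that("twin intraclass correlations match the generative closed forms", {
  tr <- true_variances(0.5, 0.2, 0.3, 0.2)
  denom <- 0.5 + 0.2 + 0.3 + 0.2 / 4

  ped_mz <- generate_pedigree(family_composition(2000, 0, 0, 0), seed = 11)
  ph <- simulate_ace_phenotypes(ped_mz, tr, n_measurements = 4, seed = 12)
  mm <- pair_member_means(ph, ped_mz)
  expect_lt(abs(cor(mm[, 1], mm[, 2]) - (0.5 + 0.2) / denom), 0.03)

  ped_dz <- generate_pedigree(family_composition(0, 2000, 0, 0), seed = 13)
  ph <- simulate_ace_phenotypes(ped_dz, tr, n_measurements = 4, seed = 14)
  mm <- pair_member_means(ph, ped_dz)
  expect_lt(abs(cor(mm[, 1], mm[, 2]) - (0.25 + 0.2) / denom), 0.03)
})

test_that("empirical phenotype covariance matches the model assembly", {
  # 1 MZ pair + 1 DZ pair + 1 singleton, two measurements each
  ped <- generate_pedigree(family_composition(1, 1, 0, 1), seed = 21)
  v <- c(0.5, 0.3, 0.4, 0.3)
  tr <- true_variances(v[1], v[2], v[3], v[4])
  K <- kinship_matrix(ped)
  L <- shared_env_matrix(ped)
  m <- 2L
  Tm <- expansion_matrix(rep(ped$subject_id, each = m), ped$subject_id)
  V_theory <- v[1] * Tm %*% K %*% t(Tm) + v[2] * Tm %*% L %*% t(Tm) +
    v[3] * Tm %*% t(Tm) + v[4] * diag(nrow(Tm))

  n_rep <- 500L
  draws <- vapply(seq_len(n_rep), function(r) {
    simulate_ace_phenotypes(ped, tr, n_measurements = m, seed = 1000 + r)$r1
  }, numeric(nrow(Tm)))
  V_emp <- stats::cov(t(draws))
  se <- sqrt((outer(diag(V_theory), diag(V_theory)) + V_theory^2) / n_rep)
  expect_true(all(abs(V_emp - V_theory) <= 3 * se))
})

test_that("connectome pairs hit their target coupling", {
  parc <- default_parcellation(60)
  # strict monotone identity at density 1, target 1
  pair <- simulate_connectome_pair(parc, 1.0, sc_density = 1, seed = 1)
  cp <- regional_coupling(pair$sc, pair$fc[[1]])
  expect_equal(cp$value, rep(1, 60))

  # independence at target 0
  vals <- vapply(1:10, function(s) {
    p <- simulate_connectome_pair(parc, 0, sc_density = 0.3, seed = s)
    mean(regional_coupling(p$sc, p$fc[[1]])$value, na.rm = TRUE)
  }, numeric(1))
  expect_lt(abs(mean(vals)), 0.02)

  expect_error(simulate_connectome_pair(default_parcellation(9)[1:2, ], 0.3),
               "3 regions")
})

test_that("the tie-aware Spearman calibration is exact in its limits", {
  # continuous limit: classical bivariate-normal relation
  for (r in c(-0.8, -0.3, 0.4, 0.9)) {
    expect_equal(scfc:::spearman_censored(r, 0), 6 / pi * asin(r / 2),
                 tolerance = 1e-12)
    expect_equal(scfc:::spearman_censored(r, 1e-12),
                 6 / pi * asin(r / 2), tolerance = 1e-6)
  }
  # inversion really inverts
  for (p0 in c(0.3, 0.7)) {
    r <- scfc:::spearman_to_latent(0.25, p0)
    expect_equal(scfc:::spearman_censored(r, p0), 0.25, tolerance = 1e-8)
  }
  # unattainable targets are refused, not silently clipped
  expect_error(scfc:::spearman_to_latent(0.99, 0.7), "unattainable")
})

test_that("generators are pure functions of their seed", {
  parc <- default_parcellation(20)
  a <- simulate_connectome_pair(parc, 0.3, seed = 77)
  b <- simulate_connectome_pair(parc, 0.3, seed = 77)
  expect_identical(a, b)
  # and do not disturb the caller's RNG stream
  set.seed(99)
  before <- rnorm(1)
  set.seed(99)
  invisible(simulate_connectome_pair(parc, 0.3, seed = 1))
  expect_identical(rnorm(1), before)
})
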