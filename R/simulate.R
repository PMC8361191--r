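#' Family composition of a synthetic cohort
#'
#' Counts of monozygotic twin pairs, dizygotic twin pairs, full siblings
#' (individuals, not pairs) and singletons, plus the sibship-size range
#' used to distribute the full siblings into families. The default is the
#' composition of the heritability cohort this package emulates: 116 MZ
#' pairs, 61 DZ pairs, 455 full siblings and 132 singletons (941
#' subjects).
#'
#' @param n_mz_pairs,n_dz_pairs,n_full_sibs,n_singletons Non-negative
#'   counts.
#' @param sibship_size_range Length-2 integer vector `(min, max)` of
#'   full-sibling family sizes.
#' @return A list of class `"scfc_composition"`.
#' @export
family_composition <- function(n_mz_pairs = 116L, n_dz_pairs = 61L,
                               n_full_sibs = 455L, n_singletons = 132L,
                               sibship_size_range = c(2L, 4L)) {
  counts <- c(n_mz_pairs, n_dz_pairs, n_full_sibs, n_singletons)
  if (any(counts < 0)) stop_scfc("composition counts must be >= 0")
  if (length(sibship_size_range) != 2L ||
      sibship_size_range[1] < 2L ||
      sibship_size_range[2] < sibship_size_range[1]) {
    stop_scfc("sibship_size_range must be (min >= 2, max >= min)")
  }
  structure(list(n_mz_pairs = as.integer(n_mz_pairs),
                 n_dz_pairs = as.integer(n_dz_pairs),
                 n_full_sibs = as.integer(n_full_sibs),
                 n_singletons = as.integer(n_singletons),
                 sibship_size_range = as.integer(sibship_size_range)),
            class = "scfc_composition")
}

#' Ground-truth variance components for simulation
#'
#' @param sigma2_A,sigma2_C,sigma2_E,sigma2_M Non-negative variances
#'   (phenotype units squared): additive genetic, common environment,
#'   unique environment, intra-subject measurement error.
#' @param beta Named numeric vector of fixed-effect coefficients; names
#'   are cohort columns (plus optional `intercept`).
#' @return A list of class `"scfc_truth"`.
#' @export
true_variances <- function(sigma2_A, sigma2_C, sigma2_E, sigma2_M,
                           beta = c(intercept = 0)) {
  v <- c(sigma2_A, sigma2_C, sigma2_E, sigma2_M)
  if (any(v < 0)) stop_scfc("variances must be >= 0")
  structure(list(sigma2_A = sigma2_A, sigma2_C = sigma2_C,
                 sigma2_E = sigma2_E, sigma2_M = sigma2_M, beta = beta),
            class = "scfc_truth")
}

#' Generate a twin/sibling pedigree
#'
#' Twin pairs each form their own family; full siblings are distributed
#' into sibships with sizes drawn uniformly from the composition's
#' sibship-size range; singletons are sole members of their families.
#' Deterministic given the seed.
#'
#' @param composition An [family_composition()] object.
#' @param seed Integer seed.
#' @return An `"scfc_pedigree"` data frame.
#' @export
generate_pedigree <- function(composition = family_composition(),
                              seed = 1L) {
  stopifnot(inherits(composition, "scfc_composition"))
  with_seed(seed, {
    rows <- list()
    fam <- 0L
    sub <- 0L
    pair <- 0L
    add <- function(relationship, family, twin_pair = NA_character_) {
      sub <<- sub + 1L
      rows[[length(rows) + 1L]] <<- data.frame(
        subject_id = sprintf("S%04d", sub),
        family_id = sprintf("F%04d", family),
        relationship = relationship, twin_pair_id = twin_pair,
        stringsAsFactors = FALSE)
    }
    for (rel in c("MZ_twin", "DZ_twin")) {
      n_pairs <- if (rel == "MZ_twin") composition$n_mz_pairs else
        composition$n_dz_pairs
      for (i in seq_len(n_pairs)) {
        fam <- fam + 1L
        pair <- pair + 1L
        tp <- sprintf("TP%04d", pair)
        add(rel, fam, tp)
        add(rel, fam, tp)
      }
    }
    smin <- composition$sibship_size_range[1]
    smax <- composition$sibship_size_range[2]
    rem <- composition$n_full_sibs
    sizes <- integer(0)
    while (rem >= smin) {
      s <- sample(seq(smin, smax), 1L)
      s <- min(s, rem)
      if (rem - s > 0 && rem - s < smin) s <- rem - smin
      if (s < smin) s <- rem
      sizes <- c(sizes, s)
      rem <- rem - s
    }
    if (rem > 0) {
      # leftover smaller than a sibship: absorb into earlier families
      for (i in seq_len(rem)) {
        j <- which(sizes < smax)[1]
        if (is.na(j)) j <- length(sizes)
        sizes[j] <- sizes[j] + 1L
      }
    }
    for (s in sizes) {
      fam <- fam + 1L
      for (i in seq_len(s)) add("full_sibling", fam)
    }
    for (i in seq_len(composition$n_singletons)) {
      fam <- fam + 1L
      add("singleton", fam)
    }
    validate_pedigree(do.call(rbind, rows))
  })
}

#' Generate synthetic cohort covariates
#'
#' Ages are drawn from a normal distribution with mean 28.67 and SD 3.70
#' years, truncated to the 22-37 year range of the young-adult cohort
#' being emulated; sex is Bernoulli with P(male) = 441/941. The remaining
#' covariates use plausible young-adult ranges: education 11-17 years,
#' total cognition score around 122 (SD 10), intracranial volume around
#' 1.55e6 mm^3, in-scanner motion log-normal around 0.14 mm framewise
#' displacement, and a right-skewed handedness score in \[-100, 100\].
#' Covariates are drawn independently of each other and of family.
#'
#' @param pedigree An `"scfc_pedigree"`; one covariate row is generated
#'   per subject.
#' @param seed Integer seed.
#' @return An `"scfc_cohort"` data frame.
#' @export
generate_covariates <- function(pedigree, seed = 1L) {
  n <- nrow(pedigree)
  with_seed(seed, {
    lo <- stats::pnorm((22 - 28.67) / 3.70)
    hi <- stats::pnorm((37 - 28.67) / 3.70)
    age <- stats::qnorm(stats::runif(n, lo, hi)) * 3.70 + 28.67
    sex <- ifelse(stats::runif(n) < 441 / 941, "male", "female")
    education <- pmin(17, pmax(11, round(stats::rnorm(n, 14.9, 1.8))))
    cognition <- stats::rnorm(n, 122, 10)
    icv <- stats::rnorm(n, 1.55e6, 1.5e5)
    motion <- exp(stats::rnorm(n, log(0.14), 0.3))
    handed_right <- stats::runif(n) < 0.9
    handedness <- ifelse(handed_right, stats::runif(n, 40, 100),
                         stats::runif(n, -100, 0))
    cohort <- data.frame(subject_id = pedigree$subject_id, age = age,
                         sex = sex, education = education,
                         cognition = cognition, icv = icv, motion = motion,
                         handedness = handedness, stringsAsFactors = FALSE)
    class(cohort) <- c("scfc_cohort", "data.frame")
    cohort
  })
}

# subject-level random effects gamma = g + c + e drawn exactly from
# N(0, sA K + sC Lambda + sE I), block by family
#' @noRd
draw_family_effects <- function(K, Lambda, sA, sC, sE) {
  n <- nrow(K)
  comp <- covariance_blocks(K, Lambda)
  gamma <- numeric(n)
  for (f in unique(comp)) {
    idx <- which(comp == f)
    S <- sA * K[idx, idx, drop = FALSE] +
      sC * Lambda[idx, idx, drop = FALSE] +
      sE * diag(length(idx))
    if (all(S == 0)) next
    R <- chol(S + diag(1e-12, length(idx)))
    gamma[idx] <- drop(crossprod(R, stats::rnorm(length(idx))))
  }
  gamma
}

#' @noRd
covariance_blocks <- function(K, Lambda) {
  linked <- (K != 0) | (Lambda != 0)
  n <- nrow(K)
  comp <- integer(n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (comp[i] == 0L) {
      cur <- cur + 1L
      queue <- i
      comp[i] <- cur
      while (length(queue)) {
        v <- queue[[1]]
        queue <- queue[-1]
        nb <- which(linked[v, ] & comp == 0L)
        comp[nb] <- cur
        queue <- c(queue, nb)
      }
    }
  }
  comp
}

#' Simulate phenotypes under the ACE + measurement-error model
#'
#' Draws phenotypes exactly from the generative model: per-subject random
#' effects `g + c + e` sampled from the pedigree-structured multivariate
#' normal (Cholesky per family block), plus independent measurement error
#' per repeated measure, plus fixed covariate effects.
#'
#' @param pedigree An `"scfc_pedigree"`.
#' @param truth A [true_variances()] object; vector-valued variances
#'   produce one phenotype column per element (independent regions with
#'   region-specific truth).
#' @param covariates Optional cohort table supplying the fixed-effect
#'   columns named in `truth$beta`.
#' @param n_measurements Repeated measures per subject.
#' @param seed Integer seed.
#' @return An `"scfc_phenotypes"` table with columns `r1`, `r2`, ...
#' @export
simulate_ace_phenotypes <- function(pedigree, truth,
                                    covariates = NULL,
                                    n_measurements = 1L, seed = 1L) {
  stopifnot(inherits(truth, "scfc_truth"))
  pedigree <- validate_pedigree(as.data.frame(pedigree))
  n_subj <- nrow(pedigree)
  m <- as.integer(n_measurements)
  if (m < 1L) stop_scfc("n_measurements must be >= 1")
  K <- kinship_matrix(pedigree)
  Lambda <- shared_env_matrix(pedigree)
  n_regions <- max(length(truth$sigma2_A), length(truth$sigma2_C),
                   length(truth$sigma2_E), length(truth$sigma2_M))
  sA <- rep_len(truth$sigma2_A, n_regions)
  sC <- rep_len(truth$sigma2_C, n_regions)
  sE <- rep_len(truth$sigma2_E, n_regions)
  sM <- rep_len(truth$sigma2_M, n_regions)

  # fixed-effect mean per subject
  mu <- rep(0, n_subj)
  beta <- truth$beta
  if (!is.null(beta) && length(beta)) {
    if ("intercept" %in% names(beta)) mu <- mu + beta[["intercept"]]
    other <- setdiff(names(beta), "intercept")
    if (length(other)) {
      if (is.null(covariates)) {
        stop_scfc("truth$beta names covariates but none were supplied")
      }
      ci <- match(pedigree$subject_id, covariates$subject_id)
      if (anyNA(ci)) stop_scfc("pedigree subject(s) missing from covariates")
      for (nm in other) {
        v <- covariates[[nm]][ci]
        if (is.null(v)) stop_scfc("covariates lack column '", nm, "'")
        if (nm == "sex") v <- ifelse(v == "male", 1, 0)
        mu <- mu + beta[[nm]] * v
      }
    }
  }

  with_seed(seed, {
    cols <- lapply(seq_len(n_regions), function(r) {
      gamma <- draw_family_effects(K, Lambda, sA[r], sC[r], sE[r])
      y <- rep(mu + gamma, each = m) +
        stats::rnorm(n_subj * m, 0, sqrt(sM[r]))
      y
    })
    tab <- data.frame(
      subject_id = rep(pedigree$subject_id, each = m),
      measurement = rep(seq_len(m), times = n_subj),
      stringsAsFactors = FALSE)
    for (r in seq_len(n_regions)) tab[[paste0("r", r)]] <- cols[[r]]
    as_phenotype_table(tab)
  })
}

# ---- connectome pair simulation ---------------------------------------------

# population Spearman correlation between a zero-censored Gaussian-margin
# variable (zero mass p0, average ranks for the tie block) and a continuous
# variable sharing latent correlation r
#' @noRd
spearman_censored <- function(r, p0) {
  if (p0 <= 0) return(6 / pi * asin(r / 2))
  if (abs(r) < 1e-12) return(0)
  t0 <- stats::qnorm(p0)
  cc <- r / sqrt(2 - r^2)
  i1 <- stats::integrate(function(x) stats::pnorm(cc * x) * stats::dnorm(x),
                         -Inf, t0, rel.tol = 1e-10)$value
  i2 <- stats::integrate(function(x) {
    stats::pnorm(x) * stats::pnorm(cc * x) * stats::dnorm(x)
  }, t0, Inf, rel.tol = 1e-10)$value
  cov_ab <- p0 / 2 * i1 + i2 - 1 / 4
  var_a <- p0^3 / 4 + (1 - p0^3) / 3 - 1 / 4
  cov_ab / sqrt(var_a / 12)
}

# invert the calibration: latent correlation giving target Spearman
#' @noRd
spearman_to_latent <- function(target, p0) {
  if (abs(target) >= 1) return(sign(target))
  if (p0 <= 0) return(2 * sin(pi * target / 6))
  max_rho <- spearman_censored(0.999999, p0)
  if (abs(target) > max_rho) {
    stop_scfc(sprintf(
      "target Spearman %.3f unattainable at SC density %.2f (max %.3f)",
      target, 1 - p0, max_rho))
  }
  stats::uniroot(function(r) spearman_censored(r, p0) - target,
                 interval = c(-0.999999, 0.999999), tol = 1e-10)$root
}

#' Simulate a matched SC/FC connectome pair
#'
#' Generates a structural connectome with sparse, zero-inflated
#' log-normal weights (non-Gaussian, as real tractography-derived SC is)
#' and a functional connectome whose entries share a Gaussian-copula
#' latent correlation with the SC entries, calibrated so that the
#' population Spearman correlation between corresponding rows equals the
#' per-region target coupling. The calibration accounts exactly for the
#' tie mass at zero in sparse SC rows (and reduces to the classical
#' `(6/pi) asin(r/2)` relation at density 1).
#'
#' @param parcellation Parcellation (>= 3 regions).
#' @param target_coupling Target per-region Spearman coupling in (-1, 1)
#'   (scalar or per-region vector; the endpoint values +-1 are permitted
#'   and map to a deterministic latent relation, which yields coupling of
#'   exactly +-1 only when `sc_density = 1` so SC rows are tie-free). For
#'   entries shared by two regions with different targets, the mean of
#'   the two targets is used.
#' @param sc_density Fraction of nonzero SC entries, in (0, 1].
#' @param n_fc Number of FC measurements to generate (independent noise
#'   per measurement, same latent SC scores).
#' @param seed Integer seed.
#' @param subject_id Subject tag for the connectomes.
#' @return List with `sc` (one connectome) and `fc` (list of `n_fc`
#'   connectomes).
#' @export
simulate_connectome_pair <- function(parcellation, target_coupling = 0.25,
                                     sc_density = 0.3, n_fc = 1L,
                                     seed = 1L, subject_id = "sim") {
  n <- nrow(parcellation)
  if (n < 3L) stop_scfc("need at least 3 regions")
  if (sc_density <= 0 || sc_density > 1) {
    stop_scfc("sc_density must be in (0, 1]")
  }
  target <- rep_len(target_coupling, n)
  if (any(abs(target) > 1)) stop_scfc("target coupling must be in [-1, 1]")
  p0 <- 1 - sc_density
  pair_target <- (outer(target, target, "+")) / 2
  uniq <- unique(as.vector(pair_target))
  r_lookup <- vapply(uniq, spearman_to_latent, numeric(1), p0 = p0)
  r_mat <- matrix(r_lookup[match(pair_target, uniq)], n, n)

  with_seed(seed, {
    sym_noise <- function() {
      z <- matrix(0, n, n)
      z[upper.tri(z)] <- stats::rnorm(n * (n - 1) / 2)
      z + t(z)
    }
    S_lat <- sym_noise()
    sc <- ifelse(S_lat > stats::qnorm(p0), exp(0.6 * S_lat), 0)
    diag(sc) <- 0
    fc_list <- lapply(seq_len(n_fc), function(j) {
      E <- sym_noise()
      F_lat <- r_mat * S_lat + sqrt(pmax(0, 1 - r_mat^2)) * E
      fc <- tanh(F_lat / 2)
      diag(fc) <- 1
      connectome(fc, "FC", subject_id, j)
    })
    list(sc = connectome(sc, "SC", subject_id, 1L), fc = fc_list)
  })
}

#' Write a complete synthetic study to disk
#'
#' Generates and writes everything a pipeline run needs: parcellation,
#' pedigree, cohort covariates, one SC and `n_fc` FC matrices per subject
#' (filenames `{subject}_{modality}_{measurement}.txt`), and a
#' ground-truth JSON with the generating parameters.
#'
#' @param out_dir Output directory (created if needed).
#' @param parcellation Parcellation to use.
#' @param composition Family composition for the pedigree.
#' @param truth [true_variances()] ground truth (recorded in the JSON and
#'   used for the simulated trait table).
#' @param target_coupling,sc_density Passed to
#'   [simulate_connectome_pair()].
#' @param n_fc FC measurements per subject.
#' @param seed Integer master seed; per-subject seeds are derived from
#'   it.
#' @return Invisibly, the output directory.
#' @export
simulate_study <- function(out_dir,
                           parcellation = default_parcellation(50L),
                           composition = family_composition(10, 10, 20, 10),
                           truth = true_variances(0.4, 0.2, 0.4, 0.25),
                           target_coupling = 0.25, sc_density = 0.3,
                           n_fc = 4L, seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pedigree <- generate_pedigree(composition, seed = seed)
  cohort <- generate_covariates(pedigree, seed = seed + 1L)
  write_table(parcellation, file.path(out_dir, "parcellation.tsv"))
  write_table(pedigree, file.path(out_dir, "pedigree.tsv"))
  write_table(cohort, file.path(out_dir, "cohort.tsv"))
  mat_dir <- file.path(out_dir, "connectomes")
  dir.create(mat_dir, showWarnings = FALSE)
  for (i in seq_len(nrow(pedigree))) {
    sid <- pedigree$subject_id[i]
    pair <- simulate_connectome_pair(parcellation, target_coupling,
                                     sc_density, n_fc = n_fc,
                                     seed = (seed * 131071L + i) %% 2147483647L,
                                     subject_id = sid)
    write_connectome(pair$sc, file.path(mat_dir,
                                        sprintf("%s_SC_1.txt", sid)))
    for (j in seq_len(n_fc)) {
      write_connectome(pair$fc[[j]],
                       file.path(mat_dir, sprintf("%s_FC_%d.txt", sid, j)))
    }
  }
  jsonlite::write_json(list(
    seed = seed, n_subjects = nrow(pedigree),
    n_regions = nrow(parcellation),
    composition = unclass(composition),
    truth = list(sigma2_A = truth$sigma2_A, sigma2_C = truth$sigma2_C,
                 sigma2_E = truth$sigma2_E, sigma2_M = truth$sigma2_M),
    target_coupling = target_coupling, sc_density = sc_density,
    n_fc = n_fc
  ), file.path(out_dir, "ground_truth.json"), auto_unbox = TRUE,
  digits = NA)
  invisible(out_dir)
}
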