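# Independent oracles and fixture builders. These deliberately avoid the
# package's computation paths: correlations from explicit sum formulas on
# average ranks, restricted likelihood from the dense covariance assembly.

# average ranks, then Pearson by the raw sum formula
oracle_spearman <- function(x, y) {
  rx <- rank(x)
  ry <- rank(y)
  n <- length(x)
  num <- sum(rx * ry) - n * mean(rx) * mean(ry)
  den <- sqrt((sum(rx^2) - n * mean(rx)^2) * (sum(ry^2) - n * mean(ry)^2))
  num / den
}

# partial correlation of ranks given a covariate, via explicit pairwise
# correlations (not residualization)
oracle_partial_spearman <- function(x, y, d) {
  rxy <- oracle_spearman(x, y)
  rxd <- oracle_spearman(x, d)
  ryd <- oracle_spearman(y, d)
  (rxy - rxd * ryd) / sqrt((1 - rxd^2) * (1 - ryd^2))
}

# per-region coupling by brute-force partner enumeration
oracle_coupling <- function(sc, fc, partner_fun) {
  n <- nrow(sc)
  vapply(seq_len(n), function(i) {
    idx <- partner_fun(i)
    if (length(idx) < 3L) return(NA_real_)
    x <- sc[i, idx]
    y <- fc[i, idx]
    if (length(unique(x)) < 2L || length(unique(y)) < 2L) return(NA_real_)
    oracle_spearman(x, y)
  }, numeric(1))
}

# random symmetric SC/FC pair on n regions (no copula machinery)
random_connectome_pair <- function(n, sparse = TRUE) {
  sym <- function(m) (m + t(m)) / 2
  sc <- sym(matrix(stats::rexp(n * n), n, n))
  if (sparse) {
    mask <- sym(matrix(stats::runif(n * n), n, n)) < 0.4
    sc[mask] <- 0
  }
  diag(sc) <- 0
  fc <- sym(matrix(stats::runif(n * n, -1, 1), n, n))
  diag(fc) <- 1
  list(sc = connectome(sc, "SC"), fc = connectome(fc, "FC"))
}

# dense restricted log-likelihood from the explicit covariance assembly
dense_reml_loglik <- function(v, y, X, K, Lambda, T_mat) {
  n <- length(y)
  p <- ncol(X)
  V <- v[1] * T_mat %*% K %*% t(T_mat) +
    v[2] * T_mat %*% Lambda %*% t(T_mat) +
    v[3] * T_mat %*% t(T_mat) + v[4] * diag(n)
  Vi <- solve(V)
  XtVX <- t(X) %*% Vi %*% X
  b <- solve(XtVX, t(X) %*% Vi %*% y)
  r <- y - X %*% b
  -0.5 * as.numeric((n - p) * log(2 * pi) +
                      determinant(V)$modulus +
                      determinant(XtVX)$modulus + t(r) %*% Vi %*% r)
}

# thorough direct maximization of the dense restricted likelihood
dense_reml_fit <- function(y, X, K, Lambda, T_mat) {
  nll <- function(lp) -dense_reml_loglik(exp(lp), y, X, K, Lambda, T_mat)
  vtot <- stats::var(y)
  best <- NULL
  for (s in list(rep(vtot / 4, 4), vtot * c(0.7, 0.1, 0.1, 0.1),
                 vtot * c(0.1, 0.1, 0.1, 0.7))) {
    o <- stats::optim(log(s), nll, method = "Nelder-Mead",
                      control = list(maxit = 10000, reltol = 1e-15))
    for (k in 1:3) {
      o <- stats::optim(o$par, nll, method = "Nelder-Mead",
                        control = list(maxit = 10000, reltol = 1e-15))
    }
    if (is.null(best) || o$value < best$value) best <- o
  }
  list(sigma2 = exp(best$par), loglik = -best$value)
}

# minimal parcellation data frame for fixtures below the packaged
# scheme's size floor
toy_parcellation <- function(n, networks = NULL) {
  set.seed(n + 1000)
  data.frame(
    region_id = seq_len(n) - 1L,
    label = sprintf("R%02d", seq_len(n)),
    hemisphere = rep_len(c("left", "right"), n),
    network = if (is.null(networks)) rep_len(c("VIS", "DMN", "SUB"), n)
              else networks,
    x = runif(n, -70, 70), y = runif(n, -100, 70), z = runif(n, -50, 80),
    stringsAsFactors = FALSE)
}

# numerically stabilized normal equations (column equilibration); the
# algebra is still (X'X)^{-1} X'y
oracle_normal_equations <- function(X, Y) {
  d <- 1 / sqrt(colSums(X^2))
  Xs <- sweep(X, 2, d, "*")
  B <- diag(d) %*% solve(t(Xs) %*% Xs) %*% t(Xs) %*% Y
  rownames(B) <- colnames(X)
  B
}

# small pedigree used across heritability tests
tiny_pedigree <- function() {
  generate_pedigree(family_composition(2, 1, 0, 2), seed = 5)
}

# subject-level pair means for intraclass checks
pair_member_means <- function(phen, ped) {
  agg <- stats::aggregate(phen[[3]], list(subject_id = phen$subject_id),
                          mean)
  agg <- agg[match(ped$subject_id, agg$subject_id), ]
  matrix(agg$x, ncol = 2, byrow = TRUE)
}
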