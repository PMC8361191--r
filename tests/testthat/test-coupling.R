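test_that("functional connectivity matches the correlation definition", {
  set.seed(1)
  ts <- matrix(rnorm(15), 5, 3)
  fc <- functional_connectivity(ts)
  # direct covariance-normalization oracle
  ctr <- scale(ts, scale = FALSE)
  oracle <- crossprod(ctr) / sqrt(outer(colSums(ctr^2), colSums(ctr^2)))
  expect_equal(unclass(fc), oracle, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(diag(fc), rep(1, 3))

  ts2 <- cbind(ts[, 1], ts[, 1], -ts[, 1] + 0)
  fc2 <- functional_connectivity(ts2)
  expect_equal(fc2[1, 2], 1)
  expect_equal(fc2[1, 3], -1)

  ts3 <- ts
  ts3[, 2] <- 5
  colnames(ts3) <- c("a", "flat", "c")
  expect_error(functional_connectivity(ts3), "flat")
})

test_that("whole-brain coupling is Spearman with average ranks", {
  # hand example: ranks (3,1,4,2) vs (2,1,4,3), sum d^2 = 2, n = 4
  sc <- matrix(0, 5, 5)
  sc[1, 2:5] <- c(0.3, 0.1, 0.4, 0.2)
  fc <- matrix(0, 5, 5)
  fc[1, 2:5] <- c(0.2, 0.1, 0.4, 0.3)
  sc <- sc + t(sc)
  fc <- fc + t(fc)
  diag(fc) <- 1
  cp <- regional_coupling(connectome(sc, "SC"), connectome(fc, "FC"))
  expect_equal(cp$value[1], 1 - 6 * 2 / (4 * (4^2 - 1)))

  # monotone invariance: strictly increasing transform gives rho = 1
  set.seed(2)
  p <- random_connectome_pair(8, sparse = FALSE)
  fc_mono <- tanh(unclass(p$sc))
  diag(fc_mono) <- 1
  cp1 <- regional_coupling(p$sc, connectome(fc_mono, "FC"))
  expect_equal(cp1$value, rep(1, 8))
  # rank reversal gives -1
  fc_rev <- tanh(-unclass(p$sc))
  diag(fc_rev) <- 1
  cp2 <- regional_coupling(p$sc, connectome(fc_rev, "FC"))
  expect_equal(cp2$value, rep(-1, 8))
})

test_that("degenerate all-tied SC rows are flagged undefined", {
  sc <- matrix(0, 6, 6)
  sc[2, 3] <- sc[3, 2] <- 1   # region 1 row is all zeros
  set.seed(3)
  fc <- random_connectome_pair(6)$fc
  cp <- regional_coupling(connectome(sc, "SC"), fc)
  expect_true(is.na(cp$value[1]))
  expect_false(is.na(cp$value[2]))
})

test_that("every variant matches the brute-force oracle on random fixtures", {
  set.seed(42)
  parc <- default_parcellation(12)
  net <- parc$network
  hemi <- parc$hemisphere
  for (rep in 1:20) {
    p <- random_connectome_pair(12)
    sc <- p$sc
    fc <- p$fc

    expect_equal(regional_coupling(sc, fc)$value,
                 oracle_coupling(sc, fc, function(i) setdiff(1:12, i)),
                 tolerance = 1e-10)
    expect_equal(network_coupling(sc, fc, parc, "within")$value,
                 oracle_coupling(sc, fc, function(i)
                   setdiff(which(net == net[i]), i)),
                 tolerance = 1e-10)
    expect_equal(network_coupling(sc, fc, parc, "between")$value,
                 oracle_coupling(sc, fc, function(i)
                   setdiff(which(net != net[i]), i)),
                 tolerance = 1e-10)
    expect_equal(intra_hemisphere_coupling(sc, fc, parc)$value,
                 oracle_coupling(sc, fc, function(i)
                   setdiff(which(hemi == hemi[i]), i)),
                 tolerance = 1e-10)

    pd <- partial_coupling_distance(sc, fc, parc)$value
    d_mat <- as.matrix(dist(as.matrix(parc[, c("x", "y", "z")])))
    pd_oracle <- vapply(1:12, function(i) {
      idx <- setdiff(1:12, i)
      oracle_partial_spearman(sc[i, idx], fc[i, idx], d_mat[i, idx])
    }, numeric(1))
    expect_equal(pd, pd_oracle, tolerance = 1e-10)
  }
})

test_that("network restriction degenerates correctly", {
  set.seed(7)
  p <- random_connectome_pair(8)
  # all regions in one network: within == whole brain
  parc_one <- toy_parcellation(8, networks = rep("VIS", 8))
  expect_equal(network_coupling(p$sc, p$fc, parc_one, "within")$value,
               regional_coupling(p$sc, p$fc)$value)
  # a region alone in its network is undefined
  parc_solo <- parc_one
  parc_solo$network[3] <- "LIM"
  w <- network_coupling(p$sc, p$fc, parc_solo, "within")
  expect_true(is.na(w$value[3]))
  expect_equal(w$n_pairs[3], 0L)
})

test_that("a constant distance covariate reduces to plain Spearman", {
  set.seed(8)
  p <- random_connectome_pair(9)
  parc <- toy_parcellation(9)
  parc$x <- parc$y <- parc$z <- 1  # all centroids identical
  expect_warning(
    pd <- partial_coupling_distance(p$sc, p$fc, parc),
    "constant")
  expect_equal(pd$value, regional_coupling(p$sc, p$fc)$value,
               tolerance = 1e-12)
})

test_that("node strength follows the row-sum definitions", {
  m <- matrix(0, 4, 4)
  m[1, 2:4] <- c(1, 2, 3)
  m <- m + t(m)
  expect_equal(node_strength(connectome(m, "SC"))[1], 6)

  f <- diag(4)
  f[1, 2] <- f[2, 1] <- -0.5
  f[1, 3] <- f[3, 1] <- 0.5
  expect_equal(node_strength(connectome(f, "FC"))[1], 1.0)

  set.seed(9)
  p <- random_connectome_pair(10)
  loop_sc <- vapply(1:10, function(i) sum(p$sc[i, -i]), numeric(1))
  loop_fc <- vapply(1:10, function(i) sum(abs(p$fc[i, -i])), numeric(1))
  expect_equal(node_strength(p$sc), loop_sc, tolerance = 1e-12)
  expect_equal(node_strength(p$fc), loop_fc, tolerance = 1e-12)
})

test_that("Fisher z is atanh with domain checking", {
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(0.5), atanh(0.5))
  expect_equal(round(fisher_z(0.5), 4), 0.5493)
  expect_equal(fisher_z(-0.7), -fisher_z(0.7))
  expect_error(fisher_z(1), "rho")
  expect_true(is.na(fisher_z(c(0.1, NA))[2]))
})

test_that("realized coupling tracks the target across seeds", {
  parc <- default_parcellation(392)
  vals <- vapply(1:20, function(s) {
    p <- simulate_connectome_pair(parc, 0.30, sc_density = 0.3, seed = s)
    mean(regional_coupling(p$sc, p$fc[[1]])$value, na.rm = TRUE)
  }, numeric(1))
  expect_lt(abs(mean(vals) - 0.30), 0.02)
})

test_that("FC averaging is entrywise on the correlation scale", {
  set.seed(10)
  a <- random_connectome_pair(6)$fc
  b <- random_connectome_pair(6)$fc
  avg <- average_fc(list(a, b))
  expect_equal(unclass(avg), (unclass(a) + unclass(b)) / 2,
               ignore_attr = TRUE)
})
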