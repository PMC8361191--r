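#' Bland-Altman agreement between two paired regional maps
#'
#' Quantifies agreement between two measurements of the same regional
#' quantity (e.g. group-mean coupling at test and retest, one point per
#' region). The bias is the mean paired difference, and the limits of
#' agreement are the 95% prediction interval for a new difference,
#' `bias +/- 1.96 * S_d`, with `S_d` the sample standard deviation of the
#' differences (n - 1 denominator).
#'
#' Differences are taken as `b - a` (second minus first: retest minus
#' test, replication minus original); flip the arguments for the opposite
#' convention.
#'
#' @param a,b Equal-length numeric vectors of paired values (length >= 2).
#' @return An object of class `"scfc_bland_altman"`: list with
#'   `bias` (mean difference), `sd_diff`, `loa_lower`, `loa_upper`, `n`,
#'   and the paired `means`/`differences` for plotting.
#' @export
bland_altman <- function(a, b) {
  if (length(a) != length(b)) stop_scfc("'a' and 'b' differ in length")
  keep <- stats::complete.cases(a, b)
  a <- a[keep]
  b <- b[keep]
  n <- length(a)
  if (n < 2L) stop_scfc("need at least 2 complete pairs")
  d <- b - a
  bias <- mean(d)
  sd_diff <- stats::sd(d)
  structure(list(
    bias = bias, sd_diff = sd_diff,
    loa_lower = bias - 1.96 * sd_diff,
    loa_upper = bias + 1.96 * sd_diff,
    n = n, means = (a + b) / 2, differences = d
  ), class = "scfc_bland_altman")
}

#' @export
print.scfc_bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman agreement over %d pairs\n", x$n))
  cat(sprintf("  bias (mean difference) = %.4f\n", x$bias))
  cat(sprintf("  SD of differences      = %.4f\n", x$sd_diff))
  cat(sprintf("  limits of agreement    = [%.4f, %.4f]\n",
              x$loa_lower, x$loa_upper))
  invisible(x)
}

#' @export
plot.scfc_bland_altman <- function(x, ...) {
  graphics::plot(x$means, x$differences,
                 xlab = "Mean of pair", ylab = "Difference (b - a)",
                 pch = 16, col = grDevices::grey(0.3, 0.6), ...)
  graphics::abline(h = x$bias, lty = 1)
  graphics::abline(h = c(x$loa_lower, x$loa_upper), lty = 2)
  invisible(x)
}

#' Agreement correlation with permutation p-value
#'
#' Pearson correlation between two paired regional maps (test vs retest,
#' or original vs out-of-sample group means), with a one-sided permutation
#' p-value obtained by shuffling the region pairing.
#'
#' @param a,b Equal-length numeric vectors (length >= 3).
#' @param n_perm Number of permutations.
#' @param seed Integer seed for the permutation stream.
#' @return List with `r` (Pearson correlation) and `p` (one-sided
#'   permutation p-value for positive association,
#'   `(1 + #{null >= observed}) / (1 + n_perm)`).
#' @export
agreement_correlation <- function(a, b, n_perm = 10000L, seed = 1L) {
  if (length(a) != length(b)) stop_scfc("'a' and 'b' differ in length")
  keep <- stats::complete.cases(a, b)
  a <- a[keep]
  b <- b[keep]
  if (length(a) < 3L) stop_scfc("need at least 3 complete pairs")
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop_scfc("constant input; correlation undefined")
  }
  r <- stats::cor(a, b)
  null_r <- with_seed(seed, {
    vapply(seq_len(n_perm), function(k) stats::cor(a, sample(b)), numeric(1))
  })
  p <- (1 + sum(null_r >= r)) / (1 + n_perm)
  list(r = r, p = p, n_perm = as.integer(n_perm))
}
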