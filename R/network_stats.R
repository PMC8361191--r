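#' @noRd
network_levels <- function(parcellation) {
  intersect(NETWORK_LABELS, unique(parcellation$network))
}

#' Per-network distribution summary of a regional map
#'
#' Median, quartiles (midpoint interpolation), mean and SD of a regional
#' quantity within each network. Undefined regional values are excluded
#' and counted.
#'
#' @param values Numeric vector aligned to the parcellation (one value
#'   per region; `NA` = undefined).
#' @param parcellation The parcellation supplying network labels.
#' @return Data frame with one row per network: `network`, `n_regions`,
#'   `n_excluded`, `median`, `q1`, `q3`, `mean`, `sd`, `empty`.
#' @export
network_summary <- function(values, parcellation) {
  if (length(values) != nrow(parcellation)) {
    stop_scfc("values and parcellation differ in length")
  }
  nets <- network_levels(parcellation)
  out <- lapply(nets, function(nw) {
    v <- values[parcellation$network == nw]
    n_all <- length(v)
    v <- v[!is.na(v)]
    if (!length(v)) {
      return(data.frame(network = nw, n_regions = n_all,
                        n_excluded = n_all, median = NA_real_,
                        q1 = NA_real_, q3 = NA_real_, mean = NA_real_,
                        sd = NA_real_, empty = TRUE,
                        stringsAsFactors = FALSE))
    }
    q <- quantile_midpoint(v, c(0.25, 0.5, 0.75))
    data.frame(network = nw, n_regions = n_all,
               n_excluded = n_all - length(v), median = q[2],
               q1 = q[1], q3 = q[3], mean = mean(v), sd = stats::sd(v),
               empty = FALSE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

# t matrix over all ordered network pairs for one regional map;
# vectorized so the permutation null is cheap
#' @noRd
net_t_matrix <- function(values, labels, nets, welch = FALSE) {
  keep <- !is.na(values)
  v <- values[keep]
  f <- factor(labels[keep], levels = nets)
  n <- tabulate(f, nbins = length(nets))
  s <- as.vector(rowsum(v, f))
  ss <- as.vector(rowsum(v^2, f))
  m <- s / n
  var_g <- (ss - n * m^2) / (n - 1)
  dm <- outer(m, m, "-")
  if (welch) {
    se <- sqrt(outer(var_g / n, var_g / n, "+"))
  } else {
    sp2 <- outer((n - 1) * var_g, (n - 1) * var_g, "+") /
      (outer(n, n, "+") - 2)
    se <- sqrt(sp2 * outer(1 / n, 1 / n, "+"))
  }
  t_mat <- dm / se
  t_mat[n < 2, ] <- NA_real_
  t_mat[, n < 2] <- NA_real_
  diag(t_mat) <- NA_real_
  dimnames(t_mat) <- list(nets, nets)
  t_mat
}

#' Pairwise network contrasts of a regional map
#'
#' Unpaired two-sample t-statistics comparing the regional values of
#' every ordered pair of networks (row network minus column network;
#' the matrix is antisymmetric). Pooled-variance t by default; Welch
#' with `welch = TRUE`.
#'
#' @inheritParams network_summary
#' @param welch Use Welch's unequal-variance t instead of pooled.
#' @return A square t-statistic matrix with network dimnames; rows and
#'   columns of singleton (or empty) networks are `NA`, as is the
#'   diagonal.
#' @export
pairwise_network_t <- function(values, parcellation, welch = FALSE) {
  if (length(values) != nrow(parcellation)) {
    stop_scfc("values and parcellation differ in length")
  }
  nets <- network_levels(parcellation)
  net_t_matrix(values, parcellation$network, nets, welch)
}

#' Permutation p-values for pairwise network contrasts
#'
#' One-sided p-values for the [pairwise_network_t()] matrix under a null
#' built by shuffling the region-to-network assignment:
#' `p = (1 + #(null t >= observed t)) / (1 + n_perm)`. A hook accepts
#' externally generated surrogate regional maps (e.g. spatially
#' autocorrelated nulls) in place of label permutation; plain label
#' permutation is anti-conservative when the map is spatially
#' autocorrelated. q-values are Benjamini-Hochberg over all off-diagonal
#' contrasts.
#'
#' @inheritParams pairwise_network_t
#' @param n_perm Number of permutations (>= 100).
#' @param seed Integer seed.
#' @param surrogates Optional matrix of surrogate maps (regions by
#'   surrogate draws); replaces label permutation.
#' @return List with matrices `t`, `p`, `q`.
#' @export
permutation_p_t <- function(values, parcellation, n_perm = 1000L,
                            seed = 1L, welch = FALSE, surrogates = NULL) {
  if (is.null(surrogates) && n_perm < 100L) {
    stop_scfc("n_perm must be >= 100")
  }
  nets <- network_levels(parcellation)
  labels <- parcellation$network
  obs <- net_t_matrix(values, labels, nets, welch)
  count <- matrix(0L, nrow(obs), ncol(obs))
  if (is.null(surrogates)) {
    with_seed(seed, {
      for (b in seq_len(n_perm)) {
        null_t <- net_t_matrix(values, sample(labels), nets, welch)
        count <- count + (!is.na(null_t) & !is.na(obs) & null_t >= obs)
      }
    })
    n_draws <- n_perm
  } else {
    if (nrow(surrogates) != length(values)) {
      stop_scfc("surrogate maps must have one row per region")
    }
    for (b in seq_len(ncol(surrogates))) {
      null_t <- net_t_matrix(surrogates[, b], labels, nets, welch)
      count <- count + (!is.na(null_t) & !is.na(obs) & null_t >= obs)
    }
    n_draws <- ncol(surrogates)
  }
  p <- (1 + count) / (1 + n_draws)
  p[is.na(obs)] <- NA_real_
  off <- !is.na(p)
  q <- p
  q[off] <- stats::p.adjust(p[off], method = "BH")
  dimnames(p) <- dimnames(q) <- dimnames(obs)
  list(t = obs, p = p, q = q, n_perm = as.integer(n_draws))
}

#' Correlation between two regional maps with permutation p-value
#'
#' Pearson correlation with a one-sided p-value from shuffling the
#' region correspondence (or from externally supplied surrogate maps for
#' the first argument).
#'
#' @param x,y Numeric vectors aligned to the same parcellation.
#' @param n_perm Number of permutations.
#' @param seed Integer seed.
#' @param surrogates Optional matrix (regions by draws) of surrogate
#'   versions of `x`.
#' @return List with `r` and one-sided `p` (positive association).
#' @export
correlation_with_permutation <- function(x, y, n_perm = 10000L, seed = 1L,
                                         surrogates = NULL) {
  keep <- stats::complete.cases(x, y)
  x <- x[keep]
  y <- y[keep]
  if (length(x) < 3L) stop_scfc("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop_scfc("constant vector; correlation undefined")
  }
  r <- stats::cor(x, y)
  if (is.null(surrogates)) {
    null_r <- with_seed(seed, {
      vapply(seq_len(n_perm), function(b) stats::cor(sample(x), y),
             numeric(1))
    })
  } else {
    null_r <- apply(surrogates[keep, , drop = FALSE], 2, stats::cor, y = y)
  }
  list(r = r, p = (1 + sum(null_r >= r)) / (1 + length(null_r)),
       n_perm = as.integer(length(null_r)))
}

#' Violin-style network distribution plot
#'
#' Base-graphics rendering of per-network distributions of a regional
#' map: one kernel-density silhouette per network with the median drawn
#' dashed and the quartiles dotted.
#'
#' @inheritParams network_summary
#' @param main Plot title.
#' @export
plot_network_distributions <- function(values, parcellation, main = "") {
  nets <- network_levels(parcellation)
  graphics::plot(NULL, xlim = c(0.5, length(nets) + 0.5),
                 ylim = range(values, na.rm = TRUE), xaxt = "n",
                 xlab = "", ylab = "value", main = main)
  graphics::axis(1, at = seq_along(nets), labels = nets, las = 2)
  for (i in seq_along(nets)) {
    v <- values[parcellation$network == nets[i]]
    v <- v[!is.na(v)]
    if (length(v) < 2) next
    d <- stats::density(v)
    w <- 0.4 * d$y / max(d$y)
    graphics::polygon(c(i - w, rev(i + w)), c(d$x, rev(d$x)),
                      col = grDevices::grey(0.85), border = grDevices::grey(0.4))
    q <- quantile_midpoint(v, c(0.25, 0.5, 0.75))
    graphics::segments(i - 0.3, q[2], i + 0.3, q[2], lty = 2)
    graphics::segments(i - 0.25, q[c(1, 3)], i + 0.25, q[c(1, 3)], lty = 3)
  }
  invisible(NULL)
}
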