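# pairwise comparison matrix for Hoeffding's bivariate ranks:
# M[i, j] = I(v_j < v_i) + 0.5 * I(v_j == v_i), diagonal included
# (the diagonal contribution is removed analytically downstream)
.hoeff_cmp <- function(v) {
  outer(v, v, function(a, b) (b < a) + 0.5 * (b == a))
}

.hoeff_D_from_ranks <- function(R, S, Q, n) {
  D1 <- sum((Q - 1) * (Q - 2))
  D2 <- sum((R - 1) * (R - 2) * (S - 1) * (S - 2))
  D3 <- sum((R - 2) * (S - 2) * (Q - 1))
  30 * ((n - 2) * (n - 3) * D1 + D2 - 2 * (n - 2) * D3) /
    (n * (n - 1) * (n - 2) * (n - 3) * (n - 4))
}

#' Hoeffding's D test of independence
#'
#' Rank-based test of bivariate independence sensitive to
#' non-monotonic dependence. The statistic uses midranks `R`, `S` and
#' bivariate ranks `Q` (ties weighted 1/2, joint ties 1/4):
#' `D = 30 * ((n-2)(n-3) D1 + D2 - 2(n-2) D3) / (n(n-1)(n-2)(n-3)(n-4))`
#' with `D1 = sum (Q-1)(Q-2)`, `D2 = sum (R-1)(R-2)(S-1)(S-2)`,
#' `D3 = sum (R-2)(S-2)(Q-1)`. The x30 scaling puts the population
#' maximum at 1 (range `[-0.5, 1]`); D is invariant under strictly
#' monotone transforms of either margin.
#'
#' The p-value is computed by a permutation test (shuffling `y`),
#' which is exact in distribution and makes no large-sample
#' approximation.
#'
#' @param x,y numeric vectors, `n >= 5`; ties allowed.
#' @param n_perm number of permutations (default 10000).
#' @param seed permutation seed.
#' @return list of class `hoeffding_d`: `D`, `p_value`, `n`, `n_perm`.
#' @export
hoeffding_d <- function(x, y, n_perm = 10000L, seed = 1L) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  if (n < 5L) stop("Hoeffding's D requires n >= 5")
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]; n <- length(x)
  if (n < 5L) stop("fewer than 5 complete pairs")

  R <- rank(x); S <- rank(y)
  Mx <- .hoeff_cmp(x); My <- .hoeff_cmp(y)
  Q <- 1 + rowSums(Mx * My) - 0.25  # remove the i == j term (0.5 * 0.5)
  D <- .hoeff_D_from_ranks(R, S, Q, n)

  p <- NA_real_
  if (n_perm > 0L) {
    set.seed(as.integer(seed) %% .Machine$integer.max)
    hits <- 0L
    for (b in seq_len(n_perm)) {
      pm <- sample.int(n)
      Qp <- 1 + rowSums(Mx * My[pm, pm]) - 0.25
      Dp <- .hoeff_D_from_ranks(R, S[pm], Qp, n)
      if (Dp >= D - 1e-12) hits <- hits + 1L
    }
    p <- (hits + 1) / (n_perm + 1)
  }
  structure(list(D = D, p_value = p, n = n, n_perm = as.integer(n_perm)),
            class = "hoeffding_d")
}

#' @export
print.hoeffding_d <- function(x, ...) {
  cat(sprintf("Hoeffding's D = %.4g, permutation P = %.4g (n = %d, %d permutations)\n",
              x$D, x$p_value, x$n, x$n_perm))
  invisible(x)
}

#' Spearman and Pearson correlation tests
#'
#' Both coefficients with t-approximation p-values (`t = c *
#' sqrt((n-2)/(1-c^2))` on `n - 2` df); Spearman uses midranks, so
#' ties are handled.
#'
#' @param x,y numeric vectors, `n >= 3`, each with nonzero variance.
#' @return list with `spearman_rho`, `spearman_p`, `pearson_r`,
#'   `pearson_p`, `n`.
#' @export
correlation_tests <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  if (n < 3L) stop("need at least 3 observations")
  if (var(x) == 0 || var(y) == 0) stop("zero variance in x or y")
  tp <- function(cc) {
    if (abs(cc) >= 1) return(0)
    tt <- cc * sqrt((n - 2) / (1 - cc^2))
    2 * pt(-abs(tt), df = n - 2)
  }
  rho <- cor(rank(x), rank(y))
  r <- cor(x, y)
  list(spearman_rho = rho, spearman_p = tp(rho),
       pearson_r = r, pearson_p = tp(r), n = n)
}
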