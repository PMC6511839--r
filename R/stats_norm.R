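#' TMM scaling factors
#'
#' Trimmed mean of M-values normalisation between samples: for each
#' sample against a reference column, gene-wise log ratios `M` and
#' average log abundances `A` are computed on library-size-scaled
#' counts, genes are double-trimmed (30% each side on `M`, 5% each
#' side on `A` by default), and the scaling factor is `2^` the
#' precision-weighted mean of the remaining `M` values (inverse
#' asymptotic binomial variance weights). Factors are rescaled so their
#' geometric mean is 1.
#'
#' @param x a `umi_counts` object or genes x samples count matrix (>= 2
#'   samples; all-zero samples are an error).
#' @param ref_sample `"auto"` (column whose 75th count-fraction
#'   percentile is closest to the mean, the usual heuristic) or a
#'   sample name / column index.
#' @param logratio_trim,sum_trim two-sided trim fractions for `M` and
#'   `A`.
#' @param min_count genes must have at least this count in both the
#'   sample and the reference to enter the trimmed mean (default 1).
#' @return named numeric vector of scaling factors, geometric mean 1.
#' @export
tmm_factors <- function(x, ref_sample = "auto", logratio_trim = 0.3,
                        sum_trim = 0.05, min_count = 1L) {
  m <- .counts_of(x)
  if (ncol(m) < 2L) stop("TMM needs at least 2 samples")
  lib <- colSums(m)
  if (any(lib == 0)) stop("degenerate sample with all-zero counts")
  if (identical(ref_sample, "auto")) {
    f75 <- apply(m, 2L, function(v) quantile(v / sum(v), 0.75, names = FALSE))
    ref <- which.min(abs(f75 - mean(f75)))
  } else {
    ref <- if (is.character(ref_sample)) match(ref_sample, colnames(m)) else as.integer(ref_sample)
    if (is.na(ref) || ref < 1L || ref > ncol(m)) stop("unknown reference sample")
  }
  yr <- m[, ref]; nr <- lib[ref]
  f <- vapply(seq_len(ncol(m)), function(k) {
    yo <- m[, k]; no <- lib[k]
    keep <- yo >= min_count & yr >= min_count
    yo <- yo[keep]; yk <- yr[keep]
    logR <- log2((yo / no) / (yk / nr))
    absE <- (log2(yo / no) + log2(yk / nr)) / 2
    v <- (no - yo) / (no * yo) + (nr - yk) / (nr * yk)
    fin <- is.finite(logR) & is.finite(absE) & absE > -1e10
    logR <- logR[fin]; absE <- absE[fin]; v <- v[fin]
    if (length(logR) == 0L || max(abs(logR)) < 1e-6) return(1)
    n <- length(logR)
    loL <- floor(n * logratio_trim) + 1; hiL <- n + 1 - loL
    loS <- floor(n * sum_trim) + 1; hiS <- n + 1 - loS
    keep2 <- rank(logR) >= loL & rank(logR) <= hiL &
             rank(absE) >= loS & rank(absE) <= hiS
    f <- 2^(sum(logR[keep2] / v[keep2], na.rm = TRUE) /
            sum(1 / v[keep2], na.rm = TRUE))
    if (!is.finite(f) || f <= 0) 1 else f
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  setNames(f, colnames(m))
}

# conditional two-sided exact NB p-value for group sums (a, b) given
# group sizes (na, nb) and common dispersion phi; conditioning on the
# total makes the distribution free of the mean:
#   P(Y_A = y | Y_A + Y_B = s) ~ NegHypergeom(r_A = na/phi, r_B = nb/phi)
# phi = 0 degenerates to Binomial(s, na/(na+nb)).
exact_nb_pvalue <- function(a, b, na, nb, phi) {
  s <- a + b
  if (s == 0) return(1)
  y <- 0:s
  if (phi > 0) {
    rA <- na / phi; rB <- nb / phi
    lw <- lgamma(y + rA) - lgamma(y + 1) +
          lgamma(s - y + rB) - lgamma(s - y + 1)
    lw <- lw - max(lw)
    p <- exp(lw); p <- p / sum(p)
  } else {
    p <- stats::dbinom(y, s, na / (na + nb))
  }
  pobs <- p[a + 1L]
  # minimum-likelihood two-sided p: all outcomes no more probable than
  # the observed one, tie mass included (small relative tolerance)
  min(1, sum(p[p <= pobs * (1 + 1e-10)]))
}

#' Exact negative-binomial two-group test (common dispersion)
#'
#' Gene-wise conditional exact test of equal means between two groups
#' of count libraries under a negative binomial model with a common,
#' user-supplied dispersion `phi`. Counts are first brought to equal
#' effective library sizes by moment matching (each sample scaled by
#' the ratio of the geometric-mean effective size to its own and the
#' group sums rounded). Conditioning on a gene's total count makes the
#' null distribution of the group-A sum parameter-free (a negative
#' hypergeometric; binomial when `phi = 0`), and the two-sided p-value
#' sums all outcomes with probability not exceeding the observed one.
#'
#' Dispersion estimation is intentionally out of scope: the test takes
#' a fixed common dispersion (default 0.1), a deliberate
#' simplification relative to full empirical-Bayes machinery.
#'
#' @param x a `umi_counts` object or genes x samples count matrix.
#' @param groups factor (or coercible) of length `ncol`, two levels.
#' @param dispersion common NB dispersion `phi >= 0`.
#' @param factors optional normalisation factors (e.g. from
#'   [tmm_factors()] or [ideges_normalize()]); default all 1.
#' @param lib_sizes optional library sizes (default column sums).
#' @return numeric vector of two-sided p-values, one per gene
#'   (all-zero genes get 1).
#' @export
nb_exact_test <- function(x, groups, dispersion = 0.1, factors = NULL,
                          lib_sizes = NULL) {
  m <- .counts_of(x)
  groups <- as.factor(groups)
  if (nlevels(groups) != 2L) stop("exactly two groups required")
  if (length(groups) != ncol(m)) stop("groups length must match samples")
  if (dispersion < 0) stop("dispersion must be >= 0")
  if (is.null(lib_sizes)) lib_sizes <- colSums(m)
  if (is.null(factors)) factors <- rep(1, ncol(m))
  eff <- lib_sizes * factors
  scale <- exp(mean(log(eff))) / eff
  sm <- sweep(m, 2L, scale, "*")
  ga <- groups == levels(groups)[1L]
  a <- round(rowSums(sm[, ga, drop = FALSE]))
  b <- round(rowSums(sm[, !ga, drop = FALSE]))
  na <- sum(ga); nb <- sum(!ga)
  vapply(seq_along(a), function(i) exact_nb_pvalue(a[i], b[i], na, nb, dispersion),
         numeric(1))
}

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR adjustment with monotonicity enforcement,
#' `q_(i) = min_{j >= i} p_(j) * m / j`.
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @return q-values in the input order.
#' @export
bh_fdr <- function(p_values) {
  if (any(!is.na(p_values) & (p_values < 0 | p_values > 1)))
    stop("p-values must lie in [0, 1]")
  p.adjust(p_values, method = "BH")
}

#' Iterative DEG-exclusion normalisation (iDEGES-style)
#'
#' Scaling normalisation that alternates between TMM factor estimation
#' and putative-DEG exclusion, de-biasing the factors when differential
#' expression is asymmetric between groups. Each iteration (default 3)
#' runs the exact NB test with the current factors, marks putative DEGs
#' at `q < fdr_inner` (default 0.1) — or, if fewer than `floor_pdeg`
#' (default 5%) of genes reach that threshold, the top `floor_pdeg`
#' fraction by p-value — and recomputes TMM factors on the remaining
#' genes. Final factors are rescaled from the reduced gene set to the
#' full library sizes and to geometric mean 1.
#'
#' With `iterations = 0` the result is exactly plain [tmm_factors()].
#'
#' @param x a `umi_counts` object or count matrix.
#' @param groups two-level factor over samples.
#' @param iterations number of exclusion iterations (default 3).
#' @param fdr_inner inner FDR threshold for putative DEGs (default 0.1).
#' @param floor_pdeg minimum excluded fraction (default 0.05).
#' @param dispersion common dispersion for the inner test.
#' @param ... passed to [tmm_factors()].
#' @return list of class `norm_result`: `factors` (geometric mean 1),
#'   `iterations`, `excluded` (list of per-iteration excluded gene id
#'   sets), `fdr_inner`, `floor_pdeg`, `dispersion`.
#' @export
ideges_normalize <- function(x, groups, iterations = 3L, fdr_inner = 0.1,
                             floor_pdeg = 0.05, dispersion = 0.1, ...) {
  m <- .counts_of(x)
  groups <- as.factor(groups)
  if (nlevels(groups) != 2L) stop("exactly two groups required")
  lib <- colSums(m)
  factors <- tmm_factors(m, ...)
  excluded <- list()
  for (it in seq_len(iterations)) {
    p <- nb_exact_test(m, groups, dispersion = dispersion,
                       factors = factors, lib_sizes = lib)
    q <- bh_fdr(p)
    deg <- which(q < fdr_inner)
    floor_n <- ceiling(floor_pdeg * nrow(m))
    if (length(deg) < floor_n)
      deg <- order(p)[seq_len(floor_n)]
    excluded[[it]] <- rownames(m)[deg]
    sub <- m[-deg, , drop = FALSE]
    f_sub <- tmm_factors(sub, ...)
    # factors estimated on the reduced set, expressed against the full
    # library sizes, then recentred
    factors <- f_sub * colSums(sub) / lib
    factors <- factors / exp(mean(log(factors)))
  }
  structure(list(factors = setNames(factors, colnames(m)),
                 iterations = as.integer(iterations),
                 excluded = excluded, fdr_inner = fdr_inner,
                 floor_pdeg = floor_pdeg, dispersion = dispersion),
            class = "norm_result")
}

#' @export
print.norm_result <- function(x, ...) {
  cat(sprintf("norm_result: %d iteration(s), inner FDR %g, floorPDEG %g\n",
              x$iterations, x$fdr_inner, x$floor_pdeg))
  print(round(x$factors, 4))
  invisible(x)
}

#' Call differentially expressed genes
#'
#' Runs the exact NB test with the supplied (or freshly computed
#' iDEGES) normalisation factors, adjusts p-values by
#' Benjamini-Hochberg, and calls DEGs at `q < fdr` (default 0.01).
#' Per gene it reports the m-value (log2 fold change of the second
#' group over the first, on normalised means with a 0.5 pseudocount),
#' the a-value (mean log2 expression), p, q, and a deterministic
#' significance rank ordered by (q, p, |m| descending), ties broken by
#' gene id. All-zero genes are excluded from testing and reported `NA`.
#'
#' @param x a `umi_counts` object or count matrix.
#' @param groups two-level factor; the first level is the baseline, so
#'   `m_value > 0` means higher expression in the second level.
#' @param norm optional `norm_result` from [ideges_normalize()];
#'   computed with defaults when `NULL`.
#' @param fdr DEG threshold on q (default 0.01).
#' @param dispersion common dispersion (taken from `norm` when
#'   available).
#' @return `data.frame` of class `de_result` with columns `gene_id`,
#'   `m_value`, `a_value`, `p_value`, `q_value`, `rank`, `deg`;
#'   `attr(, "n_deg")` holds `n_total`, and the per-direction counts
#'   `n_up_<level>` for both group levels.
#' @export
call_degs <- function(x, groups, norm = NULL, fdr = 0.01, dispersion = NULL) {
  m <- .counts_of(x)
  groups <- as.factor(groups)
  if (is.null(norm)) norm <- ideges_normalize(m, groups)
  if (is.null(dispersion)) dispersion <- norm$dispersion
  lib <- colSums(m)
  eff <- lib * norm$factors
  scale <- exp(mean(log(eff))) / eff
  sm <- sweep(m, 2L, scale, "*")
  ga <- groups == levels(groups)[1L]
  meanA <- rowMeans(sm[, ga, drop = FALSE])
  meanB <- rowMeans(sm[, !ga, drop = FALSE])
  m_value <- log2((meanB + 0.5) / (meanA + 0.5))
  a_value <- 0.5 * log2((meanA + 0.5) * (meanB + 0.5))

  testable <- rowSums(m) > 0
  p <- rep(NA_real_, nrow(m))
  p[testable] <- nb_exact_test(m[testable, , drop = FALSE], groups,
                               dispersion = dispersion,
                               factors = norm$factors, lib_sizes = lib)
  q <- rep(NA_real_, nrow(m))
  q[testable] <- bh_fdr(p[testable])
  deg <- !is.na(q) & q < fdr

  ord <- order(q, p, -abs(m_value), rownames(m), na.last = TRUE)
  rank_ <- integer(nrow(m)); rank_[ord] <- seq_len(nrow(m))
  out <- data.frame(gene_id = rownames(m), m_value = m_value,
                    a_value = a_value, p_value = p, q_value = q,
                    rank = rank_, deg = deg,
                    row.names = NULL, stringsAsFactors = FALSE)
  lv <- levels(groups)
  ndeg <- list(n_total = sum(deg),
               n_up = setNames(c(sum(deg & m_value < 0), sum(deg & m_value > 0)), lv))
  attr(out, "n_deg") <- ndeg
  attr(out, "fdr") <- fdr
  class(out) <- c("de_result", "data.frame")
  out
}

#' @export
print.de_result <- function(x, ...) {
  nd <- attr(x, "n_deg")
  cat(sprintf("de_result: %d DEGs at FDR < %g (%s-high: %d, %s-high: %d)\n",
              nd$n_total, attr(x, "fdr"),
              names(nd$n_up)[1L], nd$n_up[1L], names(nd$n_up)[2L], nd$n_up[2L]))
  print.data.frame(head(x[order(x$rank), ], 10L))
  invisible(x)
}
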