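test_that("TMM factors are 1 for identical or depth-scaled columns and multiply to 1", {
  set.seed(3)
  base <- rpois(200, 50)
  m <- cbind(a = base, b = base)
  rownames(m) <- sprintf("g%03d", 1:200)
  expect_equal(unname(tmm_factors(m)), c(1, 1))
  m2 <- cbind(a = base, b = 3L * base)  # pure depth difference
  rownames(m2) <- rownames(m)
  expect_equal(unname(tmm_factors(m2)), c(1, 1))

  m3 <- nb_matrix(G = 500, n = 4)
  expect_equal(prod(tmm_factors(m3)), 1, tolerance = 1e-12)
  expect_error(tmm_factors(cbind(a = base, b = 0L * base)), "all-zero")
})

test_that("TMM matches a sort-based trimmed weighted mean on an inflated fixture", {
  set.seed(10)
  obs <- rpois(20, 40) + 1L
  ref <- rpois(20, 40) + 1L
  obs[1:2] <- obs[1:2] * 30L  # two inflated genes
  m <- cbind(ref = ref, obs = obs)
  rownames(m) <- sprintf("g%02d", 1:20)
  f <- tmm_factors(m, ref_sample = "ref")
  expected <- tmm_oracle_pair(obs, ref)
  # factors are recentred to geometric mean 1: compare the ratio
  expect_equal(unname(f["obs"] / f["ref"]), expected / 1, tolerance = 1e-10)
})

test_that("TMM agrees with the edgeR implementation on random matrices", {
  set.seed(42)
  for (i in 1:5) {
    m <- nb_matrix(G = 800, n = 5, mu_sdlog = 1.2, size = 8)
    m <- m + matrix(rpois(length(m), 1), nrow = nrow(m))
    expect_equal(unname(tmm_factors(m)),
                 unname(edgeR::calcNormFactors(m, method = "TMM")),
                 tolerance = 1e-10)
  }
})

test_that("the exact NB test matches full enumeration for all splits with sums <= 30", {
  worst <- 0
  for (s in 0:30) for (a in 0:s) {
    worst <- max(worst,
      abs(umicount:::exact_nb_pvalue(a, s - a, 3, 4, 0.15) -
            nb_enum_oracle(a, s - a, 3, 4, 0.15)),
      abs(umicount:::exact_nb_pvalue(a, s - a, 2, 2, 0) -
            nb_enum_oracle(a, s - a, 2, 2, 0)))
  }
  expect_lt(worst, 1e-10)
})

test_that("exact test symmetry and Poisson degeneration", {
  m <- matrix(c(7, 7, 7, 7), nrow = 1,
              dimnames = list("g1", sprintf("s%d", 1:4)))
  p <- nb_exact_test(m, c("A", "A", "B", "B"), dispersion = 0.1,
                     lib_sizes = rep(100, 4))
  expect_equal(p, 1)

  # (10, 0) vs (0, 10): phi = 0 reduces to a two-sided binomial tail
  m2 <- matrix(c(10, 0, 0, 10), nrow = 2,
               dimnames = list(c("gA", "gB"), c("s1", "s2")))
  p2 <- nb_exact_test(m2, c("A", "B"), dispersion = 0, lib_sizes = rep(100, 2))
  enum <- vapply(c(10L, 10L), function(a) nb_enum_oracle(a, 10L - a, 1, 1, 0),
                 numeric(1))
  expect_equal(unname(p2), c(nb_enum_oracle(10, 0, 1, 1, 0),
                             nb_enum_oracle(0, 10, 1, 1, 0)))
  expect_error(nb_exact_test(m2, c("A", "B"), dispersion = -1), "dispersion")
})

test_that("BH q-values follow the step-up definition", {
  expect_equal(bh_fdr(c(0.2, 0.2, 0.2)), rep(0.2, 3))
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(bh_fdr(0.04), 0.04)
  expect_error(bh_fdr(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("zero iDEGES iterations reproduce plain TMM exactly", {
  set.seed(5)
  m <- nb_matrix(G = 400, n = 6)
  nr <- ideges_normalize(m, rep(c("A", "B"), each = 3), iterations = 0)
  expect_identical(unname(nr$factors), unname(tmm_factors(m)))
  expect_equal(length(nr$excluded), 0L)
})

test_that("under a null simulation iDEGES factors stay close to plain TMM", {
  set.seed(6)
  diffs <- replicate(8, {
    m <- nb_matrix(G = 600, n = 6)
    g <- rep(c("A", "B"), each = 3)
    max(abs(log2(ideges_normalize(m, g, iterations = 3)$factors) -
              log2(tmm_factors(m))))
  })
  # both estimate the same (unit) truth; allow Monte-Carlo spread
  expect_lt(mean(diffs), 0.1)
})

test_that("DEG calling reports direction, ranking and NA for all-zero genes", {
  set.seed(9)
  G <- 300; n <- 4
  fc <- rep(1, G); fc[1:20] <- 8
  m <- nb_matrix(G = G, n = 2 * n, fc = fc, n_group2 = n, size = 20)
  m[G, ] <- 0L  # untestable gene
  g <- rep(c("ctrl", "treat"), each = n)
  de <- call_degs(m, g, fdr = 0.01)
  expect_true(is.na(de$p_value[G]) && is.na(de$q_value[G]))
  expect_false(de$deg[G])
  nd <- attr(de, "n_deg")
  expect_equal(nd$n_total, sum(de$deg))
  # up-regulated genes are attributed to the treated group
  expect_gt(nd$n_up[["treat"]], 0)
  expect_true(all(de$m_value[de$deg & de$q_value < 0.01 &
                               de$gene_id %in% sprintf("g%05d", 1:20)] > 0))
  # rank is a permutation consistent with (q, p, |m|) ordering
  expect_setequal(de$rank, seq_len(G))
  ord <- order(de$rank)
  qq <- de$q_value[ord]
  expect_true(all(diff(qq[!is.na(qq)]) >= -1e-12))
})

test_that("DEG power at 4-fold effects and moderate replication is high", {
  set.seed(14)
  G <- 400; n <- 30
  fc <- rep(1, G); fc[1:40] <- 4
  m <- nb_matrix(G = G, n = 2 * n, fc = fc, n_group2 = n, size = 10,
                 mu_meanlog = 2.5)
  de <- call_degs(m, rep(c("A", "B"), each = n), fdr = 0.01)
  sens <- mean(de$deg[1:40])
  expect_gt(sens, 0.8)
})

test_that("Hoeffding's D equals the definition-level oracle, with and without ties", {
  set.seed(11)
  for (i in 1:30) {
    n <- sample(5:12, 1)
    x <- sample(1:6, n, replace = TRUE)   # ties likely
    y <- sample(1:6, n, replace = TRUE)
    h <- hoeffding_d(x, y, n_perm = 0)
    expect_equal(h$D, hoeffding_oracle(x, y), tolerance = 1e-12)
  }
})

test_that("D is maximal on monotone data, near zero under shuffling, rank-invariant", {
  h <- hoeffding_d(1:12, (1:12)^3, n_perm = 500, seed = 2)
  expect_equal(h$D, 1, tolerance = 1e-12)
  expect_lt(h$p_value, 0.01)

  set.seed(3)
  x <- rnorm(150); y <- sample(x)
  h0 <- hoeffding_d(x, y, n_perm = 300, seed = 4)
  expect_lt(abs(h0$D), 0.02)
  expect_gt(h0$p_value, 0.01)

  # invariance under strictly monotone transforms
  x2 <- rnorm(40); y2 <- x2^2 + rnorm(40, 0, 0.3)
  d1 <- hoeffding_d(x2, y2, n_perm = 0)$D
  d2 <- hoeffding_d(exp(x2), y2^3 - 2 * y2^2 * 0, n_perm = 0)$D
  d3 <- hoeffding_d(exp(x2), y2, n_perm = 0)$D
  expect_equal(d1, d3, tolerance = 1e-12)
  expect_error(hoeffding_d(1:4, 1:4), "n >= 5")
})

test_that("correlation tests match cor.test on a hand-ranked fixture", {
  x <- c(3, 1, 4, 1.5, 9)
  y <- c(2, 0.5, 5, 1, 7)
  ct <- correlation_tests(x, y)
  expect_equal(ct$spearman_rho, cor(rank(x), rank(y)))
  expect_equal(ct$pearson_r, cor(x, y))
  ref <- cor.test(x, y)
  expect_equal(ct$pearson_p, ref$p.value, tolerance = 1e-12)

  expect_equal(correlation_tests(1:10, 1:10)$spearman_rho, 1)
  expect_equal(correlation_tests(1:10, 10:1)$spearman_rho, -1)
  expect_error(correlation_tests(rep(1, 5), 1:5), "variance")
})
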