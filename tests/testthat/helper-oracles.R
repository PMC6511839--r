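# Independent oracles used across the suite. These deliberately use
# naive, definition-level computations (loops, enumeration) rather than
# the package's vectorised implementations.

# Hamming distance by explicit character loop
brute_hamming <- function(a, b) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  d <- 0L
  for (i in seq_along(ca)) if (ca[i] != cb[i]) d <- d + 1L
  d
}

brute_min_pairwise <- function(seqs) {
  best <- nchar(seqs[1])
  for (i in seq_len(length(seqs) - 1L))
    for (j in (i + 1L):length(seqs))
      best <- min(best, brute_hamming(seqs[i], seqs[j]))
  best
}

# Hoeffding's D from explicit double loops over the defining indicator
# sums (midranks and bivariate ranks counted one pair at a time)
hoeffding_oracle <- function(x, y) {
  n <- length(x)
  R <- S <- Q <- numeric(n)
  for (i in seq_len(n)) {
    ri <- si <- 1
    qi <- 1
    for (j in seq_len(n)) {
      if (j == i) next
      ri <- ri + (x[j] < x[i]) + 0.5 * (x[j] == x[i])
      si <- si + (y[j] < y[i]) + 0.5 * (y[j] == y[i])
      cx <- (x[j] < x[i]) + 0.5 * (x[j] == x[i])
      cy <- (y[j] < y[i]) + 0.5 * (y[j] == y[i])
      qi <- qi + cx * cy
    }
    R[i] <- ri; S[i] <- si; Q[i] <- qi
  }
  D1 <- sum((Q - 1) * (Q - 2))
  D2 <- sum((R - 1) * (R - 2) * (S - 1) * (S - 2))
  D3 <- sum((R - 2) * (S - 2) * (Q - 1))
  30 * ((n - 2) * (n - 3) * D1 + D2 - 2 * (n - 2) * D3) /
    (n * (n - 1) * (n - 2) * (n - 3) * (n - 4))
}

# conditional exact NB p-value by direct enumeration of dnbinom
# products (the success probability cancels; any value works)
nb_enum_oracle <- function(a, b, na, nb, phi, prob = 0.37) {
  s <- a + b
  y <- 0:s
  w <- if (phi > 0)
    dnbinom(y, size = na / phi, prob = prob) *
      dnbinom(s - y, size = nb / phi, prob = prob)
  else dbinom(y, s, na / (na + nb))
  w <- w / sum(w)
  min(1, sum(w[w <= w[a + 1] * (1 + 1e-10)]))
}

# TMM factor for one sample against a reference, computed the slow way
# (explicit sort-based trimming instead of rank arithmetic)
tmm_oracle_pair <- function(obs, ref, logratio_trim = 0.3, sum_trim = 0.05) {
  no <- sum(obs); nr <- sum(ref)
  keep <- obs > 0 & ref > 0
  obs <- obs[keep]; ref <- ref[keep]
  M <- log2((obs / no) / (ref / nr))
  A <- (log2(obs / no) + log2(ref / nr)) / 2
  w <- 1 / ((no - obs) / (no * obs) + (nr - ref) / (nr * ref))
  n <- length(M)
  loM <- floor(n * logratio_trim) + 1; hiM <- n + 1 - loM
  loA <- floor(n * sum_trim) + 1; hiA <- n + 1 - loA
  keepM <- rank(M) >= loM & rank(M) <= hiM
  keepA <- rank(A) >= loA & rank(A) <= hiA
  sel <- keepM & keepA
  2^(sum(w[sel] * M[sel]) / sum(w[sel]))
}

# expected distinct (gene, UMI) groups when drawing d of N reads
# without replacement, given group sizes m (occupancy identity)
expected_distinct_groups <- function(m, d) {
  N <- sum(m)
  sum(1 - exp(lchoose(N - m, d) - lchoose(N, d)))
}

# small simulated experiment shared by several tests
tiny_sim <- function(seed = 42, n_cells = 4L, n_genes = 50L,
                     total_molecules = 2000L, ...) {
  cfg <- sim_config(n_genes = n_genes, n_cells = n_cells,
                    total_molecules = total_molecules,
                    error_read1 = 0, error_index = 0, error_umi = 0,
                    seed = seed, ...)
  simulate_cells(cfg)
}

sim_t2g <- function(sim) {
  c(sim$reference$t2g,
    setNames(names(sim$reference$spike_seqs), names(sim$reference$spike_seqs)))
}

sim_ref_all <- function(sim) {
  c(sim$reference$transcripts, sim$reference$spike_seqs)
}

# NB count matrix with a shared expression profile (exchangeable
# samples); optional fold-change vector applied to the last group
nb_matrix <- function(G, n, mu_meanlog = 3, mu_sdlog = 1, size = 10,
                      fc = NULL, n_group2 = 0) {
  mu <- exp(rnorm(G, mu_meanlog, mu_sdlog))
  m1 <- matrix(rnbinom(G * (n - n_group2), mu = mu, size = size),
               ncol = n - n_group2)
  m <- if (n_group2 > 0) {
    mu2 <- mu * (if (is.null(fc)) 1 else fc)
    cbind(m1, matrix(rnbinom(G * n_group2, mu = mu2, size = size),
                     ncol = n_group2))
  } else m1
  dimnames(m) <- list(sprintf("g%05d", seq_len(G)), sprintf("s%02d", seq_len(n)))
  m
}
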