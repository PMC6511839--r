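#' QC screening configuration
#'
#' Default thresholds follow common practice for correlation-based
#' single-cell outlier screening: maximum tolerated false-positive rate
#' 0.05, expression cutoff TPM >= 1 for gene detection, and p < 0.001
#' for the Spearman and Pearson best-partner correlation tests.
#'
#' @param max_fpr cap on the expected fraction of samples flagged under
#'   an exchangeable null, in (0, 1).
#' @param tpm_cutoff expression threshold for counting a gene as
#'   detected.
#' @param spearman_p,pearson_p significance thresholds for the
#'   correlation tests, in (0, 1).
#' @return list of class `qc_config`.
#' @export
qc_config <- function(max_fpr = 0.05, tpm_cutoff = 1,
                      spearman_p = 0.001, pearson_p = 0.001) {
  stopifnot(max_fpr > 0, max_fpr < 1, tpm_cutoff >= 0,
            spearman_p > 0, spearman_p < 1, pearson_p > 0, pearson_p < 1)
  structure(list(max_fpr = max_fpr, tpm_cutoff = tpm_cutoff,
                 spearman_p = spearman_p, pearson_p = pearson_p),
            class = "qc_config")
}

.counts_of <- function(x) {
  if (inherits(x, "umi_counts")) x$counts else as.matrix(x)
}

#' Transcripts per million
#'
#' Within-sample length-normalised expression: `rate_g = count_g /
#' length_g`, `TPM_g = 1e6 * rate_g / sum(rate)`. Columns sum to 1e6
#' unless all-zero (returned as zeros). UMI tag counts are 3'-anchored
#' and only weakly length-dependent, so genes without a length
#' annotation are given `default_length`.
#'
#' @param x a `umi_counts` object or genes x samples count matrix.
#' @param lengths optional named numeric vector of effective gene
#'   lengths; must be positive for every gene with nonzero counts.
#' @param default_length effective length used for genes missing from
#'   `lengths` (default 1000).
#' @return genes x samples matrix of TPM values.
#' @export
tpm <- function(x, lengths = NULL, default_length = 1000) {
  m <- .counts_of(x)
  len <- rep(default_length, nrow(m))
  names(len) <- rownames(m)
  if (!is.null(lengths)) {
    hit <- intersect(names(lengths), rownames(m))
    len[hit] <- lengths[hit]
  }
  if (any(len <= 0 & rowSums(m) > 0))
    stop("non-positive effective length for an expressed gene")
  rate <- m / len
  tot <- colSums(rate)
  tot[tot == 0] <- 1  # all-zero sample stays all-zero
  sweep(rate, 2L, tot, "/") * 1e6
}

# Spearman/Pearson correlation with t-approximation p-value on the
# genes expressed (> 0) in either of the two columns
.pair_cor <- function(a, b) {
  sel <- a > 0 | b > 0
  a <- a[sel]; b <- b[sel]
  n <- length(a)
  la <- log2(a + 1); lb <- log2(b + 1)
  out <- c(rho = NA_real_, p_rho = NA_real_, r = NA_real_, p_r = NA_real_)
  if (n < 3L) return(out)
  tp <- function(cc) {
    if (is.na(cc) || abs(cc) >= 1) return(if (is.na(cc)) NA_real_ else 0)
    tt <- cc * sqrt((n - 2) / (1 - cc^2))
    2 * pt(-abs(tt), df = n - 2)
  }
  rho <- suppressWarnings(cor(rank(la), rank(lb)))
  r <- suppressWarnings(cor(la, lb))
  c(rho = rho, p_rho = tp(rho), r = r, p_r = tp(r))
}

#' Correlation-based sample quality screen
#'
#' A documented, simplified re-implementation of SinQC-style screening
#' that uses exactly four configured quantities: the maximum tolerated
#' false-positive rate, a TPM detection cutoff, and Spearman and
#' Pearson test thresholds. The rule is intentionally explicit and
#' approximate; it does not reproduce the SinQC program's internal
#' algorithm.
#'
#' For each sample the screen computes (i) the number of genes detected
#' at `TPM >= tpm_cutoff`, (ii) the mapping rate (when per-sample
#' statistics are available), and (iii) the best pairwise Spearman rho
#' and Pearson r against every other sample, on `log2(TPM + 1)` over
#' genes expressed in either sample, with t-approximation p-values. A
#' sample FAILs only when *both* best-partner correlation tests are
#' non-significant at the configured thresholds *and* it is an outlier
#' in the technical metrics (lowest best-partner correlation in the
#' dataset, or lower-`max_fpr`-tail detected genes or mapping rate).
#' The number of failures is capped at `max(1, floor(max_fpr * n))`, so
#' the expected false-positive rate under an exchangeable null stays
#' below `max_fpr`.
#'
#' @param x a `umi_counts` object or genes x samples count matrix (>= 3
#'   samples).
#' @param config a [qc_config()].
#' @param lengths optional gene lengths for [tpm()].
#' @return `data.frame` of class `qc_report`: per sample
#'   `detected_genes`, `mapping_rate`, `best_rho`, `p_spearman`,
#'   `best_r`, `p_pearson`, `status` (`"PASS"`/`"FAIL"`). The
#'   configuration is attached as `attr(, "config")` and echoed by the
#'   print method.
#' @export
qc_screen <- function(x, config = qc_config(), lengths = NULL) {
  stopifnot(inherits(config, "qc_config"))
  m <- .counts_of(x)
  n <- ncol(m)
  if (n < 3L) stop("qc_screen needs at least 3 samples")
  tp <- tpm(x, lengths = lengths)
  detected <- colSums(tp >= config$tpm_cutoff)
  mapping_rate <- if (inherits(x, "umi_counts"))
    x$samples$mapping_rate[match(colnames(m), x$samples$sample_id)]
  else rep(NA_real_, n)

  best_rho <- best_r <- p_rho <- p_r <- rep(NA_real_, n)
  cors <- array(NA_real_, dim = c(n, n, 4L))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    pc <- .pair_cor(tp[, i], tp[, j])
    cors[i, j, ] <- cors[j, i, ] <- pc
  }
  for (i in seq_len(n)) {
    others <- setdiff(seq_len(n), i)
    ks <- which.max(cors[i, others, 1L])
    kp <- which.max(cors[i, others, 3L])
    best_rho[i] <- cors[i, others[ks], 1L]; p_rho[i] <- cors[i, others[ks], 2L]
    best_r[i] <- cors[i, others[kp], 3L]; p_r[i] <- cors[i, others[kp], 4L]
  }

  corr_fail <- (is.na(p_rho) | p_rho >= config$spearman_p) &
               (is.na(p_r) | p_r >= config$pearson_p)
  tail_k <- max(1L, floor(config$max_fpr * n))
  low_detected <- rank(detected, ties.method = "first") <= tail_k
  low_maprate <- if (all(is.na(mapping_rate))) rep(FALSE, n)
                 else rank(mapping_rate, ties.method = "first", na.last = "keep") <= tail_k
  low_maprate[is.na(low_maprate)] <- FALSE
  lowest_corr <- rank(best_rho, ties.method = "first") == 1L
  technical <- lowest_corr | low_detected | low_maprate

  fail <- corr_fail & technical
  if (sum(fail) > tail_k) {   # cap failures; keep the least-correlated
    ord <- order(best_rho)
    keep_fail <- head(ord[ord %in% which(fail)], tail_k)
    fail <- seq_len(n) %in% keep_fail
  }
  out <- data.frame(sample_id = colnames(m),
                    detected_genes = as.integer(detected),
                    mapping_rate = mapping_rate,
                    best_rho = best_rho, p_spearman = p_rho,
                    best_r = best_r, p_pearson = p_r,
                    status = ifelse(fail, "FAIL", "PASS"),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "config") <- config
  class(out) <- c("qc_report", "data.frame")
  out
}

#' @export
print.qc_report <- function(x, ...) {
  cfg <- attr(x, "config")
  cat(sprintf("QC screen  MAX FPR: %g, TPM Cutoff: %g, Spearman's test P-value: <%g, Pearson's test P-value: <%g\n",
              cfg$max_fpr, cfg$tpm_cutoff, cfg$spearman_p, cfg$pearson_p))
  print.data.frame(x)
  invisible(x)
}

#' Replicate concordance
#'
#' Coefficient of determination (R^2) of an ordinary least-squares fit
#' of `log2(b + 1)` on `log2(a + 1)`, over genes detected (count > 0)
#' in either replicate. The log2(x + 1) pseudocount convention makes
#' the statistic well defined at zero counts and invariant to constant
#' scaling up to the pseudocount.
#'
#' @param counts_a,counts_b named numeric vectors of per-gene counts on
#'   the same gene universe.
#' @return R^2 (numeric scalar), with attributes `n_genes`, `slope`,
#'   `intercept`.
#' @export
replicate_concordance <- function(counts_a, counts_b) {
  if (length(counts_a) != length(counts_b))
    stop("replicates must share the gene universe")
  if (!is.null(names(counts_a)) && !is.null(names(counts_b)) &&
      !identical(names(counts_a), names(counts_b)))
    counts_b <- counts_b[names(counts_a)]
  sel <- counts_a > 0 | counts_b > 0
  if (sum(sel) < 3L) stop("fewer than 3 genes detected in either replicate")
  x <- log2(counts_a[sel] + 1); y <- log2(counts_b[sel] + 1)
  fit <- lm(y ~ x)
  r2 <- suppressWarnings(summary(fit))$r.squared
  attr(r2, "n_genes") <- sum(sel)
  attr(r2, "slope") <- unname(coef(fit)[2L])
  attr(r2, "intercept") <- unname(coef(fit)[1L])
  r2
}

#' Read a spike-in concentration table
#'
#' Tab-separated `spike_id<TAB>concentration` (ERCC-style naming,
#' `ERCC-*`); lines starting with `#` and an optional header row are
#' ignored.
#'
#' @param path file path.
#' @param dilution divide nominal concentrations by this factor (e.g.
#'   20000 for a 20,000-fold diluted mix).
#' @return named numeric vector of concentrations.
#' @export
read_spike_table <- function(path, dilution = 1) {
  ln <- readLines(path)
  ln <- ln[!grepl("^#", ln) & nzchar(ln)]
  if (length(ln) && grepl("^spike_id\t", ln[1L])) ln <- ln[-1L]
  parts <- strsplit(ln, "\t", fixed = TRUE)
  conc <- as.numeric(vapply(parts, `[[`, "", 2L))
  if (any(is.na(conc) | conc <= 0)) stop("spike concentrations must be positive numbers")
  setNames(conc / dilution, vapply(parts, `[[`, "", 1L))
}

#' Spike-in dose-response linearity
#'
#' Per sample, least-squares fit of `log2(UMI count + 1)` against
#' `log2(nominal concentration)` over the spike-in species. Counts
#' exactly proportional to concentration give slope 1 and R^2 = 1;
#' global library-size scaling moves only the intercept. Drop-out
#' spikes (count 0) are retained as pseudocount points in the primary
#' fit; a variant excluding them is also reported.
#'
#' @param x a `umi_counts` object or count matrix whose rownames
#'   include the spike ids.
#' @param spikes named numeric vector of nominal concentrations
#'   ([read_spike_table()]), or `NULL` to auto-detect `ERCC-*` rows
#'   (then concentrations must be supplied).
#' @return `data.frame` per sample: `slope`, `intercept`, `r_squared`,
#'   `n_spikes`, `n_detected`, `slope_detected`, `r_squared_detected`.
#' @export
spikein_linearity <- function(x, spikes) {
  m <- .counts_of(x)
  ids <- intersect(names(spikes), rownames(m))
  if (length(ids) == 0L) stop("no spike rows present in the matrix")
  if (length(ids) < 3L) stop("fewer than 3 spike-in species present")
  conc <- log2(spikes[ids])
  out <- lapply(colnames(m), function(s) {
    y <- m[ids, s]
    if (all(y == 0)) stop("no spike detected in sample ", s)
    fit <- lm(log2(y + 1) ~ conc)
    det <- y > 0
    if (sum(det) >= 3L && length(unique(conc[det])) >= 2L) {
      fit2 <- lm(log2(y[det] + 1) ~ conc[det])
      s2 <- unname(coef(fit2)[2L]); r2b <- suppressWarnings(summary(fit2))$r.squared
    } else { s2 <- NA_real_; r2b <- NA_real_ }
    data.frame(sample_id = s, slope = unname(coef(fit)[2L]),
               intercept = unname(coef(fit)[1L]),
               r_squared = suppressWarnings(summary(fit))$r.squared,
               n_spikes = length(ids), n_detected = sum(det),
               slope_detected = s2, r_squared_detected = r2b,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
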