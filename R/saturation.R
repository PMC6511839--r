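#' Subsample gene-assigned reads
#'
#' Uniform sampling without replacement of exactly `depth` mapped,
#' gene-assigned reads, mirroring random extraction of reads from a
#' fixed sequenced dataset (not binomial thinning).
#'
#' @param assignments a `gene_assignments` object or assignment
#'   `data.table` (one sample).
#' @param depth number of reads to draw, `0 <= depth <= nrow`.
#' @param seed integer seed.
#' @return assignment `data.table` with `depth` rows.
#' @export
subsample_reads <- function(assignments, depth, seed = 1L) {
  a <- if (inherits(assignments, "gene_assignments")) assignments$assignments
       else as.data.table(assignments)
  depth <- as.integer(depth)
  if (depth < 0L || depth > nrow(a))
    stop("depth must be between 0 and the number of mapped reads")
  set.seed(as.integer(seed) %% .Machine$integer.max)
  a[sample.int(nrow(a), depth), ]
}

.sat_stats <- function(sub) {
  d <- nrow(sub)
  if (d == 0L)
    return(list(detected_genes = 0L, umi_count = 0L, umi_unified_rate = NA_real_))
  pairs <- unique(sub[, c("gene_id", "umi")])
  list(detected_genes = uniqueN(pairs$gene_id),
       umi_count = nrow(pairs),
       umi_unified_rate = (d - nrow(pairs)) / d)
}

#' Saturation analysis by read subsampling
#'
#' Recomputes the number of detected genes and the UMI-unified rate on
#' random read subsets of increasing depth, to judge whether sequencing
#' depth suffices: detected genes rise towards a plateau and the
#' unified rate rises towards its asymptote as depth grows.
#'
#' @param assignments a `gene_assignments` object or assignment
#'   `data.table` (one sample).
#' @param depths integer vector of read depths (sorted internally;
#'   values above the available reads are an error).
#' @param replicates independent subsamples per depth.
#' @param seed base seed; each (depth, replicate) uses a distinct
#'   derived seed.
#' @return `data.frame` of class `saturation_curve` with columns
#'   `depth`, `replicate`, `detected_genes`, `umi_count`,
#'   `umi_unified_rate`; the per-depth summary (mean and sd) is in
#'   `attr(, "summary")`.
#' @export
saturation_curve <- function(assignments, depths, replicates = 5L, seed = 1L) {
  a <- if (inherits(assignments, "gene_assignments")) assignments$assignments
       else as.data.table(assignments)
  depths <- sort(unique(as.integer(depths)))
  if (any(depths < 0L) || any(depths > nrow(a)))
    stop("depths must lie in [0, number of mapped reads]")
  out <- vector("list", length(depths) * replicates)
  i <- 0L
  for (di in seq_along(depths)) {
    for (r in seq_len(replicates)) {
      i <- i + 1L
      s <- (as.integer(seed) + 7919L * di + r) %% .Machine$integer.max
      sub <- subsample_reads(a, depths[di], seed = s)
      st <- .sat_stats(sub)
      out[[i]] <- data.frame(depth = depths[di], replicate = r,
                             detected_genes = st$detected_genes,
                             umi_count = st$umi_count,
                             umi_unified_rate = st$umi_unified_rate)
    }
  }
  res <- do.call(rbind, out)
  sm <- aggregate(cbind(detected_genes, umi_unified_rate) ~ depth, data = res,
                  FUN = mean, na.action = stats::na.pass)
  sdt <- aggregate(cbind(detected_genes, umi_unified_rate) ~ depth, data = res,
                   FUN = sd, na.action = stats::na.pass)
  names(sm)[-1L] <- paste0("mean_", names(sm)[-1L])
  names(sdt)[-1L] <- paste0("sd_", names(sdt)[-1L])
  attr(res, "summary") <- merge(sm, sdt, by = "depth")
  attr(res, "seed") <- as.integer(seed)
  class(res) <- c("saturation_curve", "data.frame")
  res
}

#' @importFrom stats aggregate na.pass
#' @export
print.saturation_curve <- function(x, ...) {
  cat("saturation_curve:\n")
  print(attr(x, "summary"))
  invisible(x)
}
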