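#' Read a transcript-to-gene map
#'
#' Tab-separated table `transcript_id<TAB>gene_id`, many transcripts to
#' one gene. Lines starting with `#` are ignored; a `transcript_id`
#' header row is optional.
#'
#' @param path file path.
#' @return named character vector mapping transcript id to gene id.
#' @export
read_t2g <- function(path) {
  ln <- readLines(path)
  ln <- ln[!grepl("^#", ln) & nzchar(ln)]
  if (length(ln) && grepl("^transcript_id\t", ln[1L])) ln <- ln[-1L]
  parts <- strsplit(ln, "\t", fixed = TRUE)
  if (any(lengths(parts) < 2L)) stop("malformed transcript-to-gene map")
  tx <- vapply(parts, `[[`, "", 1L)
  if (anyDuplicated(tx)) stop("a transcript maps to more than one gene")
  setNames(vapply(parts, `[[`, "", 2L), tx)
}

#' Resolve SAM alignments to gene assignments
#'
#' Consumes alignments of demultiplexed, UMI-named reads against a
#' transcript reference and resolves each read to at most one gene
#' locus. Multiple alignments of one read to transcripts of the *same*
#' gene collapse to a single assignment (the lexicographically smallest
#' transcript id, smallest position, for determinism). A read hitting
#' transcripts of more than one gene is handled by `multimap_policy`:
#' `"discard"` (default, conservative) contributes to no gene;
#' `"first"` keeps the gene of the smallest (transcript, position)
#' alignment; `"all"` keeps one assignment per gene.
#'
#' @param sam path to a SAM (or BAM) file whose QNAMEs carry the
#'   `_UMI:` token and whose reference names appear in `t2g`.
#' @param t2g named character vector from [read_t2g()] (transcript ->
#'   gene).
#' @param multimap_policy `"discard"`, `"first"` or `"all"`.
#' @return list of class `gene_assignments`:
#'   * `assignments`: `data.table` with `read_id`, `umi`, `gene_id`,
#'     `transcript_id`, `pos` (1-based leftmost), one row per
#'     (read, gene);
#'   * `n_records`, `n_reads`, `n_unmapped`, `n_multigene_discarded`,
#'     `mapped_reads` (reads contributing at least one assignment).
#' @export
parse_alignments <- function(sam, t2g, multimap_policy = c("discard", "first", "all")) {
  multimap_policy <- match.arg(multimap_policy)
  bam <- if (grepl("\\.bam$", sam, ignore.case = TRUE)) sam else
    Rsamtools::asBam(sam, tempfile(), overwrite = TRUE, indexDestination = FALSE)
  b <- Rsamtools::scanBam(bam, param = Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos")))[[1L]]
  n_records <- length(b$qname)
  unmapped <- bitwAnd(b$flag, 4L) > 0L
  n_unmapped <- length(unique(b$qname[unmapped]))
  dt <- data.table(qname = b$qname[!unmapped],
                   rname = as.character(b$rname[!unmapped]),
                   pos = b$pos[!unmapped])
  n_reads <- length(unique(b$qname))
  if (nrow(dt) == 0L) {
    return(structure(list(
      assignments = data.table(read_id = character(), umi = character(),
                               gene_id = character(), transcript_id = character(),
                               pos = integer()),
      n_records = n_records, n_reads = n_reads, n_unmapped = n_unmapped,
      n_multigene_discarded = 0L, mapped_reads = 0L),
      class = "gene_assignments"))
  }
  missing_ref <- setdiff(unique(dt$rname), names(t2g))
  if (length(missing_ref))
    stop("reference names absent from the transcript-to-gene map: ",
         paste(head(missing_ref, 5L), collapse = ", "))
  dt[, gene_id := t2g[rname]]
  pu <- extract_umi_from_name(dt$qname)
  dt[, `:=`(read_id = pu$read_id, umi = pu$umi)]

  # collapse transcripts of the same gene, then apply the multigene policy
  setkeyv(dt, c("qname", "gene_id", "rname", "pos"))
  one <- dt[, .SD[1L], by = c("qname", "gene_id")]
  ngenes <- one[, .N, by = "qname"]
  multi <- ngenes$qname[ngenes$N > 1L]
  n_multi <- length(multi)
  if (n_multi && multimap_policy == "discard") {
    one <- one[!one$qname %in% multi, ]
  } else if (n_multi && multimap_policy == "first") {
    setkeyv(one, c("qname", "rname", "pos", "gene_id"))
    one <- one[, .SD[1L], by = "qname"]
  }  # "all": keep one row per gene
  assignments <- one[, list(read_id, umi, gene_id, transcript_id = rname, pos)]
  structure(list(assignments = assignments,
                 n_records = n_records,
                 n_reads = n_reads,
                 n_unmapped = n_unmapped,
                 n_multigene_discarded = if (multimap_policy == "discard") n_multi else 0L,
                 mapped_reads = length(unique(assignments$read_id))),
            class = "gene_assignments")
}

#' @export
print.gene_assignments <- function(x, ...) {
  cat(sprintf("gene_assignments: %d reads (%d unmapped, %d multigene-discarded), %d assignments\n",
              x$n_reads, x$n_unmapped, x$n_multigene_discarded,
              nrow(x$assignments)))
  invisible(x)
}

#' Unify reads into UMI counts
#'
#' The core tag-counting step: within one sample, all mapped reads that
#' share a gene locus and a UMI are considered copies of one original
#' first-strand cDNA and collapse to a single count. Reads on different
#' genes are never merged, even with identical UMIs. One representative
#' read per (gene, UMI) group is chosen at random under `seed`; the
#' choice never affects the counts. UMIs are compared by exact identity
#' (no mismatch merging), and UMIs containing `N` are discarded because
#' they cannot be grouped unambiguously.
#'
#' @param assignments a `gene_assignments` object or its `assignments`
#'   `data.table` (one sample).
#' @param seed integer seed for representative selection.
#' @return list of class `umi_unification`: `counts` (named integer
#'   vector, distinct UMIs per gene), `representatives` (`data.table`
#'   gene_id/umi/read_id), `n_reads` (reads considered),
#'   `n_umi` (total distinct (gene, UMI) pairs), `n_umi_n_dropped`.
#' @export
unify_umis <- function(assignments, seed = 1L) {
  a <- if (inherits(assignments, "gene_assignments")) assignments$assignments
       else as.data.table(assignments)
  has_n <- grepl("N", a$umi, fixed = TRUE)
  n_dropped <- sum(has_n)
  a <- a[!has_n, ]
  if (nrow(a) == 0L) {
    return(structure(list(counts = integer(0),
                          representatives = data.table(gene_id = character(),
                                                       umi = character(),
                                                       read_id = character()),
                          n_reads = 0L, n_umi = 0L,
                          n_umi_n_dropped = n_dropped),
                     class = "umi_unification"))
  }
  set.seed(as.integer(seed) %% .Machine$integer.max)
  a <- a[sample.int(nrow(a)), ]  # random order; first row per group = representative
  setkeyv(a, c("gene_id", "umi"))
  reps <- a[, list(read_id = read_id[1L]), by = c("gene_id", "umi")]
  counts_dt <- reps[, .N, by = "gene_id"]
  structure(list(counts = setNames(counts_dt$N, counts_dt$gene_id),
                 representatives = reps,
                 n_reads = nrow(a),
                 n_umi = nrow(reps),
                 n_umi_n_dropped = n_dropped),
            class = "umi_unification")
}

#' Assemble a UMI count matrix with per-sample statistics
#'
#' @param unified named list of [unify_umis()] results, one per sample
#'   (names are the sample ids; duplicates are an error).
#' @param gene_universe character vector of all gene ids (rows); genes
#'   absent from a sample get 0.
#' @param mapped_reads optional named integer vector of mapped read
#'   counts per sample (defaults to each sample's `n_reads`).
#' @param total_reads optional named integer vector of total sequenced
#'   reads per sample (for mapping rates; `NA` if unknown).
#' @return object of class `umi_counts`: list with
#'   * `counts`: genes x samples integer matrix of unified UMI counts;
#'   * `samples`: data.frame with `sample_id`, `total_reads`,
#'     `mapped_reads`, `mapping_rate`, `umi_counts` (column sums),
#'     `umi_unified_rate` = (mapped - UMI)/mapped, `detected_genes`.
#' @export
build_matrix <- function(unified, gene_universe, mapped_reads = NULL,
                         total_reads = NULL) {
  ids <- names(unified)
  if (is.null(ids) || anyDuplicated(ids)) stop("duplicate or missing sample ids")
  gene_universe <- unique(as.character(gene_universe))
  m <- matrix(0L, nrow = length(gene_universe), ncol = length(ids),
              dimnames = list(gene_universe, ids))
  for (s in ids) {
    cnt <- unified[[s]]$counts
    bad <- setdiff(names(cnt), gene_universe)
    if (length(bad)) stop("counted genes outside the gene universe: ",
                          paste(head(bad, 5L), collapse = ", "))
    m[names(cnt), s] <- as.integer(cnt)
  }
  umi_col <- colSums(m)
  mapped <- vapply(ids, function(s) {
    if (!is.null(mapped_reads)) as.integer(mapped_reads[[s]])
    else unified[[s]]$n_reads
  }, integer(1))
  if (any(umi_col > mapped))
    stop("UMI counts exceed mapped reads for some sample")
  tot <- vapply(ids, function(s) {
    if (!is.null(total_reads)) as.integer(total_reads[[s]]) else NA_integer_
  }, integer(1))
  samples <- data.frame(
    sample_id = ids,
    total_reads = tot,
    mapped_reads = mapped,
    mapping_rate = ifelse(is.na(tot), NA_real_, mapped / tot),
    umi_counts = as.integer(umi_col),
    umi_unified_rate = ifelse(mapped > 0, (mapped - umi_col) / mapped, NA_real_),
    detected_genes = colSums(m >= 1L),
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(counts = m, samples = samples), class = "umi_counts")
}

#' @export
print.umi_counts <- function(x, ...) {
  cat(sprintf("umi_counts: %d genes x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  print(x$samples)
  invisible(x)
}

#' @export
dim.umi_counts <- function(x) dim(x$counts)

#' Toy exact k-mer aligner emitting SAM
#'
#' A test-scale stand-in for a read aligner: each read is aligned to
#' every reference transcript containing its first `k`-mer exactly, at
#' the leftmost occurrence (CIGAR `kM` plus a soft clip for the
#' remainder). Reads whose leading k-mer occurs nowhere are emitted as
#' unmapped records. Output is valid SAM with `@SQ` headers, suitable
#' for [parse_alignments()].
#'
#' @param names,seq parallel character vectors of read names (QNAMEs;
#'   must be whitespace-free) and sequences.
#' @param reference named character vector or `DNAStringSet` of
#'   transcript sequences (unique ids).
#' @param k k-mer length (default 31); all reads must be at least `k`
#'   long.
#' @param out path of the SAM file to write.
#' @return `out`, invisibly; attribute `n_mapped` gives the number of
#'   reads with at least one alignment.
#' @export
toy_align <- function(names, seq, reference, k = 31L, out = tempfile(fileext = ".sam")) {
  ref <- if (inherits(reference, "DNAStringSet")) as.character(reference)
         else unlist(reference)
  if (is.null(base::names(ref)) || anyDuplicated(base::names(ref)))
    stop("reference transcripts must have unique ids")
  if (any(nchar(seq) < k)) stop("all reads must be at least k bases long")
  if (any(grepl("[ \t]", names))) stop("read names must be whitespace-free")

  # k-mer dictionary of the reference: leftmost occurrence per (kmer, ref)
  kmers <- rbindlist(lapply(base::names(ref), function(id) {
    s <- ref[[id]]
    L <- nchar(s)
    if (L < k) return(NULL)
    st <- seq_len(L - k + 1L)
    data.table(kmer = substring(s, st, st + k - 1L), rname = id, pos = st)
  }))
  setkeyv(kmers, c("kmer", "rname", "pos"))
  kmers <- kmers[, .SD[1L], by = c("kmer", "rname")]

  reads <- data.table(qname = names, seq = seq, kmer = substr(seq, 1L, k))
  setkey(kmers, kmer)
  hits <- kmers[reads, on = "kmer", allow.cartesian = TRUE]
  mapped <- hits[!is.na(hits$rname), ]
  unmapped_q <- setdiff(reads$qname, mapped$qname)

  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           sprintf("@SQ\tSN:%s\tLN:%d", base::names(ref), nchar(ref)))
  cig <- function(len) ifelse(len > k, sprintf("%dM%dS", k, len - k),
                              sprintf("%dM", k))
  rec_m <- if (nrow(mapped)) sprintf("%s\t0\t%s\t%d\t255\t%s\t*\t0\t0\t%s\t*",
                                     mapped$qname, mapped$rname, mapped$pos,
                                     cig(nchar(mapped$seq)), mapped$seq) else character(0)
  useq <- reads$seq[match(unmapped_q, reads$qname)]
  rec_u <- if (length(unmapped_q)) sprintf("%s\t4\t*\t0\t0\t*\t*\t0\t0\t%s\t*",
                                           unmapped_q, useq) else character(0)
  writeLines(c(hdr, rec_m, rec_u), out)
  attr(out, "n_mapped") <- length(unique(mapped$qname))
  invisible(out)
}

#' Count UMIs for a set of demultiplexed samples
#'
#' Convenience wrapper running [toy_align()] (or consuming existing SAM
#' files), [parse_alignments()] and [unify_umis()] per sample, then
#' [build_matrix()].
#'
#' @param reads a `demux_result` from [demultiplex()] (its kept reads
#'   are used), or a named list of SAM paths.
#' @param reference transcript sequences for [toy_align()] (ignored when
#'   `reads` are SAM paths).
#' @param t2g transcript-to-gene map (named character vector).
#' @param k k-mer length for the toy aligner.
#' @param multimap_policy see [parse_alignments()].
#' @param seed unification seed.
#' @return a `umi_counts` object (see [build_matrix()]); genes are the
#'   full universe of `t2g`.
#' @export
count_samples <- function(reads, t2g, reference = NULL, k = 31L,
                          multimap_policy = "discard", seed = 1L) {
  gene_universe <- unique(unname(t2g))
  if (inherits(reads, "demux_result")) {
    surv <- as.data.frame(reads$reads)
    surv <- surv[surv$kept, ]
    samples <- sort(unique(surv$sample_id))
    sams <- lapply(samples, function(s) {
      sub <- surv[surv$sample_id == s, ]
      toy_align(sub$name, sub$seq, reference, k = k)
    })
    base::names(sams) <- samples
  } else sams <- reads
  unified <- list(); mapped <- integer(0); total <- integer(0)
  for (s in base::names(sams)) {
    pa <- parse_alignments(sams[[s]], t2g, multimap_policy = multimap_policy)
    unified[[s]] <- unify_umis(pa, seed = seed)
    mapped[s] <- pa$mapped_reads
    total[s] <- pa$n_reads
  }
  build_matrix(unified, gene_universe, mapped_reads = mapped,
               total_reads = total)
}
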