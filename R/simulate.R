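#' Simulation configuration
#'
#' Parameters of the synthetic read generator. Defaults describe a
#' desk-scale multiplexed single-cell DGE experiment: 10 cells, 200
#' genes (one transcript each, ~1 kb), roughly 10,000 transcript
#' molecules per cell of which about half are captured into
#' first-strand cDNA, 10-nt UMIs and 8-nt indexes, a one-parameter
#' geometric PCR duplication model (`reads per molecule = 1 +
#' Geometric(p_dup)`, so `p_dup = 0.3` gives ~3.3 reads per molecule),
#' per-base substitution error rates of 1e-3 (typical Illumina scale),
#' and an 8-species spike-in ladder with 2-fold concentration steps
#' entering each cell independently of the expression model.
#'
#' @param n_genes,transcripts_per_gene,transcript_length reference
#'   shape; lengths are drawn uniformly within +/- 20% of
#'   `transcript_length`.
#' @param n_cells number of cells (samples).
#' @param total_molecules mean true transcript molecules per cell.
#' @param expr_sigma sdlog of the log-normal gene-abundance profile.
#' @param capture_rate per-molecule capture probability into cDNA.
#' @param umi_length,index_length tag lengths.
#' @param p_dup geometric duplication parameter in (0, 1]; 1 means a
#'   single read per molecule.
#' @param error_read1,error_index,error_umi per-base substitution
#'   error rates for the three read regions.
#' @param read_length read1 length (must not exceed the shortest
#'   transcript).
#' @param n_spikes,spike_top,spike_capture spike ladder: `n_spikes`
#'   species at concentrations `spike_top / 2^(k-1)`; expected captured
#'   spike molecules per cell are `concentration * spike_capture`.
#' @param seed master seed; every derived draw is a deterministic
#'   function of it.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 200L, transcripts_per_gene = 1L,
                       transcript_length = 1000L, n_cells = 10L,
                       total_molecules = 10000L, expr_sigma = 1,
                       capture_rate = 0.5, umi_length = 10L,
                       index_length = 8L, p_dup = 0.3,
                       error_read1 = 0.001, error_index = 0.001,
                       error_umi = 0.001, read_length = 80L,
                       n_spikes = 8L, spike_top = 1024,
                       spike_capture = 0.25, seed = 1L) {
  stopifnot(p_dup > 0, p_dup <= 1,
            error_read1 >= 0, error_read1 <= 1,
            error_index >= 0, error_index <= 1,
            error_umi >= 0, error_umi <= 1,
            capture_rate > 0, capture_rate <= 1,
            transcript_length >= read_length)
  structure(as.list(environment()), class = "sim_config")
}

.random_dna <- function(n, len) {
  if (n == 0L) return(character(0))
  m <- matrix(sample(.DNA_BASES, n * len, replace = TRUE), nrow = n)
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

# substitute bases at rate `rate`, changing each hit to a different base
.mutate <- function(seqs, rate) {
  if (rate <= 0 || length(seqs) == 0L) return(seqs)
  lens <- nchar(seqs)
  total <- sum(lens)
  nhit <- rbinom(1L, total, rate)
  if (nhit == 0L) return(seqs)
  flat_pos <- sample.int(total, nhit)
  ends <- cumsum(lens)
  read_idx <- findInterval(flat_pos - 1L, c(0L, ends), rightmost.closed = FALSE)
  offset <- flat_pos - c(0L, ends)[read_idx]
  for (k in seq_len(nhit)) {
    i <- read_idx[k]; j <- offset[k]
    old <- substr(seqs[i], j, j)
    new <- sample(setdiff(.DNA_BASES, old), 1L)
    substr(seqs[i], j, j) <- new
  }
  seqs
}

#' Generate a synthetic transcript reference
#'
#' Random-sequence transcripts grouped into genes, a
#' transcript-to-gene map, a log-normal gene abundance profile, and an
#' `ERCC-`-named spike ladder. Deterministic under the config seed.
#'
#' @param config a [sim_config()].
#' @return list of class `sim_reference`: `transcripts` (named
#'   character vector), `t2g` (named vector transcript -> gene),
#'   `gene_abundance` (relative expression proportions),
#'   `spike_table` (named concentrations), `spike_seqs`.
#' @export
make_reference <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed %% .Machine$integer.max)
  G <- config$n_genes; Tpg <- config$transcripts_per_gene
  genes <- sprintf("g%04d", seq_len(G))
  tx <- as.vector(t(outer(genes, seq_len(Tpg),
                          function(g, j) sprintf("%s.t%d", g, j))))
  lens <- sample(seq(round(config$transcript_length * 0.8),
                     round(config$transcript_length * 1.2)),
                 length(tx), replace = TRUE)
  lens <- pmax(lens, config$read_length)
  seqs <- vapply(lens, function(L) paste(sample(.DNA_BASES, L, replace = TRUE),
                                         collapse = ""), "")
  names(seqs) <- tx
  t2g <- setNames(rep(genes, each = Tpg), tx)

  ab <- rlnorm(G, meanlog = 0, sdlog = config$expr_sigma)
  ab <- setNames(ab / sum(ab), genes)

  spikes <- character(0); spike_tab <- numeric(0)
  if (config$n_spikes > 0L) {
    sid <- sprintf("ERCC-%04d", seq_len(config$n_spikes))
    slen <- pmax(config$read_length,
                 sample(seq(round(config$transcript_length * 0.8),
                            round(config$transcript_length * 1.2)),
                        config$n_spikes, replace = TRUE))
    spikes <- setNames(vapply(slen, function(L)
      paste(sample(.DNA_BASES, L, replace = TRUE), collapse = ""), ""), sid)
    spike_tab <- setNames(config$spike_top / 2^(seq_len(config$n_spikes) - 1L), sid)
  }
  structure(list(transcripts = seqs, t2g = t2g, gene_abundance = ab,
                 spike_table = spike_tab, spike_seqs = spikes),
            class = "sim_reference")
}

#' Write a simulated reference to disk
#'
#' FASTA of transcripts (spikes appended), transcript-to-gene TSV
#' (spikes map to themselves), and the spike concentration TSV.
#'
#' @param reference a `sim_reference`.
#' @param dir output directory.
#' @return named vector of the written paths.
#' @export
write_reference <- function(reference, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  allseq <- c(reference$transcripts, reference$spike_seqs)
  fa <- file.path(dir, "transcripts.fasta")
  dna <- Biostrings::DNAStringSet(allseq)
  Biostrings::writeXStringSet(dna, fa)
  t2g_path <- file.path(dir, "t2g.tsv")
  t2g_all <- c(reference$t2g,
               setNames(names(reference$spike_seqs), names(reference$spike_seqs)))
  writeLines(c("transcript_id\tgene_id",
               paste(names(t2g_all), t2g_all, sep = "\t")), t2g_path)
  sp <- file.path(dir, "spikes.tsv")
  writeLines(c("spike_id\tconcentration",
               paste(names(reference$spike_table),
                     reference$spike_table, sep = "\t")), sp)
  c(fasta = fa, t2g = t2g_path, spikes = sp)
}

#' Simulate multiplexed DGE reads with ground truth
#'
#' Generates the paired read1 / index-read FASTQ records of a pooled
#' DGE run. Per cell, true molecule counts per gene are Poisson around
#' the shared abundance profile; each molecule is captured with
#' `capture_rate`, receives a uniform random UMI, and emits `1 +
#' Geometric(p_dup)` reads. Each read starts at a uniform position
#' within its transcript (fragmentation happens after amplification,
#' so duplicate reads of one molecule need not share a start). The
#' index read is `index + UMI + 2 random bases` (20 nt). Substitution
#' errors are applied per region at the configured rates. Spike-in
#' molecules bypass the expression model: captured spike molecules per
#' cell are Poisson in `concentration * spike_capture`.
#'
#' @param config a [sim_config()].
#' @param reference a `sim_reference` from [make_reference()] (built
#'   from `config` when `NULL`).
#' @param index_set an [index_set()] with at least `n_cells` entries;
#'   default [design_indexes()] at distance 3.
#' @return list of class `sim_run`:
#'   * `read1`, `index`: lists with `id`, `seq`, `qual`;
#'   * `truth`: list with `molecules` (`data.table` cell/gene/
#'     transcript/umi/molecule_id/n_reads), `per_cell_gene`
#'     (cell/gene/true_molecules/captured/distinct_umi), `reads`
#'     (read_id/molecule_id/cell/gene/umi);
#'   * `index_set`, `reference`, `config`.
#' @export
simulate_cells <- function(config, reference = NULL, index_set = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(reference)) reference <- make_reference(config)
  if (is.null(index_set))
    index_set <- design_indexes(config$n_cells, config$index_length, 3L)
  if (nrow(index_set) < config$n_cells)
    stop("index set smaller than the number of cells")
  set.seed((config$seed + 1L) %% .Machine$integer.max)

  cells <- index_set$sample_id[seq_len(config$n_cells)]
  genes <- names(reference$gene_abundance)
  lam <- reference$gene_abundance * config$total_molecules

  mol <- list(); pcg <- list()
  for (ci in seq_along(cells)) {
    true_g <- rpois(length(genes), lam)
    cap_g <- rbinom(length(genes), true_g, config$capture_rate)
    # spikes: ladder concentration times capture efficiency, expression
    # model bypassed
    sp_ids <- names(reference$spike_table)
    cap_s <- if (length(sp_ids))
      rpois(length(sp_ids), reference$spike_table * config$spike_capture)
    else integer(0)
    all_g <- c(genes, sp_ids)
    all_cap <- c(cap_g, cap_s)
    all_true <- c(true_g, rep(NA_integer_, length(sp_ids)))
    pcg[[ci]] <- data.table(cell = cells[ci], gene = all_g,
                            true_molecules = all_true, captured = all_cap)
    if (sum(all_cap) == 0L) next
    gvec <- rep(all_g, all_cap)
    mol[[ci]] <- data.table(cell = cells[ci], gene = gvec)
  }
  molecules <- rbindlist(mol)
  n_mol <- nrow(molecules)
  if (n_mol == 0L) stop("simulation produced no captured molecules")

  # transcript choice, UMI, read multiplicity per molecule
  tx_by_gene <- split(names(reference$t2g), unname(reference$t2g))
  pick_tx <- function(g) {
    tt <- tx_by_gene[[g]]
    if (is.null(tt)) g else tt[sample.int(length(tt), 1L)]
  }
  gene_v <- molecules$gene
  tx_v <- character(n_mol)
  is_spike <- gene_v %in% names(reference$spike_table)
  tx_v[is_spike] <- gene_v[is_spike]
  n_tx <- vapply(tx_by_gene[gene_v], length, integer(1))
  single <- !is_spike & n_tx == 1L
  tx_v[single] <- vapply(tx_by_gene[gene_v[single]], `[[`, "", 1L)
  rest <- !is_spike & !single
  if (any(rest)) tx_v[rest] <- vapply(gene_v[rest], pick_tx, "")
  molecules[, `:=`(transcript = tx_v,
                   umi = .random_dna(n_mol, config$umi_length),
                   molecule_id = seq_len(n_mol),
                   n_reads = 1L + rgeom(n_mol, config$p_dup))]

  truth_pairs <- molecules[, list(distinct_umi = uniqueN(umi)),
                           by = c("cell", "gene")]
  per_cell_gene <- rbindlist(pcg)
  per_cell_gene <- merge(per_cell_gene, truth_pairs,
                         by = c("cell", "gene"), all.x = TRUE)
  per_cell_gene[is.na(distinct_umi), distinct_umi := 0L]

  # expand molecules to reads
  reads <- molecules[rep(seq_len(n_mol), molecules$n_reads),
                     c("cell", "gene", "transcript", "umi", "molecule_id")]
  n_reads <- nrow(reads)
  reads[, read_id := sprintf("sim%08d", seq_len(n_reads))]

  allseq <- c(reference$transcripts, reference$spike_seqs)
  tlen <- nchar(allseq)[reads$transcript]
  start <- 1L + floor(runif(n_reads) * (tlen - config$read_length + 1L))
  r1 <- substring(allseq[reads$transcript], start,
                  start + config$read_length - 1L)
  r1 <- .mutate(r1, config$error_read1)

  idx_of_cell <- setNames(index_set$index_seq, index_set$sample_id)
  idx_part <- .mutate(idx_of_cell[reads$cell], config$error_index)
  umi_part <- .mutate(reads$umi, config$error_umi)
  index_read <- paste0(idx_part, umi_part, .random_dna(n_reads, 2L))

  q1 <- strrep("F", config$read_length)           # constant Q37
  qi <- strrep("F", config$index_length + config$umi_length + 2L)
  structure(list(
    read1 = list(id = reads$read_id, seq = unname(r1), qual = rep(q1, n_reads)),
    index = list(id = reads$read_id, seq = index_read, qual = rep(qi, n_reads)),
    truth = list(molecules = molecules, per_cell_gene = per_cell_gene,
                 reads = reads[, c("read_id", "molecule_id", "cell", "gene", "umi")]),
    index_set = index_set[seq_len(config$n_cells), ],
    reference = reference, config = config),
    class = "sim_run")
}

#' @export
print.sim_run <- function(x, ...) {
  cat(sprintf("sim_run: %d cells, %d reads from %d captured molecules (seed %d)\n",
              x$config$n_cells, length(x$read1$id),
              nrow(x$truth$molecules), x$config$seed))
  invisible(x)
}

#' Write simulated FASTQ files
#'
#' @param sim a `sim_run`.
#' @param dir output directory.
#' @param compress write gzip-compressed FASTQ.
#' @return named vector with the `read1` and `index` paths.
#' @export
write_fastq_pair <- function(sim, dir, compress = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ext <- if (compress) ".fastq.gz" else ".fastq"
  p1 <- file.path(dir, paste0("read1", ext))
  p2 <- file.path(dir, paste0("index", ext))
  write_fastq(sim$read1$id, sim$read1$seq, sim$read1$qual, p1)
  write_fastq(sim$index$id, sim$index$seq, sim$index$qual, p2)
  c(read1 = p1, index = p2)
}

#' Compare a recovered count matrix against simulation truth
#'
#' @param x a `umi_counts` object (cells as samples).
#' @param truth the `truth` component of a `sim_run` (or the `sim_run`
#'   itself).
#' @return list: `per_cell` (`data.frame` with exact-match fraction and
#'   max absolute deviation per cell), `exact_match_fraction` (over all
#'   cell x gene cells), `max_abs_deviation`, `total_deviation`
#'   (signed sum, counts minus truth).
#' @export
ground_truth_compare <- function(x, truth) {
  if (inherits(truth, "sim_run")) truth <- truth$truth
  m <- .counts_of(x)
  pcg <- truth$per_cell_gene
  cells <- colnames(m)
  if (!all(cells %in% unique(pcg$cell)))
    stop("sample ids do not match simulated cells")
  per_cell <- lapply(cells, function(cl) {
    tt <- pcg[pcg$cell == cl, ]
    tv <- setNames(tt$distinct_umi, tt$gene)
    got <- m[, cl]
    want <- rep(0L, length(got)); names(want) <- rownames(m)
    hit <- intersect(names(tv), names(want))
    want[hit] <- tv[hit]
    dev <- got - want
    data.frame(cell = cl,
               exact_match_fraction = mean(dev == 0),
               max_abs_deviation = max(abs(dev)),
               total_deviation = sum(dev),
               stringsAsFactors = FALSE)
  })
  per_cell <- do.call(rbind, per_cell)
  list(per_cell = per_cell,
       exact_match_fraction = with(per_cell, sum(exact_match_fraction * nrow(m)) / (nrow(m) * length(cells))),
       max_abs_deviation = max(per_cell$max_abs_deviation),
       total_deviation = sum(per_cell$total_deviation))
}
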