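#' Read a FASTQ file into parallel character vectors
#'
#' Thin wrapper over [Biostrings::readDNAStringSet()] returning plain
#' character vectors, which the vectorised trimming and demultiplexing
#' code operates on.
#'
#' @param path FASTQ file (optionally gzip-compressed).
#' @return list with components `id` (full header line), `seq`, `qual`
#'   (Phred+33 strings).
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  list(id = names(x),
       seq = as.character(x),
       qual = as.character(S4Vectors::mcols(x)$qualities))
}

#' Write a FASTQ file
#'
#' @param id,seq,qual parallel character vectors (read names, sequences,
#'   Phred+33 quality strings).
#' @param path output path; a `.gz` suffix triggers compression.
#' @export
write_fastq <- function(id, seq, qual, path) {
  x <- Biostrings::DNAStringSet(seq)
  names(x) <- id
  Biostrings::writeXStringSet(x, path, format = "fastq",
                              qualities = Biostrings::BStringSet(qual),
                              compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Trim an index read to its informative 18 nt
#'
#' Index reads are sequenced at 20 nt; the final 2 nt carry no
#' information and are removed, leaving 8 nt of multiplex index plus
#' 10 nt of UMI. Inputs of exactly 18 nt pass through unchanged; longer
#' inputs are cut to their first 18 nt.
#'
#' @param index_seq,index_qual character vectors of index-read sequences
#'   and Phred+33 qualities (trimmed in register).
#' @return list with `seq` and `qual`, all 18 nt.
#' @export
trim_index_read <- function(index_seq, index_qual = NULL) {
  n <- nchar(index_seq)
  if (any(n < 18L)) stop("index reads shorter than 18 nt")
  out <- list(seq = substr(index_seq, 1L, 18L))
  if (!is.null(index_qual)) {
    if (any(nchar(index_qual) != n)) stop("quality strings out of register")
    out$qual <- substr(index_qual, 1L, 18L)
  }
  out
}

#' Split a trimmed index read into multiplex index and UMI
#'
#' The default layout places the 8-nt multiplex index before the 10-nt
#' UMI, following the structure of the RT oligo (priming site - index -
#' UMI). An `effective_index_len` shorter than `index_len` uses only the
#' leading bases of the index field for demultiplexing (the UMI
#' positions are unchanged); error-correction guarantees then depend on
#' the pairwise distance of the truncated index set.
#'
#' @param trimmed character vector of trimmed index reads.
#' @param layout `"index_first"` (default) or `"umi_first"`.
#' @param index_len,umi_len field widths; must sum to the read length.
#' @param effective_index_len number of index bases actually used
#'   (default `index_len`).
#' @return list with `index` and `umi` character vectors.
#' @export
split_index_umi <- function(trimmed, layout = c("index_first", "umi_first"),
                            index_len = 8L, umi_len = 10L,
                            effective_index_len = index_len) {
  layout <- match.arg(layout)
  n <- unique(nchar(trimmed))
  if (length(n) != 1L || n != index_len + umi_len)
    stop("trimmed reads must all have length index_len + umi_len")
  if (effective_index_len < 1L || effective_index_len > index_len)
    stop("effective_index_len must be in [1, index_len]")
  if (layout == "index_first") {
    idx <- substr(trimmed, 1L, index_len)
    umi <- substr(trimmed, index_len + 1L, index_len + umi_len)
  } else {
    umi <- substr(trimmed, 1L, umi_len)
    idx <- substr(trimmed, umi_len + 1L, umi_len + index_len)
  }
  list(index = substr(idx, 1L, effective_index_len), umi = umi)
}

UMI_SEP <- "_UMI:"

#' Embed a UMI in a read name / recover it
#'
#' The UMI travels with the read through alignment inside the read name,
#' appended as `_UMI:<seq>` to the first whitespace-delimited token of
#' the original header (SAM QNAMEs cannot contain whitespace, so only
#' that token survives alignment anyway).
#'
#' @param read_id original read header (anything after the first
#'   whitespace is dropped).
#' @param umi UMI sequence, `[ACGTN]+`.
#' @return `embed_umi_in_name()`: the combined name.
#'   `extract_umi_from_name()`: list with `read_id` and `umi`.
#' @export
embed_umi_in_name <- function(read_id, umi) {
  if (any(grepl("[^ACGTN]", umi))) stop("UMI must match [ACGTN]+")
  token <- sub("[ \t].*$", "", read_id)
  paste0(token, UMI_SEP, umi)
}

#' @param name read name carrying a UMI token.
#' @rdname embed_umi_in_name
#' @export
extract_umi_from_name <- function(name) {
  pos <- regexpr(UMI_SEP, name, fixed = TRUE)
  if (any(pos < 0L)) stop("read name lacks the _UMI: token")
  list(read_id = substr(name, 1L, pos - 1L),
       umi = substr(name, pos + nchar(UMI_SEP), nchar(name)))
}

# Phred+33 quality strings -> list of integer vectors, vectorised by
# grouping reads of equal length
phred_ints <- function(qual) {
  n <- nchar(qual)
  out <- vector("list", length(qual))
  for (len in unique(n)) {
    i <- which(n == len)
    if (len == 0L) { out[i] <- list(integer(0)); next }
    raw <- as.integer(charToRaw(paste(qual[i], collapse = ""))) - 33L
    m <- matrix(raw, nrow = len)
    out[i] <- lapply(seq_along(i), function(k) m[, k])
  }
  out
}

qtrim_keep_len <- function(q, trailing_q, window, window_q) {
  keep <- length(q)
  repeat {  # iterate trailing + window to a fixpoint, so the op is idempotent
    prev <- keep
    qq <- q[seq_len(keep)]
    keep <- if (any(qq >= trailing_q)) max(which(qq >= trailing_q)) else 0L
    if (keep == 0L) return(0L)
    if (keep >= window) {
      cs <- cumsum(q[seq_len(keep)])
      wmean <- (cs[window:keep] - c(0, cs[seq_len(keep - window)])) / window
      bad <- which(wmean < window_q)
      if (length(bad)) keep <- bad[1L] - 1L
    }
    if (keep == prev || keep == 0L) return(as.integer(keep))
  }
}

#' Quality-trim reads
#'
#' Reproduces the trailing-quality and sliding-window trimming commonly
#' applied to DGE read1 data: (1) remove 3' bases with quality below
#' `trailing_q`; (2) scan 5' to 3' with a window of `window` bases and
#' truncate at the start of the first window whose mean quality falls
#' below `window_q`; (3) drop reads shorter than `minlen` after
#' trimming. Defaults correspond to `TRAILING:20 SLIDINGWINDOW:4:15
#' MINLEN:30`. The operation never lengthens a read and is idempotent.
#'
#' @param seq,qual parallel character vectors.
#' @param trailing_q,window,window_q,minlen trimming parameters.
#' @return list with trimmed `seq` and `qual` and a logical `kept`
#'   marking reads that survived the `minlen` filter (dropped reads are
#'   returned trimmed but flagged `FALSE`).
#' @export
quality_trim <- function(seq, qual, trailing_q = 20L, window = 4L,
                         window_q = 15L, minlen = 30L) {
  n <- nchar(qual)
  if (any(nchar(seq) != n))
    stop("sequence and quality strings out of register")
  keep <- integer(length(qual))
  clear_q <- max(trailing_q, window_q)
  for (len in unique(n)) {
    i <- which(n == len)
    if (len == 0L) { keep[i] <- 0L; next }
    raw <- as.integer(charToRaw(paste(qual[i], collapse = ""))) - 33L
    if (min(raw) < 0L || max(raw) > 60L)
      stop("malformed quality string (outside Phred+33 range)")
    m <- matrix(raw, nrow = len)
    qmin <- do.call(pmin, lapply(seq_len(len), function(r) m[r, ]))
    ok <- qmin >= clear_q  # nothing to trim; skip the per-read scan
    keep[i[ok]] <- len
    for (k in which(!ok))
      keep[i[k]] <- qtrim_keep_len(m[, k], trailing_q, window, window_q)
  }
  list(seq = substr(seq, 1L, keep),
       qual = substr(qual, 1L, keep),
       kept = keep >= minlen)
}

#' Clip a 3' adapter
#'
#' Truncates each read at the start of the first full occurrence of the
#' adapter, or at a terminal match between the read's 3' end and a
#' prefix of the adapter of at least `min_overlap` bases. This is a
#' deliberate simplification of palindromic adapter clipping: DGE read1
#' data are single-end, so only read-through into the 3' adapter needs
#' removal.
#'
#' @param seq,qual parallel character vectors (`qual` optional).
#' @param adapter adapter sequence.
#' @param min_overlap minimum terminal prefix match length (default 7).
#' @return list with clipped `seq` (and `qual` if supplied).
#' @export
trim_adapter <- function(seq, adapter, qual = NULL, min_overlap = 7L) {
  if (!nzchar(adapter)) stop("adapter must be non-empty")
  n <- nchar(seq)
  cut <- n  # keep length
  hit <- regexpr(adapter, seq, fixed = TRUE)
  full <- hit > 0L
  cut[full] <- pmin(cut[full], hit[full] - 1L)
  alen <- nchar(adapter)
  if (alen - 1L >= min_overlap) {
    for (o in seq(from = alen - 1L, to = min_overlap, by = -1L)) {
      m <- n >= o & substr(seq, n - o + 1L, n) == substr(adapter, 1L, o)
      cut[m] <- pmin(cut[m], n[m] - o)
    }
  }
  out <- list(seq = substr(seq, 1L, cut))
  if (!is.null(qual)) out$qual <- substr(qual, 1L, cut)
  out
}

#' Demultiplex a read1 / index-read FASTQ pair
#'
#' The full front end of the tag-counting pipeline: index reads are
#' trimmed to 18 nt, split into multiplex index and UMI, decoded against
#' the index set with single-substitution error correction
#' ([assign_index()]), and the UMI is embedded into the read1 name.
#' Assigned reads are then optionally adapter-clipped, quality-trimmed
#' and length-filtered, and written to one FASTQ per sample.
#'
#' Reads whose UMI contains `N` are kept (and flagged in the returned
#' table); the counting stage discards them at UMI unification.
#'
#' @param read1_fastq,index_fastq paths to the positionally paired FASTQ
#'   files (equal record counts; ids checked on the first token).
#'   Alternatively, lists as returned by [read_fastq()].
#' @param set an [index_set()].
#' @param out_dir output directory for per-sample FASTQ files; `NULL`
#'   suppresses file output (the reads are still returned).
#' @param layout,effective_index_len,umi_len see [split_index_umi()].
#' @param max_correct substitutions corrected at index decoding.
#' @param adapter optional 3' adapter to clip ([trim_adapter()]).
#' @param trailing_q,window,window_q,minlen see [quality_trim()].
#' @param compress write `.fastq.gz` instead of `.fastq`.
#' @return list of class `demux_result`:
#'   * `report`: list with `total_pairs`, per-sample `assigned` counts,
#'     `unassigned`, `assigned_fraction`, and per-sample `written`
#'     counts (reads surviving trimming);
#'   * `reads`: `data.table` of assigned reads (`sample_id`, `name`,
#'     `seq`, `qual`, `umi`, `umi_has_n`, `kept`);
#'   * `files`: named vector of written file paths (if any).
#' @export
demultiplex <- function(read1_fastq, index_fastq, set, out_dir = NULL,
                        layout = "index_first", effective_index_len = NULL,
                        umi_len = 10L, max_correct = 1L, adapter = NULL,
                        trailing_q = 20L, window = 4L, window_q = 15L,
                        minlen = 30L, compress = FALSE) {
  stopifnot(inherits(set, "index_set"))
  r1 <- if (is.list(read1_fastq)) read1_fastq else read_fastq(read1_fastq)
  ir <- if (is.list(index_fastq)) index_fastq else read_fastq(index_fastq)
  if (length(r1$seq) != length(ir$seq))
    stop("read1 and index FASTQ have different record counts")
  if (length(r1$id)) {
    t1 <- sub("[ \t].*$", "", r1$id)
    t2 <- sub("[ \t].*$", "", ir$id)
    if (!identical(t1, t2)) stop("read1 and index FASTQ ids do not pair")
  }
  L <- attr(set, "index_length")
  if (is.null(effective_index_len)) effective_index_len <- L

  total <- length(r1$seq)
  samples <- set$sample_id
  if (total == 0L) {
    report <- list(total_pairs = 0L,
                   assigned = setNames(integer(length(samples)), samples),
                   unassigned = 0L, assigned_fraction = NA_real_,
                   written = setNames(integer(length(samples)), samples))
    return(structure(list(report = report,
                          reads = data.table(sample_id = character(),
                                             name = character(), seq = character(),
                                             qual = character(), umi = character(),
                                             umi_has_n = logical(), kept = logical()),
                          files = character(0)), class = "demux_result"))
  }

  tr <- trim_index_read(ir$seq, ir$qual)
  parts <- split_index_umi(tr$seq, layout = layout, index_len = L,
                           umi_len = umi_len,
                           effective_index_len = effective_index_len)
  dec_set <- set
  if (effective_index_len < L) {
    # decode against the truncated index set; distance (and therefore
    # the correction guarantee) may be lower than the full set's
    trunc <- substr(set$index_seq, 1L, effective_index_len)
    if (anyDuplicated(trunc))
      stop("effective_index_len collapses distinct indexes; cannot demultiplex")
    dec_set <- index_set(set$sample_id, trunc, min_distance = 1L)
  }
  sid <- assign_index(parts$index, dec_set, max_correct = max_correct)

  assigned <- table(factor(sid, levels = samples))
  report <- list(total_pairs = total,
                 assigned = setNames(as.integer(assigned), samples),
                 unassigned = sum(is.na(sid)),
                 assigned_fraction = sum(!is.na(sid)) / total)

  keep <- !is.na(sid)
  name <- embed_umi_in_name(r1$id[keep], parts$umi[keep])
  seqk <- r1$seq[keep]; qualk <- r1$qual[keep]
  if (!is.null(adapter)) {
    ad <- trim_adapter(seqk, adapter, qual = qualk)
    seqk <- ad$seq; qualk <- ad$qual
  }
  qt <- quality_trim(seqk, qualk, trailing_q = trailing_q, window = window,
                     window_q = window_q, minlen = minlen)
  umik <- parts$umi[keep]
  reads <- data.table(sample_id = sid[keep], name = name,
                      seq = qt$seq, qual = qt$qual, umi = umik,
                      umi_has_n = grepl("N", umik, fixed = TRUE),
                      kept = qt$kept)

  files <- character(0)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    ext <- if (compress) ".fastq.gz" else ".fastq"
    present <- unique(reads$sample_id[reads$kept])
    for (s in present) {
      sub <- reads[reads$sample_id == s & reads$kept, ]
      f <- file.path(out_dir, paste0(s, ext))
      write_fastq(sub$name, sub$seq, sub$qual, f)
      files[s] <- f
    }
  }
  wr <- reads[reads$kept, .N, by = "sample_id"]
  written <- setNames(integer(length(samples)), samples)
  written[wr$sample_id] <- wr$N
  report$written <- written

  structure(list(report = report, reads = reads, files = files),
            class = "demux_result")
}

#' @export
print.demux_result <- function(x, ...) {
  r <- x$report
  cat(sprintf("demultiplex: %d pairs, %d assigned (%.1f%%), %d unassigned\n",
              r$total_pairs, sum(r$assigned),
              100 * r$assigned_fraction, r$unassigned))
  invisible(x)
}

#' Write a demultiplexing report
#'
#' @param x a `demux_result` from [demultiplex()].
#' @param tsv,json optional output paths.
#' @export
write_demux_report <- function(x, tsv = NULL, json = NULL) {
  stopifnot(inherits(x, "demux_result"))
  r <- x$report
  if (!is.null(tsv)) {
    df <- data.frame(sample_id = names(r$assigned),
                     assigned = as.integer(r$assigned),
                     written = as.integer(r$written[names(r$assigned)]))
    fwrite(df, tsv, sep = "\t")
  }
  if (!is.null(json)) {
    jsonlite::write_json(r, json, auto_unbox = TRUE, digits = NA)
  }
  invisible(x)
}
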