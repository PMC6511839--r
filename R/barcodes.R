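#' Construct an index set
#'
#' An index set pairs sample identifiers with fixed-length DNA multiplex
#' index sequences and records the guaranteed minimum pairwise Hamming
#' distance of the set. A set with minimum distance `2e + 1` supports
#' correction of up to `e` substitution errors per index read.
#'
#' @param sample_id character vector of unique sample identifiers.
#' @param index_seq character vector of index sequences, all the same
#'   length, alphabet `A/C/G/T`.
#' @param min_distance claimed minimum pairwise Hamming distance; checked
#'   against the sequences when the set has two or more entries.
#' @return A `data.frame` of class `index_set` with columns `sample_id`
#'   and `index_seq` and attributes `index_length` and `min_distance`.
#' @seealso [design_indexes()], [assign_index()], [read_index_table()]
#' @export
index_set <- function(sample_id, index_seq, min_distance = 1L) {
  sample_id <- as.character(sample_id)
  index_seq <- toupper(as.character(index_seq))
  if (length(sample_id) != length(index_seq))
    stop("sample_id and index_seq must have equal length")
  if (anyDuplicated(sample_id))
    stop("sample_id values must be unique")
  if (anyDuplicated(index_seq))
    stop("index sequences must be unique")
  L <- unique(nchar(index_seq))
  if (length(L) != 1L)
    stop("all index sequences must have identical length")
  if (any(grepl("[^ACGT]", index_seq)))
    stop("index sequences must use only A, C, G, T")
  min_distance <- as.integer(min_distance)
  if (length(index_seq) >= 2L) {
    d <- min_pairwise_hamming_seqs(index_seq)
    if (d < min_distance)
      stop(sprintf("observed minimum pairwise distance %d < claimed %d",
                   d, min_distance))
  }
  out <- data.frame(sample_id = sample_id, index_seq = index_seq,
                    stringsAsFactors = FALSE)
  attr(out, "index_length") <- as.integer(L)
  attr(out, "min_distance") <- min_distance
  class(out) <- c("index_set", "data.frame")
  out
}

#' @export
print.index_set <- function(x, ...) {
  cat(sprintf("index_set: %d indexes of length %d, min pairwise Hamming >= %d\n",
              nrow(x), attr(x, "index_length"), attr(x, "min_distance")))
  print.data.frame(head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat(sprintf("... and %d more\n", nrow(x) - 6L))
  invisible(x)
}

# substitution patterns reaching every word within Hamming distance
# <= radius: a matrix of digit offsets (0 = keep, 1..3 = rotate base)
.ball_patterns <- function(length, radius) {
  rows <- list(matrix(0L, nrow = 1L, ncol = length))
  if (radius >= 1L) {
    for (k in seq_len(radius)) {
      pos <- combn(length, k)
      deltas <- as.matrix(expand.grid(rep(list(1:3), k)))
      for (j in seq_len(ncol(pos))) {
        block <- matrix(0L, nrow = nrow(deltas), ncol = length)
        block[, pos[, j]] <- deltas
        rows[[length(rows) + 1L]] <- block
      }
    }
  }
  do.call(rbind, rows)
}

.DNA_BASES <- c("A", "C", "G", "T")

.word_to_digits <- function(w, L) {
  # base-4 digits, most significant first (lexicographic order A<C<G<T)
  as.integer((w %/% 4^((L - 1L):0L)) %% 4)
}

.digits_to_seq <- function(dmat) {
  apply(dmat, 1L, function(d) paste(.DNA_BASES[d + 1L], collapse = ""))
}

.has_homopolymer <- function(dmat, run) {
  if (ncol(dmat) < run) return(rep(FALSE, nrow(dmat)))
  hit <- rep(FALSE, nrow(dmat))
  for (s in seq_len(ncol(dmat) - run + 1L)) {
    block <- dmat[, s:(s + run - 1L), drop = FALSE]
    hit <- hit | (matrixStats_rowAllEqual(block))
  }
  hit
}

matrixStats_rowAllEqual <- function(m) {
  if (ncol(m) == 1L) return(rep(TRUE, nrow(m)))
  out <- rep(TRUE, nrow(m))
  for (j in 2L:ncol(m)) out <- out & (m[, j] == m[, 1L])
  out
}

#' Design multiplex indexes by greedy lexicographic scan
#'
#' Scans all `4^length` DNA words in lexicographic order (`A < C < G <
#' T`) and retains each word whose Hamming distance to every previously
#' retained word is at least `min_distance`. The construction is fully
#' deterministic, so a given parameter triple always yields the same
#' code. With `min_distance = 3` the resulting set corrects any single
#' substitution error at decoding time ([assign_index()]).
#'
#' The scan is implemented by sphere elimination: each retained word
#' marks every word within distance `min_distance - 1` as unusable,
#' which is equivalent to the pairwise-distance test but linear in the
#' number of retained words.
#'
#' @param count number of indexes required, or `Inf` to exhaust the scan
#'   and return the maximal greedy code.
#' @param length index length in nucleotides (default 8; limited to 12).
#' @param min_distance required minimum pairwise Hamming distance
#'   (default 3).
#' @param forbid_homopolymer reject candidate words containing a
#'   homopolymer run of this length or more; `NULL` (default) disables
#'   the filter.
#' @return An [index_set()] with `count` entries (sample ids
#'   `S001, S002, ...`), or the maximal set when `count = Inf`.
#'   Errors if the scan exhausts all words before reaching `count`.
#' @examples
#' idx <- design_indexes(12)
#' min_pairwise_hamming(idx)
#' @export
design_indexes <- function(count, length = 8L, min_distance = 3L,
                           forbid_homopolymer = NULL) {
  if (!is.infinite(count)) {
    count <- as.integer(count)
    if (is.na(count) || count < 1L) stop("count must be >= 1")
  }
  length <- as.integer(length)
  min_distance <- as.integer(min_distance)
  if (length < 1L) stop("length must be >= 1")
  if (length > 12L) stop("index length > 12 not supported by the exhaustive scan")
  if (min_distance < 1L || min_distance > length)
    stop("min_distance must be in [1, length]")

  n_words <- 4L^length
  alive <- rep(TRUE, n_words)
  if (!is.null(forbid_homopolymer)) {
    run <- as.integer(forbid_homopolymer)
    if (run < 2L) stop("forbid_homopolymer must be >= 2")
    dall <- t(vapply(0:(n_words - 1L), .word_to_digits, integer(length), L = length))
    alive[.has_homopolymer(dall, run)] <- FALSE
  }

  pat <- .ball_patterns(length, min_distance - 1L)
  pow4 <- 4L^((length - 1L):0L)
  kept <- integer(0)
  w <- 0L
  while (w < n_words && length(kept) < count) {
    if (alive[w + 1L]) {
      kept <- c(kept, w)
      d <- .word_to_digits(w, length)
      dmat <- matrix(d, nrow = nrow(pat), ncol = length, byrow = TRUE)
      nb <- ((dmat + pat) %% 4L - dmat) %*% pow4 + w
      alive[nb + 1L] <- FALSE
    }
    w <- w + 1L
  }
  if (!is.infinite(count) && length(kept) < count)
    stop(sprintf(
      "capacity error: only %d indexes of length %d at distance >= %d exist under the constraints (requested %d)",
      length(kept), length, min_distance, count))

  dmat <- t(vapply(kept, .word_to_digits, integer(length), L = length))
  seqs <- .digits_to_seq(dmat)
  index_set(sprintf("S%03d", seq_along(seqs)), seqs, min_distance = min_distance)
}

min_pairwise_hamming_seqs <- function(seqs) {
  n <- length(seqs)
  L <- nchar(seqs[1L])
  m <- matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
              nrow = n, byrow = TRUE)
  # Hamming distance = L - number of agreeing positions; agreement counts
  # accumulate over the four one-hot indicator matrices
  agree <- matrix(0, n, n)
  for (b in c("A", "C", "G", "T")) {
    ind <- (m == b) * 1
    agree <- agree + tcrossprod(ind)
  }
  d <- L - agree
  as.integer(min(d[upper.tri(d)]))
}

#' Minimum pairwise Hamming distance of an index set
#'
#' @param set an [index_set()] (or a character vector of equal-length
#'   sequences).
#' @return Integer, the minimum Hamming distance over all unordered
#'   pairs.
#' @export
min_pairwise_hamming <- function(set) {
  seqs <- if (inherits(set, "index_set")) set$index_seq else as.character(set)
  if (length(seqs) < 2L) stop("need at least 2 sequences")
  if (length(unique(nchar(seqs))) != 1L) stop("sequences differ in length")
  min_pairwise_hamming_seqs(seqs)
}

#' Decode observed index reads with error correction
#'
#' Assigns each observed index sequence to the unique sample whose index
#' lies within Hamming distance `max_correct`. `N` bases mismatch every
#' base. If no index qualifies, or two or more indexes tie at the
#' minimal qualifying distance, the read is left unassigned (`NA`):
#' mis-assignment is considered worse than loss.
#'
#' @param observed character vector of observed index sequences (may
#'   contain `N`), each the same length as the set's indexes.
#' @param set an [index_set()].
#' @param max_correct maximum number of substitutions corrected (default
#'   1; 0 means exact matching only).
#' @return Character vector of sample ids, `NA` where unassigned.
#' @export
assign_index <- function(observed, set, max_correct = 1L) {
  stopifnot(inherits(set, "index_set"))
  observed <- toupper(as.character(observed))
  L <- attr(set, "index_length")
  if (any(nchar(observed) != L))
    stop(sprintf("observed sequences must have length %d", L))
  max_correct <- as.integer(max_correct)

  out <- set$sample_id[match(observed, set$index_seq)]
  miss <- which(is.na(out) )
  if (length(miss) == 0L || max_correct == 0L) return(out)

  om <- matrix(unlist(strsplit(observed[miss], "", fixed = TRUE),
                      use.names = FALSE), ncol = L, byrow = TRUE)
  nidx <- nrow(set)
  dmin <- rep(L + 1L, length(miss))
  nmin <- integer(length(miss))
  best <- integer(length(miss))
  for (j in seq_len(nidx)) {
    ref <- strsplit(set$index_seq[j], "", fixed = TRUE)[[1L]]
    dj <- rowSums(om != matrix(ref, nrow = nrow(om), ncol = L, byrow = TRUE))
    better <- dj < dmin
    tie <- dj == dmin
    best[better] <- j
    nmin[better] <- 1L
    nmin[tie] <- nmin[tie] + 1L
    dmin[better] <- dj[better]
  }
  ok <- dmin <= max_correct & nmin == 1L
  out[miss[ok]] <- set$sample_id[best[ok]]
  out
}

#' Read / write an index table
#'
#' Tab-separated table with two columns, `sample_id` and `index_seq`.
#' Lines beginning with `#` are ignored; a header row is optional and
#' detected by the literal column name `sample_id`.
#'
#' @param path file path.
#' @param min_distance distance claim recorded on the returned set
#'   (validated against the sequences).
#' @return [read_index_table()] returns an [index_set()].
#' @export
read_index_table <- function(path, min_distance = 1L) {
  ln <- readLines(path)
  ln <- ln[!grepl("^#", ln) & nzchar(ln)]
  if (length(ln) && grepl("^sample_id\t", ln[1L])) ln <- ln[-1L]
  parts <- strsplit(ln, "\t", fixed = TRUE)
  if (any(lengths(parts) < 2L)) stop("malformed index table: expected 2 tab-separated columns")
  index_set(vapply(parts, `[[`, "", 1L), vapply(parts, `[[`, "", 2L),
            min_distance = min_distance)
}

#' @param set an [index_set()] to write.
#' @rdname read_index_table
#' @export
write_index_table <- function(set, path) {
  stopifnot(inherits(set, "index_set"))
  writeLines(c("sample_id\tindex_seq",
               paste(set$sample_id, set$index_seq, sep = "\t")), path)
  invisible(path)
}
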