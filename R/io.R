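#' Read / write a UMI count matrix as TSV
#'
#' Genes as rows (first column `gene_id`), samples as columns.
#'
#' @param x a `umi_counts` object or count matrix.
#' @param path file path.
#' @export
write_count_matrix <- function(x, path) {
  m <- .counts_of(x)
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  fwrite(df, path, sep = "\t")
  invisible(path)
}

#' @rdname write_count_matrix
#' @return [read_count_matrix()] returns an integer matrix with gene
#'   rownames.
#' @export
read_count_matrix <- function(path) {
  dt <- fread(path, sep = "\t")
  m <- as.matrix(dt[, -1L])
  rownames(m) <- dt[[1L]]
  storage.mode(m) <- "integer"
  m
}

#' Write per-sample statistics as TSV
#'
#' @param x a `umi_counts` object.
#' @param path file path.
#' @export
write_sample_stats <- function(x, path) {
  stopifnot(inherits(x, "umi_counts"))
  fwrite(x$samples, path, sep = "\t")
  invisible(path)
}

#' Export a count matrix as MatrixMarket triple
#'
#' Writes `matrix.mtx`, `genes.tsv` and `samples.tsv` into `dir`.
#'
#' @param x a `umi_counts` object or count matrix.
#' @param dir output directory.
#' @export
write_mtx <- function(x, dir) {
  m <- .counts_of(x)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sp <- Matrix::Matrix(m, sparse = TRUE)
  Matrix::writeMM(sp, file.path(dir, "matrix.mtx"))
  writeLines(rownames(m), file.path(dir, "genes.tsv"))
  writeLines(colnames(m), file.path(dir, "samples.tsv"))
  invisible(dir)
}

#' Write a differential expression table as TSV
#'
#' @param de a `de_result` from [call_degs()].
#' @param path file path.
#' @export
write_de_table <- function(de, path) {
  stopifnot(inherits(de, "de_result"))
  fwrite(as.data.frame(de)[order(de$rank), ], path, sep = "\t")
  invisible(path)
}
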