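test_that("index-read trimming keeps the first 18 nt", {
  tr <- trim_index_read("ACGTACGTAACCGGTTAATT", strrep("I", 20))
  expect_equal(tr$seq, "ACGTACGTAACCGGTTAA")
  expect_equal(nchar(tr$qual), 18L)
  expect_equal(trim_index_read(strrep("A", 18))$seq, strrep("A", 18))
  expect_error(trim_index_read(strrep("A", 17)), "shorter than 18")
})

test_that("index/UMI split honours layout and effective length", {
  t18 <- paste0(strrep("A", 8), strrep("C", 10))
  sp <- split_index_umi(t18)
  expect_equal(sp$index, strrep("A", 8))
  expect_equal(sp$umi, strrep("C", 10))
  sp2 <- split_index_umi(t18, layout = "umi_first")
  expect_equal(sp2$umi, paste0(strrep("A", 8), "CC"))
  expect_equal(sp2$index, strrep("C", 8))
  # 6-bp effective mode: leading index bases, UMI positions unchanged
  sp6 <- split_index_umi(t18, effective_index_len = 6)
  expect_equal(sp6$index, strrep("A", 6))
  expect_equal(sp6$umi, strrep("C", 10))
  expect_error(split_index_umi(strrep("A", 17)), "length")
})

test_that("UMI name embedding round-trips and is SAM-safe", {
  nm <- embed_umi_in_name("r1", "ACGTACGTAC")
  expect_equal(nm, "r1_UMI:ACGTACGTAC")
  back <- extract_umi_from_name(nm)
  expect_equal(back$read_id, "r1")
  expect_equal(back$umi, "ACGTACGTAC")
  # whitespace: only the first token survives (QNAME rule)
  nm2 <- embed_umi_in_name("M01234:55:000-AB 1:N:0:1", "NNACGTACGT")
  expect_false(grepl("[ \t]", nm2))
  expect_equal(extract_umi_from_name(nm2)$read_id, "M01234:55:000-AB")
  expect_error(extract_umi_from_name("r1"), "_UMI:")
  expect_error(embed_umi_in_name("r1", "ACGTACGTAX"), "ACGTN")
})

test_that("quality trimming implements trailing, sliding-window and minlen rules", {
  q40 <- strrep("I", 80)
  r <- quality_trim(strrep("A", 80), q40)
  expect_equal(nchar(r$seq), 80L)
  expect_true(r$kept)

  # last base Q10 (+) removed by TRAILING:20
  q <- paste0(strrep("I", 79), "+")
  r2 <- quality_trim(strrep("A", 80), q)
  expect_equal(nchar(r2$seq), 79L)

  # a low-quality window truncates from its start: the first window
  # whose mean drops below 15 starts at base 40 (I + 3 x '#')
  q3 <- paste0(strrep("I", 40), strrep("#", 10), strrep("I", 30))
  r3 <- quality_trim(strrep("A", 80), q3)
  expect_equal(nchar(r3$seq), 39L)

  # reads ending below 30 nt are dropped
  r4 <- quality_trim(strrep("A", 29), strrep("I", 29))
  expect_false(r4$kept)
})

test_that("quality trimming never lengthens and is idempotent", {
  set.seed(9)
  n <- 60
  seqs <- vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), 50, TRUE), collapse = ""), "")
  quals <- vapply(seq_len(n), function(i)
    rawToChar(as.raw(sample(33:73, 50, TRUE))), "")
  r1 <- quality_trim(seqs, quals)
  expect_true(all(nchar(r1$seq) <= 50))
  r2 <- quality_trim(r1$seq[nchar(r1$seq) > 0], r1$qual[nchar(r1$seq) > 0])
  expect_identical(r2$seq, r1$seq[nchar(r1$seq) > 0])
})

test_that("adapter clipping removes full hits and terminal prefixes only", {
  ad <- "AGATCGGAAGAGC"
  expect_equal(trim_adapter(paste0("CCCC", ad, "TTTT"), ad)$seq, "CCCC")
  # terminal 7-nt prefix
  expect_equal(trim_adapter(paste0(strrep("C", 20), substr(ad, 1, 7)), ad)$seq,
               strrep("C", 20))
  # 6-nt terminal prefix is below the overlap threshold
  r <- paste0(strrep("C", 20), substr(ad, 1, 6))
  expect_equal(trim_adapter(r, ad)$seq, r)
  expect_equal(trim_adapter("ACGTACGT", ad)$seq, "ACGTACGT")
  expect_error(trim_adapter("ACGT", ""), "non-empty")
})

test_that("demultiplexing assigns every pair exactly once and conserves counts", {
  sim <- tiny_sim(seed = 7, n_cells = 3, n_genes = 20, total_molecules = 400)
  dx <- demultiplex(sim$read1, sim$index, sim$index_set)
  r <- dx$report
  expect_equal(sum(r$assigned) + r$unassigned, r$total_pairs)
  expect_equal(r$assigned_fraction, 1)  # error-free indexes
  expect_true(all(grepl("_UMI:[ACGTN]{10}$", dx$reads$name)))
})

test_that("single-substitution index errors are fully corrected at demux", {
  sim <- tiny_sim(seed = 8, n_cells = 4, n_genes = 10, total_molecules = 150)
  # corrupt every index read with exactly one substitution in the index field
  idx <- sim$index$seq
  set.seed(1)
  pos <- sample(8, length(idx), TRUE)
  for (i in seq_along(idx)) {
    old <- substr(idx[i], pos[i], pos[i])
    substr(idx[i], pos[i], pos[i]) <- sample(setdiff(c("A", "C", "G", "T"), old), 1)
  }
  sim$index$seq <- idx
  dx <- demultiplex(sim$read1, sim$index, sim$index_set)
  expect_equal(dx$report$assigned_fraction, 1)
  # assignments equal the simulated cell of origin
  truth_cell <- sim$truth$reads$cell[match(
    extract_umi_from_name(dx$reads$name)$read_id, sim$truth$reads$read_id)]
  expect_identical(dx$reads$sample_id, truth_cell)
})

test_that("demultiplexing empty input and mismatched pairing behave", {
  s <- design_indexes(2, 8, 3)
  empty <- list(id = character(0), seq = character(0), qual = character(0))
  dx <- demultiplex(empty, empty, s)
  expect_equal(dx$report$total_pairs, 0L)
  expect_equal(length(dx$files), 0L)

  one <- list(id = "r1", seq = "ACGT", qual = "IIII")
  expect_error(demultiplex(one, empty, s), "record counts")
  two <- list(id = "rX", seq = strrep("A", 20), qual = strrep("I", 20))
  expect_error(demultiplex(one, two, s), "pair")
})

test_that("per-sample FASTQ files round-trip through disk", {
  sim <- tiny_sim(seed = 10, n_cells = 2, n_genes = 10, total_molecules = 100)
  dir <- tempfile()
  dx <- demultiplex(sim$read1, sim$index, sim$index_set, out_dir = dir)
  expect_true(all(file.exists(dx$files)))
  back <- read_fastq(dx$files[1])
  expect_equal(length(back$seq), unname(dx$report$written[names(dx$files)[1]]))
  expect_true(all(grepl("_UMI:", back$id)))
  expect_equal(unname(nchar(back$seq)), unname(nchar(back$qual)))
})
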