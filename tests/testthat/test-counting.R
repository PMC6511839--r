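# hand-built SAM fixtures for alignment-resolution tests
write_sam <- function(records, refs = c(t1 = 100L, t2 = 100L, t3 = 100L)) {
  f <- tempfile(fileext = ".sam")
  writeLines(c("@HD\tVN:1.6",
               sprintf("@SQ\tSN:%s\tLN:%d", names(refs), refs),
               records), f)
  f
}
rec <- function(qname, rname, pos, flag = 0L) {
  if (flag == 4L)
    sprintf("%s\t4\t*\t0\t0\t*\t*\t0\t0\tACGTACGTAC\t*", qname)
  else
    sprintf("%s\t%d\t%s\t%d\t255\t10M\t*\t0\t0\tACGTACGTAC\t*", qname, flag, rname, pos)
}
T2G <- c(t1 = "g1", t2 = "g1", t3 = "g2")

test_that("alignments resolve to genes; same-gene multi-transcripts collapse", {
  sam <- write_sam(c(rec("r1_UMI:AAAAAAAAAA", "t1", 5)))
  pa <- parse_alignments(sam, T2G)
  expect_equal(nrow(pa$assignments), 1L)
  expect_equal(pa$assignments$gene_id, "g1")
  expect_equal(pa$assignments$pos, 5L)
  expect_equal(pa$assignments$umi, "AAAAAAAAAA")

  sam2 <- write_sam(c(rec("r1_UMI:AAAAAAAAAA", "t1", 5),
                      rec("r1_UMI:AAAAAAAAAA", "t2", 9)))
  pa2 <- parse_alignments(sam2, T2G)
  expect_equal(nrow(pa2$assignments), 1L)
  expect_equal(pa2$assignments$gene_id, "g1")
})

test_that("multigene reads follow the multimap policy", {
  sam <- write_sam(c(rec("r1_UMI:AAAAAAAAAA", "t1", 5),
                     rec("r1_UMI:AAAAAAAAAA", "t3", 2)))
  pa <- parse_alignments(sam, T2G, multimap_policy = "discard")
  expect_equal(nrow(pa$assignments), 0L)
  expect_equal(pa$n_multigene_discarded, 1L)

  pa_first <- parse_alignments(sam, T2G, multimap_policy = "first")
  expect_equal(nrow(pa_first$assignments), 1L)
  expect_equal(pa_first$assignments$gene_id, "g1")  # t1 < t3

  pa_all <- parse_alignments(sam, T2G, multimap_policy = "all")
  expect_setequal(pa_all$assignments$gene_id, c("g1", "g2"))
})

test_that("unmapped records are counted but yield no assignment", {
  sam <- write_sam(c(rec("r1_UMI:AAAAAAAAAA", "t1", 1),
                     rec("r2_UMI:CCCCCCCCCC", NA, 0, flag = 4L)))
  pa <- parse_alignments(sam, T2G)
  expect_equal(pa$n_unmapped, 1L)
  expect_equal(pa$mapped_reads, 1L)
})

test_that("unknown references and missing UMI tokens are errors", {
  sam <- write_sam(rec("r1_UMI:AAAAAAAAAA", "t9", 1), refs = c(t9 = 50L))
  expect_error(parse_alignments(sam, T2G), "absent from the transcript-to-gene map")
  sam2 <- write_sam(rec("r1", "t1", 1))
  expect_error(parse_alignments(sam2, T2G), "_UMI:")
})

test_that("UMI unification collapses by gene x UMI only", {
  a <- data.frame(read_id = c("r1", "r2", "r3", "r4", "r5"),
                  umi = c("AAAAAAAAAA", "AAAAAAAAAA", "AAAAAAAAAA",
                          "AAAAAAAAAA", "CCCCCCCCCC"),
                  gene_id = c("g1", "g1", "g1", "g2", "g1"),
                  transcript_id = "t", pos = 1L)
  u <- unify_umis(a, seed = 3)
  expect_equal(u$counts[["g1"]], 2L)  # two distinct UMIs on g1
  expect_equal(u$counts[["g2"]], 1L)  # same UMI, different gene: independent
  # representative comes from within the group
  rep1 <- u$representatives[u$representatives$gene_id == "g1" &
                            u$representatives$umi == "AAAAAAAAAA", ]
  expect_true(rep1$read_id %in% c("r1", "r2", "r3"))
})

test_that("unification counts are seed-invariant; UMIs with N are discarded", {
  set.seed(2)
  a <- data.frame(read_id = sprintf("r%03d", 1:300),
                  umi = sample(c("AAAAAAAAAA", "CCCCCCCCCC", "GGGGGGGGGG"), 300, TRUE),
                  gene_id = sample(c("g1", "g2"), 300, TRUE),
                  transcript_id = "t", pos = 1L)
  u1 <- unify_umis(a, seed = 1)
  u2 <- unify_umis(a, seed = 999)
  expect_identical(u1$counts[sort(names(u1$counts))],
                   u2$counts[sort(names(u2$counts))])

  an <- rbind(a, data.frame(read_id = "rN", umi = "AAAAANAAAA", gene_id = "g1",
                            transcript_id = "t", pos = 1L))
  un <- unify_umis(an, seed = 1)
  expect_equal(un$n_umi_n_dropped, 1L)
  expect_identical(un$counts[sort(names(un$counts))],
                   u1$counts[sort(names(u1$counts))])

  expect_equal(unify_umis(a[0, ], seed = 1)$n_umi, 0L)
})

test_that("matrix assembly computes the per-sample statistics from their definitions", {
  u <- list(
    sA = list(counts = c(g1 = 3L, g2 = 1L), n_reads = 10L),
    sB = list(counts = c(g2 = 2L), n_reads = 5L))
  m <- build_matrix(u, gene_universe = c("g1", "g2", "g3"))
  expect_equal(dim(m), c(3L, 2L))
  expect_equal(m$counts["g3", "sA"], 0L)
  st <- m$samples
  expect_equal(st$umi_counts, c(4L, 2L))
  expect_equal(st$umi_unified_rate, c((10 - 4) / 10, (5 - 2) / 5))
  expect_equal(st$detected_genes, c(2L, 1L))

  expect_error(build_matrix(setNames(u, c("sA", "sA")), c("g1", "g2")),
               "duplicate")
})

test_that("toy aligner reports leftmost k-mer hits, multi-hits and unmapped reads", {
  ref <- c(tA = paste0(strrep("A", 5), strrep("CGT", 20)),
           tB = paste0(strrep("G", 40), strrep("A", 5), strrep("T", 20)))
  # read equal to a prefix of tA maps at position 1
  sam <- toy_align("r1_UMI:AAAAAAAAAA", substr(ref["tA"], 1, 40), ref, k = 31)
  ln <- readLines(sam)
  hit <- strsplit(grep("^r1", ln, value = TRUE), "\t")[[1]]
  expect_equal(hit[c(3, 4)], c("tA", "1"))

  # a shared leading k-mer yields one record per transcript
  shared <- paste0(strrep("A", 5), strrep("C", 26))
  ref2 <- c(x1 = paste0(shared, strrep("G", 20)), x2 = paste0(strrep("T", 10), shared))
  sam2 <- toy_align("r2_UMI:AAAAAAAAAA", paste0(shared, "GGGG"), ref2, k = 31)
  recs <- grep("^r2", readLines(sam2), value = TRUE)
  expect_equal(length(recs), 2L)
  pos2 <- vapply(strsplit(recs, "\t"), function(x) as.integer(x[4]), integer(1))
  expect_setequal(pos2, c(1L, 11L))

  # absent k-mer: unmapped flag
  sam3 <- toy_align("r3_UMI:AAAAAAAAAA", strrep("CA", 20), ref, k = 31)
  rec3 <- strsplit(grep("^r3", readLines(sam3), value = TRUE), "\t")[[1]]
  expect_equal(rec3[2], "4")

  expect_error(toy_align("r", strrep("A", 40), c(a = "ACGT", a = "ACGT")), "unique")
  expect_error(toy_align("r", "ACGT", c(a = strrep("A", 40))), "at least k")
})

test_that("PCR duplication leaves UMI counts invariant while scaling mapped reads", {
  sim <- tiny_sim(seed = 21, n_cells = 3, n_genes = 30, total_molecules = 600)
  t2g <- sim_t2g(sim)
  ref <- sim_ref_all(sim)
  dx <- demultiplex(sim$read1, sim$index, sim$index_set)
  uc1 <- count_samples(dx, t2g, reference = ref, seed = 5)

  m <- 3L
  dup <- function(v) rep(v, each = m)
  r1 <- list(id = paste0(dup(sim$read1$id), ".", seq_len(m)),
             seq = dup(sim$read1$seq), qual = dup(sim$read1$qual))
  ir <- list(id = paste0(dup(sim$index$id), ".", seq_len(m)),
             seq = dup(sim$index$seq), qual = dup(sim$index$qual))
  dx2 <- demultiplex(r1, ir, sim$index_set)
  uc2 <- count_samples(dx2, t2g, reference = ref, seed = 5)

  expect_identical(uc1$counts, uc2$counts)
  expect_equal(uc2$samples$mapped_reads, m * uc1$samples$mapped_reads)
})

test_that("full accounting: reads split into assigned/unmapped/multigene buckets", {
  sim <- tiny_sim(seed = 13, n_cells = 2, n_genes = 15, total_molecules = 300)
  dx <- demultiplex(sim$read1, sim$index, sim$index_set)
  surv <- as.data.frame(dx$reads)
  surv <- surv[surv$kept, ]
  t2g <- sim_t2g(sim)
  ref <- sim_ref_all(sim)
  total_acc <- 0L
  for (s in unique(surv$sample_id)) {
    sub <- surv[surv$sample_id == s, ]
    pa <- parse_alignments(toy_align(sub$name, sub$seq, ref), t2g)
    expect_equal(pa$mapped_reads + pa$n_unmapped + pa$n_multigene_discarded,
                 nrow(sub))
    total_acc <- total_acc + nrow(sub)
  }
  expect_equal(total_acc + sum(!dx$reads$kept) + dx$report$unassigned,
               dx$report$total_pairs)
})
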