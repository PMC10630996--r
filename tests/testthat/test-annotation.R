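gtf_line <- function(chrom, start1, end1, strand, gene, tx) {
  sprintf('%s\tsrc\texon\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s";',
          chrom, start1, end1, strand, gene, tx)
}

test_that("parse_gtf reads exon features into transcript models", {
  f <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c(gtf_line("chr1", 101, 200, "+", "gA", "tA"),
               gtf_line("chr1", 301, 400, "+", "gA", "tA"),
               gtf_line("chr1", 501, 650, "+", "gA", "tA")), f)
  models <- parse_gtf(f)
  expect_length(models, 1)
  m <- models[["tA"]]
  expect_s3_class(m, "TranscriptModel")
  expect_equal(nrow(m$exons), 3)
  # 1-based closed GTF converted to 0-based half-open
  expect_equal(m$exons$start, c(100L, 300L, 500L))
  expect_equal(m$exons$end, c(200L, 400L, 650L))
})

test_that("minus-strand exons are stored 5' to 3' (descending genomic order)", {
  f <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c(gtf_line("chr1", 101, 200, "-", "gB", "tB"),
               gtf_line("chr1", 301, 400, "-", "gB", "tB")), f)
  m <- parse_gtf(f)[["tB"]]
  expect_equal(m$exons$start, c(300L, 100L))
})

test_that("malformed GTF lines are reported with their line number", {
  f <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c(gtf_line("chr1", 101, 200, "+", "gA", "tA"),
               "chr1\tbroken line"), f)
  expect_error(parse_gtf(f), "line 2")
})

test_that("written GTF round-trips through the parser", {
  cfg <- sim_config(n_genes = 8, seed = 5)
  sim <- build_toy_genome(cfg)
  f <- withr::local_tempfile(fileext = ".gtf")
  write_gtf(sim$models, f)
  back <- parse_gtf(f)
  expect_setequal(names(back),
                  vapply(sim$models, function(m) m$transcript_id, ""))
  for (m in sim$models) {
    b <- back[[m$transcript_id]]
    expect_equal(b$gene_id, m$gene_id)
    expect_equal(b$strand, m$strand)
    expect_equal(b$exons, m$exons)
  }
})

test_that("representative transcript: exon count, then exonic length, then id", {
  mk <- function(tx, starts, ends)
    transcript_model("g1", tx, "chr1", "+", starts, ends)
  t1 <- mk("T1", c(0, 500, 1000), c(400, 900, 1400))        # 3 exons, 1200 nt
  t2 <- mk("T2", c(0, 6000), c(2500, 8500))                 # 2 exons, 5000 nt
  expect_equal(select_representative(list(t1, t2))$transcript_id, "T1")
  t3 <- mk("T2", c(0, 500, 1000), c(500, 1000, 1500))       # 3 exons, 1500 nt
  expect_equal(select_representative(list(t1, t3))$transcript_id, "T2")
  t4 <- mk("T1", c(0, 500), c(400, 900))                    # 2 exons, 800 nt
  t5 <- mk("T2", c(0, 500), c(400, 900))
  expect_equal(select_representative(list(t4, t5))$transcript_id, "T1")
  expect_error(select_representative(list()), "empty")
})

test_that("representative selection is invariant under input permutation", {
  set.seed(11)
  mods <- lapply(1:6, function(i)
    transcript_model("gP", paste0("tx", i), "chr1", "+",
                     c(0, 200, 400)[seq_len(1 + i %% 3)],
                     c(100 + 10 * i, 300, 500)[seq_len(1 + i %% 3)]))
  ref <- select_representative(mods)$transcript_id
  for (k in 1:10)
    expect_equal(select_representative(sample(mods))$transcript_id, ref)
})

test_that("exon classification covers first/internal/last/single", {
  m5 <- transcript_model("g1", "t1", "chr1", "+",
                         seq(0, 4000, 1000), seq(200, 4200, 1000))
  expect_equal(classify_exons(m5)$cls,
               c("first", "internal", "internal", "internal", "last"))
  m1 <- transcript_model("g2", "t2", "chr1", "-", 0, 300)
  expect_equal(classify_exons(m1)$cls, "single")
  m2 <- transcript_model("g3", "t3", "chr1", "-", c(0, 500), c(200, 800))
  expect_equal(classify_exons(m2)$cls, c("first", "last"))
  expect_equal(sum(classify_exons(m5)$cls == "internal"), 3)
})

test_that("relative positions count upstream from the junction-side boundary", {
  exp_plus <- toy_exon(100, 200, "+")
  expect_equal(relative_position(173, exp_plus), -27L)
  expect_equal(relative_position(199, exp_plus), -1L)
  expect_error(relative_position(200, exp_plus), "outside")
  exm <- toy_exon(100, 200, "-")
  expect_equal(relative_position(126, exm), -27L)
})

test_that("minus-strand relative position matches counting along the reversed sequence", {
  # place a marked base and verify it sits 27 from the 3' end of the
  # reverse-complemented exon sequence
  plus <- paste(rep("A", 300), collapse = "")
  substr(plus, 127, 127) <- "G"     # 0-based position 126
  genome <- Biostrings::DNAStringSet(c(chr1 = plus))
  exon_seq <- Biostrings::reverseComplement(
    Biostrings::subseq(genome[["chr1"]], 101, 200))   # exon [100,200) on '-'
  s <- as.character(exon_seq)
  # base at relative position -27 is the 27th from the 3' end
  expect_equal(substr(s, nchar(s) - 27 + 1, nchar(s) - 27 + 1), "C")
  expect_equal(relative_position(126, toy_exon(100, 200, "-")), -27L)
})

test_that("junction-adjacent base is -1 and 5'-most base is -length on both strands", {
  set.seed(21)
  for (i in 1:40) {
    st <- sample(0:5000, 1)
    len <- sample(30:400, 1)
    strand <- sample(c("+", "-"), 1)
    ex <- toy_exon(st, st + len, strand)
    g_junction <- if (strand == "+") st + len - 1L else st
    g_fivemost <- if (strand == "+") st else st + len - 1L
    expect_equal(relative_position(g_junction, ex), -1L)
    expect_equal(relative_position(g_fivemost, ex), -len)
  }
})

test_that("uridine counting is sense-strand aware", {
  base <- strsplit(paste(rep("G", 60), collapse = ""), "")[[1]]
  # plus-strand exon [0,40): window [-30,-24] covers 0-based 10..16
  seq1 <- base; seq1[11:17] <- strsplit("GCGCGCG", "")[[1]]
  ex <- toy_exon(0, 40, "+")
  expect_equal(count_uridines(ex, c(chr1 = paste(seq1, collapse = ""))), 0L)
  seq2 <- base; seq2[11:17] <- strsplit("TTTTTTT", "")[[1]]
  expect_equal(count_uridines(ex, c(chr1 = paste(seq2, collapse = ""))), 7L)
  # minus-strand exon [0,40): window [-30,-24] covers 0-based 24..30
  seq3 <- base; seq3[25:31] <- strsplit("AAACCCA", "")[[1]]
  exm <- toy_exon(0, 40, "-")
  expect_equal(count_uridines(exm, c(chr1 = paste(seq3, collapse = ""))), 3L)
  # window undefined for a too-short exon
  shrt <- toy_exon(0, 20, "+")
  expect_true(is.na(count_uridines(shrt, c(chr1 = paste(seq1, collapse = "")))))
  expect_error(count_uridines(ex, c(chrX = "AAAA")), "missing")
})

test_that("exon class tallies satisfy the count identity", {
  sim <- small_sim()
  ex <- sim$exons
  n_multi <- sum(vapply(sim$models, function(m) nrow(m$exons) > 1, TRUE))
  n_single <- sum(ex$cls == "single")
  expect_equal(sum(ex$cls == "internal"),
               nrow(ex) - 2L * n_multi - n_single)
  expect_equal(sum(ex$cls == "first"), n_multi)
  expect_equal(sum(ex$cls == "last"), n_multi)
})
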