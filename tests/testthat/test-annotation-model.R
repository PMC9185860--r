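test_that("read_genome loads FASTA records, uppercases, and validates", {
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">chrT", "ACGT"), fa)
  g <- read_genome(fa)
  expect_equal(as.character(g[["chrT"]]), "ACGT")

  writeLines(c(">c1 description", "acgtn", ">c2", "GGGG", "CC"), fa)
  g <- read_genome(fa)
  expect_setequal(names(g), c("c1", "c2"))
  expect_equal(as.character(g[["c1"]]), "ACGTN")   # soft-mask uppercased
  expect_equal(as.character(g[["c2"]]), "GGGGCC")  # wrapped record joined

  writeLines(character(0), fa)
  expect_error(read_genome(fa), "no records")
  writeLines(c(">dup", "AC", ">dup", "GT"), fa)
  expect_error(read_genome(fa), "duplicate contig")
  writeLines(c("ACGT"), fa)
  expect_error(read_genome(fa), "malformed FASTA")
})

test_that("read_gtf converts coordinates, orders exons by strand, flags CCDS", {
  gtf <- tempfile(fileext = ".gtf")
  attr1 <- 'gene_id "g1"; transcript_id "t1"; gene_name "GENE1";'
  attr2 <- 'gene_id "g1"; transcript_id "t2"; gene_name "GENE1"; ccds_id "CCDS1";'
  attr3 <- 'gene_id "g2"; transcript_id "t3"; gene_name "GENE2"; tag "basic";'
  writeLines(c(
    paste("chrT", "src", "exon", 101, 200, ".", "+", ".", attr1, sep = "\t"),
    paste("chrT", "src", "exon", 301, 400, ".", "+", ".", attr1, sep = "\t"),
    paste("chrT", "src", "exon", 101, 200, ".", "-", ".", attr2, sep = "\t"),
    paste("chrT", "src", "exon", 301, 400, ".", "-", ".", attr2, sep = "\t"),
    paste("chrT", "src", "exon", 501, 520, ".", "+", ".", attr3, sep = "\t"),
    paste("chrT", "src", "five_prime_utr", 501, 520, ".", "+", ".", attr3,
          sep = "\t")
  ), gtf)
  tx <- read_gtf(gtf)
  expect_equal(nrow(tx), 3L)

  t1 <- tx[tx$transcript_id == "t1", ]
  expect_equal(t1$exons[[1]]$start, c(100L, 300L))  # 1-based -> 0-based
  expect_equal(t1$exons[[1]]$end, c(200L, 400L))
  expect_equal(t1$length, 200L)

  # minus strand: exon 1 is the genomically rightmost
  t2 <- tx[tx$transcript_id == "t2", ]
  expect_equal(t2$exons[[1]]$start[t2$exons[[1]]$index == 1L], 300L)
  expect_true(t2$has_ccds)
  expect_false(t1$has_ccds)
  expect_false(tx$has_ccds[tx$transcript_id == "t3"])
})

test_that("read_gtf skips rows without transcript_id and rejects mixed strands", {
  gtf <- tempfile(fileext = ".gtf")
  writeLines(c(
    paste("chrT", "s", "exon", 1, 10, ".", "+", ".", 'gene_id "g";', sep = "\t"),
    paste("chrT", "s", "exon", 21, 30, ".", "+", ".",
          'gene_id "g"; transcript_id "tA";', sep = "\t")
  ), gtf)
  expect_warning(tx <- read_gtf(gtf), "without transcript_id")
  expect_equal(tx$transcript_id, "tA")

  writeLines(c(
    paste("chrT", "s", "exon", 1, 10, ".", "+", ".",
          'gene_id "g"; transcript_id "tB";', sep = "\t"),
    paste("chrT", "s", "exon", 21, 30, ".", "-", ".",
          'gene_id "g"; transcript_id "tB";', sep = "\t")
  ), gtf)
  expect_error(read_gtf(gtf), "inconsistent strand")
})

test_that("spliced_sequence concatenates exons with strand handling", {
  g <- mk_genome(chrT = "ATGCCCTAA")
  tp <- mk_tx("t+", list(c(0L, 3L), c(6L, 9L)))
  expect_equal(spliced_sequence(tp, g), "ATGTAA")

  tm <- mk_tx("t-", list(c(0L, 3L)), strand = "-")
  expect_equal(spliced_sequence(tm, g), "CAT")

  tp3 <- mk_tx("t3", list(c(0L, 3L), c(4L, 6L), c(6L, 9L)))
  expect_equal(spliced_sequence(tp3, g, exon_range = 2:2), "CC")
  expect_error(spliced_sequence(tp3, g, exon_range = 4:4), "out of bounds")
  expect_error(spliced_sequence(tp3, g, exon_range = c(1L, 3L)), "contiguous")
})

test_that("GTF round trip reproduces models exactly", {
  tx <- read_gtf(file.path(fixture_dir(), "annotation.gtf"))
  out <- tempfile(fileext = ".gtf")
  write_gtf(tx, out)
  tx2 <- read_gtf(out)
  expect_equal(tx2, tx)
})

test_that("mirrored genome with flipped strands leaves spliced sequences unchanged", {
  genome <- read_genome(file.path(fixture_dir(), "genome.fa"))
  tx <- read_gtf(file.path(fixture_dir(), "annotation.gtf"))
  mg <- mirror_genome(genome)
  mtx <- mirror_transcripts(tx, genome)
  for (i in seq_len(nrow(tx))) {
    s1 <- spliced_sequence(tx[i, ], genome)
    s2 <- spliced_sequence(mtx[i, ], mg)
    expect_identical(s2, s1, label = tx$transcript_id[i])
    expect_equal(nchar(s1), tx$length[i])
  }
})
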