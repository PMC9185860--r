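test_that("enumerate_orfs reproduces the canonical circle cases", {
  o <- enumerate_orfs("ATGAAATAA", min_peptide = 1L)
  expect_equal(nrow(o), 1L)
  expect_equal(o$start, 0L)
  expect_equal(o$length_nt, 9L)
  expect_equal(o$crossings, 0)
  expect_equal(o$orf_class, "0C")
  expect_equal(o$peptide, "MK")

  o <- enumerate_orfs("TAAATGCCC", min_peptide = 1L)
  expect_equal(o$start, 3L)
  expect_equal(o$length_nt, 9L)
  expect_equal(o$crossings, 1)   # floor((3 + 9 - 1) / 9)
  expect_equal(o$peptide, "MP")

  o <- enumerate_orfs("ATGAAAAAAA", min_peptide = 1L)
  expect_equal(o$length_nt, 24L)  # stop reached on the third pass
  expect_equal(o$crossings, 2)
  expect_equal(o$orf_class, "2C")
  expect_equal(o$peptide, "MKKNEKK")

  o <- enumerate_orfs("ATGGCTGCT", min_peptide = 1L)
  expect_true(o$endless)
  expect_equal(o$orf_class, "edlsC")
  expect_equal(o$length_nt, 0L)
  expect_equal(o$crossings, Inf)
  expect_equal(o$peptide, "MAA")

  expect_error(enumerate_orfs("AT"), ">= 3")
  # min_peptide drops short finite ORFs but never endless ones
  expect_equal(nrow(enumerate_orfs("ATGAAATAA", min_peptide = 5L)), 0L)
  expect_equal(nrow(enumerate_orfs("ATGGCTGCT", min_peptide = 50L)), 1L)
})

test_that("engine agrees with the brute-force scan on random circles", {
  set.seed(202)
  for (i in 1:120) {
    L <- sample(9:150, 1)
    s <- random_circle(L)
    a <- as.data.frame(enumerate_orfs(s, min_peptide = 1L)[, orf_cmp_cols])
    b <- as.data.frame(orf_scan_reference(s, min_peptide = 1L))
    b$crossings <- as.numeric(b$crossings)
    expect_equal(a, b, info = s)
  }
})

test_that("build_circle assembles exon blocks with offset adjustment", {
  g <- mk_genome(chrT = paste0(strrep("T", 100), "ATGAA", strrep("T", 20),
                               "ATAACC", strrep("T", 50)))
  tx <- mk_tx("t1", list(c(50L, 60L), c(100L, 105L), c(125L, 131L),
                         c(150L, 160L)))
  a <- tibble::tibble(assigned = TRUE, transcript_id = "t1",
                      exon_m = 2L, exon_n = 3L, acceptor_offset = 0L,
                      donor_offset = 0L, name = "X_e2-e3")
  circ <- build_circle(a, tx, g)
  expect_equal(circ$seq, "ATGAAATAACC")
  expect_equal(circ$L, 11L)
  expect_equal(circ$seq, spliced_sequence(tx, g, 2:3))

  a2 <- a; a2$donor_offset <- 2L      # circle 2 nt longer at the 3' end
  circ2 <- build_circle(a2, tx, g)
  expect_equal(circ2$L, 13L)
  expect_equal(substr(circ2$seq, 1, 11), circ$seq)

  a3 <- a; a3$acceptor_offset <- 6L   # consumes the whole 5-nt exon
  expect_error(build_circle(a3, tx, g), "outside its exon")
})

test_that("build_circle reverse-complements minus-strand blocks in order", {
  # transcript reads exon1 then exon2; genome holds the reverse complement
  g <- mk_genome(chrT = "TTACCGGTTTCATGG")
  tx <- mk_tx("tm", list(c(10L, 15L), c(2L, 8L)), strand = "-")
  a <- tibble::tibble(assigned = TRUE, transcript_id = "tm",
                      exon_m = 1L, exon_n = 2L, acceptor_offset = 0L,
                      donor_offset = 0L, name = "M_e1-e2")
  circ <- build_circle(a, tx, g)
  # revcomp("CATGG") = CCATG ; revcomp("ACCGGT") = ACCGGT
  expect_equal(circ$seq, "CCATGACCGGT")
})

test_that("project_cds maps CDS onto circle coordinates with phase", {
  g <- mk_genome(chrT = paste0(strrep("G", 100), "ATGAA", strrep("G", 20),
                               "ATAA", strrep("G", 50)))
  tx <- mk_tx("t1", list(c(50L, 60L), c(100L, 105L), c(125L, 129L),
                         c(150L, 160L)),
              cds = list(c(100L, 105L), c(125L, 129L)))
  a <- tibble::tibble(assigned = TRUE, transcript_id = "t1",
                      exon_m = 2L, exon_n = 3L, acceptor_offset = 0L,
                      donor_offset = 0L, name = "X_e2-e3")
  circ <- build_circle(a, tx, g)
  p <- project_cds(a, circ, tx)
  expect_true(p$present)
  expect_equal(nrow(p$intervals), 1L)  # one contiguous run over the junction-free span
  expect_equal(p$intervals$circle_start, 0L)
  expect_equal(p$intervals$circle_end, 9L)
  expect_equal(p$intervals$phase, 0L)

  # CDS starting mid-exon-M: projection starts at the in-exon offset
  tx2 <- mk_tx("t1", list(c(50L, 60L), c(100L, 105L), c(125L, 129L),
                          c(150L, 160L)),
               cds = list(c(102L, 105L), c(125L, 129L)))
  p2 <- project_cds(a, build_circle(a, tx2, g), tx2)
  expect_equal(p2$intervals$circle_start[1], 2L)

  # noncoding transcript
  tx3 <- mk_tx("t1", list(c(100L, 105L), c(125L, 129L)))
  a3 <- a; a3$exon_m <- 1L; a3$exon_n <- 2L
  p3 <- project_cds(a3, build_circle(a3, tx3, g), tx3)
  expect_false(p3$present)
})

test_that("novelty classification follows the parental-frame rules", {
  # circle TAAATGCCC with CDS over positions 3..8 in frame: the one-crossing
  # ORF's pre-junction codons are parental, its wrapped stop is novel
  proj <- structure(list(
    present = TRUE,
    intervals = tibble::tibble(circle_start = 3L, circle_end = 9L,
                               phase = 0L, cds_offset = 0L),
    cds_pos = c(NA, NA, NA, 0L, 1L, 2L, 3L, 4L, 5L)
  ), class = "cds_projection")
  o <- classify_novelty(enumerate_orfs("TAAATGCCC", 1L), proj, L = 9L)
  expect_equal(o$orf_class, "1C3'")
  expect_false(o$novel_n); expect_true(o$novel_c)

  # no CDS at all: one-crossing ORF stays 1C3' with the fallback qualifier
  noproj <- structure(list(present = FALSE, intervals = NULL,
                           cds_pos = rep(NA_integer_, 9L)),
                      class = "cds_projection")
  o2 <- classify_novelty(enumerate_orfs("TAAATGCCC", 1L), noproj, L = 9L)
  expect_equal(o2$qualifier, "no-parental-frame")
  expect_true(o2$novel_n && o2$novel_c)

  # CDS covering the whole circle in frame both sides of the junction:
  # frame-preserving, no novel termini
  proj3 <- structure(list(
    present = TRUE,
    intervals = tibble::tibble(circle_start = 0L, circle_end = 9L,
                               phase = 0L, cds_offset = 0L),
    cds_pos = 0:8
  ), class = "cds_projection")
  o3 <- classify_novelty(enumerate_orfs("TAAATGCCC", 1L), proj3, L = 9L)
  expect_equal(o3$qualifier, "frame-preserving")
  expect_false(o3$novel_n || o3$novel_c)

  # two crossings: novel at both ends regardless of the projection
  o4 <- classify_novelty(enumerate_orfs("ATGAAAAAAA", 1L), noproj, L = 10L)
  expect_equal(o4$orf_class, "2C")
  expect_true(o4$novel_n && o4$novel_c)
})

test_that("ORF-to-protein mapping is exact coordinate arithmetic", {
  res <- fixture_result()
  tx <- res$transcripts
  genome <- read_genome(file.path(fixture_dir(), "genome.fa"))
  asg <- res$assignments
  z <- asg[asg$assigned & asg$gene_symbol == "CIRZERO", ]
  circ <- build_circle(z, tx, genome)
  proj <- project_cds(z, circ, tx)
  orf <- enumerate_orfs(circ, 1L)
  orf <- classify_novelty(orf, proj, circ$L)
  al <- map_orf_to_protein(orf[1, ], proj, parent_protein_length = 2L,
                           L = circ$L)
  expect_true(al$aligned)
  expect_equal(al$parental_start, 1L)  # the circle CDS is the whole protein
  expect_equal(al$parental_end, 2L)
  expect_equal(al$n_overhang, 0L)
  expect_equal(al$c_overhang, 0L)

  # one-crossing ORF of the minus-strand scenario: M + P parental, stop novel
  t3 <- asg[asg$assigned & asg$gene_symbol == "CIRTHREE", ]
  circ3 <- build_circle(t3, tx, genome)
  proj3 <- project_cds(t3, circ3, tx)
  orf3 <- classify_novelty(enumerate_orfs(circ3, 1L), proj3, circ3$L)
  al3 <- map_orf_to_protein(orf3[1, ], proj3, parent_protein_length = 4L,
                            L = circ3$L)
  expect_equal(c(al3$parental_start, al3$parental_end), c(1L, 2L))
  expect_equal(al3$n_overhang, 0L)
  expect_equal(al3$c_overhang, 0L)

  orfE <- enumerate_orfs("ATGGCTGCT", 1L)
  expect_error(map_orf_to_protein(orfE[1, ], proj3, 4L, L = 9L), "endless")
})

test_that("rotation maps cyclically anchored ORFs predictably", {
  # The unrolled linear scan is scan-origin dependent for ATGs that precede
  # the first in-frame stop (their cyclic suppressor may lie across the
  # origin), so the rotation-stable finite set is the cyclically *anchored*
  # ORFs: those whose start is the first ATG after the preceding in-frame
  # stop of the cyclic reading. That set must map start -> (start - r) mod L
  # with identical lengths and peptides.
  anchored <- function(seq, o) {
    L <- nchar(seq)
    d <- paste0(seq, seq)
    codon_at <- function(p) substr(d, p + 1, p + 3)
    is_stop <- function(p) codon_at(p) %in% c("TAA", "TAG", "TGA")
    vapply(seq_len(nrow(o)), function(k) {
      if (o$endless[k]) return(FALSE)
      s <- o$start[k]
      p <- (s - 3) %% L; q <- NA_integer_
      for (step in seq_len(L)) {
        if (is_stop(p)) { q <- p; break }
        p <- (p - 3) %% L
      }
      if (is.na(q)) return(FALSE)
      p <- (q + 3) %% L
      for (step in seq_len(L)) {
        if (codon_at(p) == "ATG") return(p == s)
        p <- (p + 3) %% L
      }
      FALSE
    }, logical(1))
  }
  set.seed(77)
  for (i in 1:30) {
    L <- sample(c(9:60), 1)
    s <- random_circle(L)
    r <- sample(seq_len(L - 1), 1)
    s2 <- paste0(substr(s, r + 1, L), substr(s, 1, r))
    a <- enumerate_orfs(s, 1L)
    b <- enumerate_orfs(s2, 1L)
    aa <- a[anchored(s, a), ]; bb <- b[anchored(s2, b), ]
    expect_setequal(
      paste((aa$start - r) %% L, aa$length_nt, aa$peptide),
      paste(bb$start, bb$length_nt, bb$peptide)
    )
    # anchored 0C ORFs avoiding the junction in both circles are preserved
    # with their crossing counts
    a0 <- aa[aa$crossings == 0 & aa$start > 0 &
               (aa$start + aa$length_nt) < L &
               ((aa$start - r) %% L) > 0 &
               ((aa$start - r) %% L) + aa$length_nt < L, ]
    if (nrow(a0) > 0) {
      expect_true(all(
        paste((a0$start - r) %% L, a0$length_nt, a0$peptide) %in%
          paste(bb$start[bb$crossings == 0], bb$length_nt[bb$crossings == 0],
                bb$peptide[bb$crossings == 0])))
    }
    # endless readings: same count, cyclically equivalent period peptides
    ae <- a[a$endless, ]; be <- b[b$endless, ]
    expect_equal(nrow(ae), nrow(be))
    canon <- function(p) {
      shifts <- vapply(seq_len(nchar(p)), function(k) {
        paste0(substr(p, k, nchar(p)), substr(p, 1, k - 1))
      }, character(1))
      min(shifts)
    }
    expect_setequal(vapply(ae$peptide, canon, character(1), USE.NAMES = FALSE),
                    vapply(be$peptide, canon, character(1), USE.NAMES = FALSE))
  }
})

test_that("every emitted ORF carries exactly one class and classes partition", {
  set.seed(55)
  for (i in 1:20) {
    s <- random_circle(sample(9:100, 1))
    o <- enumerate_orfs(s, 1L)
    if (nrow(o) == 0) next
    expect_true(all(o$orf_class %in% c("0C", "1C5'", "1C3'", "2C", "edlsC")))
    expect_equal(sum(table(o$orf_class)), nrow(o))
    expect_equal(o$orf_class == "0C", !o$endless & o$crossings == 0)
    expect_equal(o$orf_class == "edlsC", o$endless)
    # crossing closed form holds for finite ORFs
    f <- o[!o$endless, ]
    expect_equal(f$crossings, (f$start + f$length_nt - 1) %/% nchar(s))
  }
})
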