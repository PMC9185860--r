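# a plus-strand 4-exon transcript used across matching tests
plus_models <- function() {
  mk_tx("tP", list(c(100L, 200L), c(300L, 400L), c(500L, 600L),
                   c(700L, 800L)))
}

test_that("match_transcripts finds exact boundary matches with offsets 0", {
  j <- mk_junction("chrT", 300, 600)
  m <- match_transcripts(j, plus_models(), tolerance = 2L)
  expect_equal(nrow(m), 1L)
  expect_equal(m$acceptor_exon, 2L)
  expect_equal(m$donor_exon, 3L)
  expect_equal(m$acceptor_offset, 0L)
  expect_equal(m$donor_offset, 0L)
  expect_equal(m$total_offset, 0L)
})

test_that("matching respects the tolerance at each end", {
  j <- mk_junction("chrT", 300, 602)   # donor end 2 nt past the exon boundary
  m2 <- match_transcripts(j, plus_models(), tolerance = 2L)
  expect_equal(m2$donor_offset, 2L)
  expect_equal(m2$total_offset, 2L)
  m1 <- match_transcripts(j, plus_models(), tolerance = 1L)
  expect_equal(nrow(m1), 0L)
})

test_that("minus-strand junction ends map to donor/acceptor after strand flip", {
  # transcript order: exon1 [700,800), exon2 [500,600), exon3 [300,400)
  mm <- mk_tx("tM", list(c(700L, 800L), c(500L, 600L), c(300L, 400L)),
              strand = "-")
  # circle over exons 2..3: genomic-left end is the donor exon's start
  j <- mk_junction("chrT", 300, 600, "-")
  m <- match_transcripts(j, mm, tolerance = 2L)
  expect_equal(m$acceptor_exon, 2L)
  expect_equal(m$donor_exon, 3L)
  expect_equal(m$total_offset, 0L)
  # acceptor ordinal must not exceed donor ordinal
  j2 <- mk_junction("chrT", 500, 800, "-")
  m2 <- match_transcripts(j2, mm, tolerance = 2L)
  expect_equal(m2$acceptor_exon, 1L)
  expect_equal(m2$donor_exon, 2L)
})

test_that("ranking: junction fit beats CCDS, CCDS breaks offset ties", {
  # T_A exact fit, no CCDS, few exons; T_B off by 2 at the donor, CCDS, many
  tA <- mk_tx("T_A", list(c(100L, 200L), c(300L, 400L), c(500L, 600L),
                          c(700L, 800L)))
  tB <- mk_tx("T_B", list(c(100L, 200L), c(300L, 400L), c(500L, 598L),
                          c(700L, 800L), c(900L, 950L), c(960L, 970L),
                          c(980L, 990L), c(1000L, 1010L), c(1020L, 1030L)),
              ccds = TRUE)
  models <- dplyr::bind_rows(tA, tB)
  j <- mk_junction("chrT", 300, 600)
  a <- rank_and_assign(j, models, tolerance = 2L)
  expect_equal(a$transcript_id, "T_A")
  expect_equal(a$competing_matches, 2L)

  # equal offsets: the CCDS transcript wins
  tB2 <- mk_tx("T_B", list(c(100L, 200L), c(300L, 400L), c(500L, 600L)),
               ccds = TRUE)
  a2 <- rank_and_assign(j, dplyr::bind_rows(tA, tB2), tolerance = 2L)
  expect_equal(a2$transcript_id, "T_B")
})

test_that("commonness gives a gene's junctions to the shared transcript", {
  res <- fixture_result()
  comg <- res$assignments[res$assignments$assigned &
                            res$assignments$gene_symbol == "COMG", ]
  expect_equal(nrow(comg), 3L)
  expect_equal(unique(comg$transcript_id), "TX_COMS")
})

test_that("assignments are invariant under input permutations", {
  res <- fixture_result()
  tx <- res$transcripts
  master <- res$junctions
  base <- rank_and_assign(master, tx, tolerance = 2L)
  for (seed in 1:3) {
    set.seed(seed)
    perm <- rank_and_assign(master[sample(nrow(master)), ],
                            tx[sample(nrow(tx)), ], tolerance = 2L)
    perm <- perm[match(junction_key(base), junction_key(perm)), ]
    expect_equal(perm$transcript_id, base$transcript_id)
    expect_equal(perm$exon_m, base$exon_m)
    expect_equal(perm$exon_n, base$exon_n)
  }
})

test_that("a zero-offset candidate is never beaten by a nonzero one", {
  set.seed(401)
  for (rep in 1:25) {
    shifts <- sample(0:2, 3, replace = TRUE)
    if (!any(shifts == 0L)) shifts[sample(3, 1)] <- 0L
    models <- dplyr::bind_rows(lapply(1:3, function(k) {
      d <- shifts[k]
      mk_tx(sprintf("T%d", k),
            list(c(100L, 200L), c(300L + d, 400L), c(500L, 600L - d),
                  c(700L, 800L)),
            ccds = sample(c(TRUE, FALSE), 1))
    }))
    a <- rank_and_assign(mk_junction("chrT", 300, 600), models,
                         tolerance = 2L)
    won <- as.integer(sub("T", "", a$transcript_id))
    expect_equal(shifts[won], 0L)
  }
})

test_that("circ_name formats the exon pair after the gene symbol", {
  expect_equal(circ_name("PTP4A2", 2, 3), "PTP4A2_e2-e3")
  expect_equal(circ_name("GENEX", 4, 4), "GENEX_e4")
  res <- fixture_result()
  asg <- res$assignments[res$assignments$assigned, ]
  nm <- circ_name(asg)
  trip <- paste(asg$gene_symbol, asg$exon_m, asg$exon_n)
  expect_equal(duplicated(nm), duplicated(trip))  # injective on (symbol, M, N)
  expect_error(circ_name(res$assignments), "unassigned")
})
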