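test_that("parse_ciri converts 1-based coordinates, filters and dedups", {
  p <- write_ciri_file(c(
    "chrT:101|300\tchrT\t101\t300\t5\t+",
    "chrT:101|300\tchrT\t101\t300\t7\t+",
    "chrT:401|500\tchrT\t401\t500\t1\t+"
  ))
  j <- parse_ciri(p, "cyto", min_reads = 2L)
  expect_equal(nrow(j), 1L)   # low-read row dropped, duplicate collapsed
  expect_equal(j$start, 100L)
  expect_equal(j$end, 300L)
  expect_equal(j$read_support[[1]]$cyto, 5L)

  expect_equal(nrow(parse_ciri(p, "cyto", min_reads = 8L)), 0L)

  bad <- write_ciri_file("x\tchrT\tabc\t300\t5\t+")
  expect_error(parse_ciri(bad, "s"), "non-numeric coordinate at row 1")

  nohdr <- tempfile()
  writeLines(c("a\tb", "1\t2"), nohdr)
  expect_error(parse_ciri(nohdr, "s"), "missing required column")
})

test_that("parse_bed adopts BED coordinates and requires strand", {
  p <- tempfile(fileext = ".bed")
  writeLines("chrT\t100\t300\tj1\t5\t+", p)
  j <- parse_bed(p, "lib")
  expect_equal(j[, c("start", "end")], tibble::tibble(start = 100L, end = 300L))

  writeLines("chrT\t100\t300\tj1\t5\t.", p)
  expect_error(parse_bed(p, "lib"), "strand required")

  writeLines(character(0), p)
  expect_equal(nrow(parse_bed(p, "lib")), 0L)

  writeLines("chrT\t100\t300", p)
  expect_error(parse_bed(p, "lib"), ">= 6 columns")
})

test_that("parse_archive handles both dialects, skips bad rows, honors column_map", {
  p <- tempfile(fileext = ".tsv")
  writeLines(c("circRNA_ID\tposition\tstrand",
               "hsa_circ_0000001\tchr1:101-300\t+",
               "hsa_circ_0000002\tchr1:101\t+"), p)
  expect_warning(j <- parse_archive(p, "circbase"), "skipped 1 row")
  expect_equal(nrow(j), 1L)
  expect_equal(j$start, 100L)
  expect_equal(j$accessions[[1]]$circbase, "hsa_circ_0000001")
  expect_equal(attr(j, "skipped_rows"), 1L)

  p2 <- tempfile(fileext = ".tsv")
  writeLines(c("circRNA_ID\tchr\tstart\tend\tstrand",
               "id9\tchr2\t100\t300\t-"), p2)
  j2 <- parse_archive(p2, "circrnadb",
                      column_map = list(coord_base = 0L))
  expect_equal(j2$start, 100L)   # declared 0-based: adopted unchanged
  j3 <- parse_archive(p2, "circrnadb")
  expect_equal(j3$start, 99L)
})

test_that("junction normalization is idempotent through BED", {
  master <- fixture_result()$junctions
  bed <- tempfile(fileext = ".bed")
  write_bed(master, bed)
  back <- parse_bed(bed, "roundtrip")
  expect_identical(junction_key(back), junction_key(master))
})

test_that("reconcile produces the designed partition and is order-invariant", {
  j1 <- mk_junction("c", 0, 10); j2 <- mk_junction("c", 20, 30)
  j3 <- mk_junction("c", 40, 50)
  A <- dplyr::bind_rows(j1, j2); B <- dplyr::bind_rows(j2, j3)
  part <- reconcile(list(A = A, B = B))
  counts <- setNames(part$count, part$region)
  expect_equal(counts[["A"]], 1L)
  expect_equal(counts[["B"]], 1L)
  expect_equal(counts[["A&B"]], 1L)

  ident <- reconcile(list(A = A, B = A))
  expect_equal(ident$region, "A&B")
  expect_equal(ident$count, 2L)

  expect_error(reconcile(list(A = A)), ">=2 sets")

  sets <- list(x = A, y = B, z = dplyr::bind_rows(j1, j3))
  p1 <- reconcile(sets)
  p2 <- reconcile(rev(sets))
  expect_equal(sort(p1$count), sort(p2$count))
  expect_equal(sum(p1$count), 3L)   # union size
})

test_that("localization profiles mark presence per compartment", {
  j1 <- mk_junction("c", 0, 10)
  prof <- localization_profiles(list(cytoplasm = j1, polysome = j1,
                                     nucleoplasm = j1[0, ]))
  expect_equal(nrow(prof), 1L)
  expect_true(prof$cytoplasm && prof$polysome)
  expect_false(prof$nucleoplasm || prof$chromatin)

  expect_error(localization_profiles(list(mitochondria = j1)),
               "unknown compartment")
})

test_that("merging unions sources and keeps per-source read support", {
  p1 <- write_ciri_file("x\tchrT\t101\t300\t5\t+")
  p2 <- write_ciri_file("x\tchrT\t101\t300\t9\t+")
  m <- merge_junctions(parse_ciri(p1, "cyto"), parse_ciri(p2, "poly"))
  expect_equal(nrow(m), 1L)
  expect_setequal(m$sources[[1]], c("cyto", "poly"))
  expect_equal(m$read_support[[1]]$cyto, 5L)
  expect_equal(m$read_support[[1]]$poly, 9L)
})
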