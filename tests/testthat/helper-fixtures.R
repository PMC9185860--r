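# Shared fixture builders. The full synthetic dataset is generated once per
# test session and cached; everything else is built inline in code.

fixture_dir <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      d <- file.path(tempdir(), "circann-default-fixture")
      if (!dir.exists(d)) generate_fixtures(d)
      cache <<- d
    }
    cache
  }
})

fixture_truth <- function() {
  jsonlite::read_json(file.path(fixture_dir(), "ground_truth.json"))
}

fixture_result <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- suppressMessages(
        annotate_run(file.path(fixture_dir(), "config.yml"), write = FALSE))
    }
    cache
  }
})

# a genome from named sequences
mk_genome <- function(...) {
  seqs <- c(...)
  Biostrings::DNAStringSet(seqs)
}

# one transcript model row; exons given in transcript order as a list of
# c(start, end) genomic intervals
mk_tx <- function(id, exons, strand = "+", contig = "chrT", gene = "G1",
                  sym = "GENE1", ccds = FALSE, cds = NULL) {
  ex <- do.call(rbind, exons)
  extab <- tibble::tibble(start = ex[, 1L], end = ex[, 2L],
                          index = seq_len(nrow(ex)))
  cdtab <- if (is.null(cds)) {
    tibble::tibble(start = integer(), end = integer())
  } else {
    cd <- do.call(rbind, cds)
    tibble::tibble(start = cd[, 1L], end = cd[, 2L])
  }
  tibble::tibble(
    transcript_id = id, gene_id = gene, gene_symbol = sym, contig = contig,
    strand = strand, has_ccds = ccds, n_exons = nrow(extab),
    length = sum(extab$end - extab$start),
    exons = list(extab), cds = list(cdtab)
  )
}

# one junction row with empty provenance
mk_junction <- function(contig, start, end, strand = "+") {
  tibble::tibble(contig = contig, start = as.integer(start),
                 end = as.integer(end), strand = strand,
                 sources = list(list()), read_support = list(list()),
                 accessions = list(list()))
}

# a CIRI2-dialect table file
write_ciri_file <- function(rows, path = tempfile(fileext = ".tsv")) {
  header <- paste(c("circRNA_ID", "chr", "circRNA_start", "circRNA_end",
                    "#junction_reads", "strand"), collapse = "\t")
  writeLines(c(header, rows), path)
  path
}

random_circle <- function(L) {
  paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
}

orf_cmp_cols <- c("start", "length_nt", "crossings", "endless", "peptide")

# the 1,000-circle engine-vs-oracle comparison, run once and cached
acceptance_oracle <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      set.seed(20220609)
      t0 <- Sys.time()
      lengths <- sample(9:300, 1000L, replace = TRUE)
      agree <- 0L
      rows <- vector("list", length(lengths))
      for (i in seq_along(lengths)) {
        s <- random_circle(lengths[i])
        eng <- as.data.frame(enumerate_orfs(s, min_peptide = 1L)[, orf_cmp_cols])
        ora <- as.data.frame(orf_scan_reference(s, min_peptide = 1L))
        ora$crossings <- as.numeric(ora$crossings)
        rownames(eng) <- NULL
        rownames(ora) <- NULL
        if (isTRUE(all.equal(eng, ora, check.attributes = FALSE))) {
          agree <- agree + 1L
        }
        ora$L <- rep(lengths[i], nrow(ora))
        rows[[i]] <- ora
      }
      cache <<- list(
        n = length(lengths), agree = agree, lengths = lengths,
        oracle = do.call(rbind, rows),
        elapsed = as.numeric(difftime(Sys.time(), t0, units = "secs"))
      )
    }
    cache
  }
})
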