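#' Blueprint for the default synthetic fixture
#'
#' Describes a fully self-contained toy dataset on one contig (`chrT`):
#'
#' * six single-transcript genes each hosting one backsplice junction with a
#'   designed ORF scenario (`0C`, `1C5'`, `1C3'` on the minus strand, `2C`,
#'   `edlsC`, and `none` — a circle without any ATG);
#' * a three-isoform gene `PTPX` whose transcripts host 9, 2 and 1
#'   backsplice exon pairs respectively (the shape of a gene with many
#'   circRNA isoforms where no single reference transcript fits all);
#' * a `COMG` gene where a shared CCDS transcript matches all three of the
#'   gene's junctions while a rival CCDS transcript with more exons matches
#'   only one — the commonness criterion must give all three junctions to
#'   the shared transcript;
#' * three archive-only junctions in intergenic space (present in the
#'   database dumps but never called de novo).
#'
#' Compartment memberships and archive memberships are chosen so that every
#' region of the three-set database Venn (de novo / circBase-like /
#' circRNADb-like) and a rich compartment Venn are populated, with counts
#' that are recomputed here by direct bookkeeping and written to the ground
#' truth.
#'
#' @param seed Integer seed; the same seed yields byte-identical fixture
#'   files.
#' @return A `fixture_spec` list with elements `seed`, `units` (transcript
#'   layout blueprints) and `junctions` (junction blueprints).
#' @export
fixture_spec <- function(seed = 42L) {
  units <- list(
    list(gene_id = "G_0C", sym = "CIRZERO", tx = "TX_0C", strand = "+",
         ccds = TRUE, exon_seqs = c(NA, "ATGAA", "ATAA", NA),
         exon_lens = c(12L, 5L, 4L, 12L), intron_lens = c(10L, 10L, 10L),
         cds_t = c(12L, 21L)),
    list(gene_id = "G_1C5", sym = "CIRFIVE", tx = "TX_1C5", strand = "+",
         ccds = TRUE, exon_seqs = c(NA, "GCTTAA", "CCAATG", NA),
         exon_lens = c(12L, 6L, 6L, 12L), intron_lens = c(10L, 10L, 10L),
         cds_t = c(12L, 18L)),
    list(gene_id = "G_1C3", sym = "CIRTHREE", tx = "TX_1C3", strand = "-",
         ccds = TRUE, exon_seqs = c(NA, "TAAAT", "GCCC", "GAAGAGTGAGCC"),
         exon_lens = c(12L, 5L, 4L, 12L), intron_lens = c(10L, 10L, 10L),
         cds_t = c(15L, 30L)),
    list(gene_id = "G_2C", sym = "CIRTWO", tx = "TX_2C", strand = "+",
         ccds = FALSE, exon_seqs = c(NA, "ATGAA", "AAAAA", NA),
         exon_lens = c(12L, 5L, 5L, 12L), intron_lens = c(10L, 10L, 10L),
         cds_t = NULL),
    list(gene_id = "G_EDLS", sym = "CIRENDLESS", tx = "TX_EDLS", strand = "+",
         ccds = FALSE, exon_seqs = c(NA, "ATGG", "CTGCT", NA),
         exon_lens = c(12L, 4L, 5L, 12L), intron_lens = c(10L, 10L, 10L),
         cds_t = NULL),
    list(gene_id = "G_NONE", sym = "CIRNONE", tx = "TX_NONE", strand = "+",
         ccds = FALSE, exon_seqs = c(NA, "GGCTC", "CGCC", NA),
         exon_lens = c(12L, 5L, 4L, 12L), intron_lens = c(10L, 10L, 10L),
         cds_t = NULL),
    list(gene_id = "G_PTPX", sym = "PTPX", tx = "TX_PTP1", strand = "+",
         ccds = TRUE, exon_seqs = rep(NA_character_, 10L),
         exon_lens = rep(30L, 10L), intron_lens = rep(20L, 9L),
         cds_t = NULL),
    list(gene_id = "G_PTPX", sym = "PTPX", tx = "TX_PTP2", strand = "+",
         ccds = FALSE, exon_seqs = rep(NA_character_, 4L),
         exon_lens = rep(30L, 4L), intron_lens = rep(20L, 3L),
         cds_t = NULL),
    list(gene_id = "G_PTPX", sym = "PTPX", tx = "TX_PTP3", strand = "+",
         ccds = FALSE, exon_seqs = rep(NA_character_, 2L),
         exon_lens = rep(30L, 2L), intron_lens = 20L,
         cds_t = NULL),
    list(gene_id = "G_COMG", sym = "COMG", tx = "TX_COMS", strand = "+",
         ccds = TRUE, exon_seqs = rep(NA_character_, 5L),
         exon_lens = rep(30L, 5L), intron_lens = rep(20L, 4L),
         cds_t = c(0L, 150L),
         overlays = list(list(
           tx = "TX_COMR", ccds = TRUE,
           exons_rel = list(c(50L, 80L), c(82L, 86L), c(87L, 93L),
                            c(137L, 143L), c(144L, 150L), c(187L, 193L),
                            c(200L, 230L))
         )))
  )
  jb <- function(id, tx, pair, comps, arch, scenario = NA_character_,
                 exp = NULL, expected_tx = tx) {
    list(id = id, tx = tx, pair = pair, acc_off = 0L, don_off = 0L,
         comps = comps, arch = arch, scenario = scenario, exp = exp,
         expected_tx = expected_tx)
  }
  junctions <- list(
    jb("s0C", "TX_0C", c(2L, 3L), c("cytoplasm", "polysome"), "circbase",
       "0C", list(class = "0C", novel_n = FALSE, novel_c = FALSE,
                  peptide = "MK")),
    jb("s1C5", "TX_1C5", c(2L, 3L), "cytoplasm", character(0),
       "1C5'", list(class = "1C5'", novel_n = TRUE, novel_c = FALSE,
                    peptide = "MA")),
    jb("s1C3", "TX_1C3", c(2L, 3L), c("nucleoplasm", "chromatin"),
       c("circbase", "circrnadb"),
       "1C3'", list(class = "1C3'", novel_n = FALSE, novel_c = TRUE,
                    peptide = "MP")),
    jb("s2C", "TX_2C", c(2L, 3L), COMPARTMENTS, "circrnadb",
       "2C", list(class = "2C", novel_n = TRUE, novel_c = TRUE,
                  peptide = "MKKNEKK")),
    jb("sEdls", "TX_EDLS", c(2L, 3L), "polysome", character(0),
       "edlsC", list(class = "edlsC", novel_n = TRUE, novel_c = TRUE,
                     peptide = "MAA")),
    jb("sNone", "TX_NONE", c(2L, 3L), "nucleoplasm", "circbase", "none"),
    jb("j1", "TX_PTP1", c(2L, 3L), "cytoplasm", "circbase"),
    jb("j2", "TX_PTP1", c(2L, 4L), "cytoplasm", "circbase"),
    jb("j3", "TX_PTP1", c(3L, 5L), "cytoplasm", "circbase"),
    jb("j4", "TX_PTP1", c(4L, 6L), "cytoplasm", "circbase"),
    jb("j5", "TX_PTP1", c(5L, 7L), "cytoplasm", "circrnadb"),
    jb("j6", "TX_PTP1", c(6L, 8L), "cytoplasm", "circrnadb"),
    jb("j7", "TX_PTP1", c(7L, 9L), "cytoplasm", c("circbase", "circrnadb")),
    jb("j8", "TX_PTP1", c(2L, 9L), "cytoplasm", character(0)),
    jb("j9", "TX_PTP1", c(3L, 10L), "cytoplasm", character(0)),
    jb("j10", "TX_PTP2", c(2L, 3L), c("cytoplasm", "polysome"), "circbase"),
    jb("j11", "TX_PTP2", c(2L, 4L), c("cytoplasm", "polysome"), character(0)),
    jb("j12", "TX_PTP3", c(1L, 2L), "cytoplasm", "circrnadb"),
    jb("c1", "TX_COMS", c(2L, 3L), "cytoplasm", "circbase"),
    jb("c2", "TX_COMS", c(3L, 5L), "cytoplasm", character(0)),
    jb("c3", "TX_COMS", c(2L, 5L), "cytoplasm", c("circbase", "circrnadb")),
    list(id = "a1", tx = NA_character_, coords = c(10L, 90L), strand = "+",
         comps = character(0), arch = "circbase", scenario = NA_character_,
         exp = NULL, expected_tx = NA_character_),
    list(id = "a2", tx = NA_character_, coords = c(20L, 100L), strand = "+",
         comps = character(0), arch = "circrnadb", scenario = NA_character_,
         exp = NULL, expected_tx = NA_character_),
    list(id = "a3", tx = NA_character_, coords = c(30L, 110L), strand = "-",
         comps = character(0), arch = c("circbase", "circrnadb"),
         scenario = NA_character_, exp = NULL, expected_tx = NA_character_)
  )
  structure(list(seed = as.integer(seed), contig = "chrT",
                 units = units, junctions = junctions),
            class = "fixture_spec")
}

# internal: random DNA string of length n (uses the session RNG)
rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Designed circle sequence for an ORF scenario
#'
#' Constructs a circle of length `L` whose ORF scan is guaranteed to contain
#' the requested scenario, then verifies the construction against the
#' brute-force reference scan ([orf_scan_reference()]) before returning.
#' `1C5'` and `1C3'` both denote a single-crossing ORF here (the 5'/3'
#' subtype depends on the parental CDS, which a bare sequence cannot carry).
#'
#' @param scenario One of `"0C"`, `"1C5'"`, `"1C3'"`, `"2C"`, `"edlsC"`,
#'   `"none"`.
#' @param L Circle length (>= 9). `edlsC` requires `L %% 3 == 0` (a
#'   stop-free codon cycle exists only then for a designed single frame);
#'   `2C` requires `L %% 3 != 0`.
#' @param seed Optional seed for the random filler of `"none"`.
#' @return A nucleotide string of length `L`.
#' @export
scenario_sequence <- function(scenario, L, seed = NULL) {
  L <- as.integer(L)
  if (L < 9L) abort("scenario sequences require L >= 9")
  if (!is.null(seed)) set.seed(seed)
  seq <- switch(scenario,
    "0C" = {
      orf_len <- 3L * (L %/% 3L)
      body <- strrep("GCC", orf_len %/% 3L - 2L)
      paste0("ATG", body, "TAA", strrep("C", L - orf_len))
    },
    "1C5'" = ,
    "1C3'" = {
      p <- L %% 3L
      paste0("TAA", strrep("C", p), "ATG", strrep("C", L - 6L - p))
    },
    "2C" = {
      if (L %% 3L == 0L) abort("2C construction requires L %% 3 != 0")
      # place the only stop at t with t = L (mod 3): the reading from the
      # ATG at 0 first meets it in frame on its third pass over the circle
      t <- 3L
      while (t %% 3L != L %% 3L) t <- t + 1L
      paste0("ATG", strrep("C", t - 3L), "TAA", strrep("C", L - t - 3L))
    },
    "edlsC" = {
      if (L %% 3L != 0L) abort("edlsC construction requires L %% 3 == 0")
      paste0("ATG", strrep("GCT", (L - 3L) %/% 3L))
    },
    "none" = paste(sample(c("C", "G"), L, replace = TRUE), collapse = ""),
    abort(sprintf("unknown scenario '%s'", scenario))
  )
  stopifnot(nchar(seq) == L)
  ref <- orf_scan_reference(seq, min_peptide = 1L)
  ok <- switch(scenario,
    "0C" = any(!ref$endless & ref$crossings == 0),
    "1C5'" = ,
    "1C3'" = any(!ref$endless & ref$crossings == 1),
    "2C" = any(!ref$endless & ref$crossings >= 2),
    "edlsC" = any(ref$endless),
    "none" = nrow(ref) == 0L
  )
  if (!ok) {
    abort(sprintf("scenario construction failed verification: %s (L=%d)",
                  scenario, L))
  }
  seq
}

#' Generate the synthetic fixture files
#'
#' Writes a genome FASTA, an Ensembl-dialect GTF, one CIRI2-style junction
#' table per subcellular compartment, circBase-like and circRNADb-like
#' archive dumps, a protein domain table, a ready-to-run pipeline config
#' (YAML) and a ground-truth JSON. Ground truth (expected assignments,
#' designed ORF classes, Venn region counts, localization matrix, circle
#' sequences) is computed here by direct blueprint bookkeeping and the
#' brute-force reference ORF scan — never by the annotation engine itself —
#' so pipeline tests against it are non-circular.
#'
#' @param out_dir Output directory (created if missing).
#' @param spec A [fixture_spec()].
#' @return Invisibly, a list with the manifest (tibble of written files),
#'   the ground truth list, and the built transcript table.
#' @export
generate_fixtures <- function(out_dir, spec = fixture_spec()) {
  if (!inherits(spec, "fixture_spec")) abort("spec must be a fixture_spec")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(spec$seed)
  contig <- spec$contig

  ## ---- lay out transcript units left to right ------------------------------
  genome_parts <- character(0)
  cursor <- 0L
  tx_rows <- list()
  tx_layout <- list()   # tx -> list(exon_seqs, exons(tibble), strand, ...)
  for (u in spec$units) {
    gap <- sample(40:60, 1L)
    genome_parts <- c(genome_parts, rand_dna(gap))
    cursor <- cursor + gap
    ne <- length(u$exon_lens)
    if (length(u$intron_lens) != ne - 1L) {
      abort(sprintf("inconsistent blueprint '%s': need %d intron lengths",
                    u$tx, ne - 1L))
    }
    exon_seqs <- map_chr(seq_len(ne), function(i) {
      if (!is.na(u$exon_seqs[i])) u$exon_seqs[i] else rand_dna(u$exon_lens[i])
    })
    if (any(nchar(exon_seqs) != u$exon_lens)) {
      abort(sprintf("inconsistent blueprint '%s': exon sequence lengths", u$tx))
    }
    intron_seqs <- map_chr(u$intron_lens, rand_dna)
    layout <- character(0)
    offs <- matrix(0L, ne, 2L)
    pos <- 0L
    for (i in seq_len(ne)) {
      offs[i, ] <- c(pos, pos + u$exon_lens[i])
      layout <- c(layout, exon_seqs[i])
      pos <- pos + u$exon_lens[i]
      if (i < ne) {
        layout <- c(layout, intron_seqs[i])
        pos <- pos + u$intron_lens[i]
      }
    }
    layout <- paste(layout, collapse = "")
    Lf <- nchar(layout)
    fragment <- if (u$strand == "+") layout else revcomp(layout)
    unit_start <- cursor
    genome_parts <- c(genome_parts, fragment)
    cursor <- cursor + Lf
    gexons <- if (u$strand == "+") {
      tibble(start = unit_start + offs[, 1L], end = unit_start + offs[, 2L],
             index = seq_len(ne))
    } else {
      tibble(start = unit_start + (Lf - offs[, 2L]),
             end = unit_start + (Lf - offs[, 1L]), index = seq_len(ne))
    }
    cds_g <- cds_to_genomic(u$cds_t, offs, u$exon_lens, gexons, u$strand)
    tx_rows[[u$tx]] <- tibble(
      transcript_id = u$tx, gene_id = u$gene_id, gene_symbol = u$sym,
      contig = contig, strand = u$strand, has_ccds = isTRUE(u$ccds),
      n_exons = ne, length = sum(u$exon_lens),
      exons = list(gexons), cds = list(cds_g)
    )
    tx_layout[[u$tx]] <- list(exon_seqs = exon_seqs, exons = gexons,
                              strand = u$strand, sym = u$sym,
                              cds_len = if (is.null(u$cds_t)) 0L
                                        else diff(u$cds_t))
    for (ov in (u$overlays %||% list())) {
      rel <- do.call(rbind, ov$exons_rel)
      oex <- tibble(start = unit_start + rel[, 1L],
                    end = unit_start + rel[, 2L],
                    index = seq_len(nrow(rel)))
      oseqs <- map_chr(seq_len(nrow(oex)), function(i) {
        substr(layout, rel[i, 1L] + 1L, rel[i, 2L])
      })
      tx_rows[[ov$tx]] <- tibble(
        transcript_id = ov$tx, gene_id = u$gene_id, gene_symbol = u$sym,
        contig = contig, strand = u$strand, has_ccds = isTRUE(ov$ccds),
        n_exons = nrow(oex), length = sum(oex$end - oex$start),
        exons = list(oex), cds = list(tibble(start = integer(),
                                             end = integer()))
      )
      tx_layout[[ov$tx]] <- list(exon_seqs = oseqs, exons = oex,
                                 strand = u$strand, sym = u$sym, cds_len = 0L)
    }
  }
  tail_start <- cursor + 50L
  genome_parts <- c(genome_parts, rand_dna(50L + 200L))
  genome_str <- paste(genome_parts, collapse = "")
  transcripts <- bind_rows(tx_rows) |> arrange(.data$transcript_id)

  ## ---- junction coordinates and designed truth -----------------------------
  jinfo <- map(spec$junctions, function(b) {
    if (!is.na(b$tx)) {
      lay <- tx_layout[[b$tx]]
      if (is.null(lay)) abort(sprintf("inconsistent blueprint '%s': unknown transcript", b$id))
      ex <- lay$exons
      m <- b$pair[1L]; n <- b$pair[2L]
      if (m > n || n > nrow(ex)) {
        abort(sprintf("inconsistent blueprint '%s': exon pair out of range", b$id))
      }
      em <- ex[ex$index == m, ]; en <- ex[ex$index == n, ]
      if (lay$strand == "+") {
        start <- em$start + b$acc_off; end <- en$end + b$don_off
      } else {
        start <- en$start - b$don_off; end <- em$end - b$acc_off
      }
      circ <- paste(lay$exon_seqs[m:n], collapse = "")
      strand <- lay$strand
      sym <- lay$sym
      name <- circ_name_chr(sym, m, n)
    } else {
      start <- tail_start + b$coords[1L]; end <- tail_start + b$coords[2L]
      strand <- b$strand; circ <- NA_character_
      sym <- NA_character_; name <- NA_character_
      m <- NA_integer_; n <- NA_integer_
    }
    ref <- if (!is.na(circ)) orf_scan_reference(circ, min_peptide = 1L) else NULL
    list(id = b$id, key = junction_key(contig, start, end, strand),
         contig = contig, start = start, end = end, strand = strand,
         name = name, gene_symbol = sym, exon_m = m, exon_n = n,
         transcript = b$expected_tx, compartments = b$comps,
         archives = b$arch, scenario = b$scenario, exp = b$exp,
         circle_seq = circ,
         has_orf = if (is.null(ref)) NA else nrow(ref) > 0L)
  })

  ## ---- write genome + GTF --------------------------------------------------
  genome_path <- file.path(out_dir, "genome.fa")
  writeLines(c(paste0(">", contig),
               substring(genome_str,
                         seq(1L, nchar(genome_str), 60L),
                         pmin(seq(1L, nchar(genome_str), 60L) + 59L,
                              nchar(genome_str)))),
             genome_path)
  gtf_path <- file.path(out_dir, "annotation.gtf")
  write_gtf(transcripts, gtf_path)

  ## ---- CIRI tables per compartment -----------------------------------------
  reads <- list()
  for (ji in jinfo) {
    for (cp in ji$compartments) {
      reads[[paste(ji$id, cp, sep = "/")]] <- sample(2:60, 1L)
    }
  }
  ciri_paths <- character(0)
  for (cp in COMPARTMENTS) {
    rows <- keep(jinfo, ~cp %in% .x$compartments)
    lines <- c(paste(c("circRNA_ID", "chr", "circRNA_start", "circRNA_end",
                       "#junction_reads", "SM_MS_SMS", "#non_junction_reads",
                       "junction_reads_ratio", "circRNA_type", "gene_id",
                       "strand"), collapse = "\t"))
    ord <- order(map_int(rows, "start"), map_int(rows, "end"))
    for (ji in rows[ord]) {
      jr <- reads[[paste(ji$id, cp, sep = "/")]]
      lines <- c(lines, paste(c(
        sprintf("%s:%d|%d", ji$contig, ji$start + 1L, ji$end),
        ji$contig, ji$start + 1L, ji$end, jr, "0_0_0",
        jr * 3L, sprintf("%.3f", jr / (jr * 3L + jr)), "exon",
        ji$gene_symbol %||% "n/a", ji$strand), collapse = "\t"))
    }
    p <- file.path(out_dir, sprintf("ciri_%s.tsv", cp))
    writeLines(lines, p)
    ciri_paths <- c(ciri_paths, p)
  }

  ## ---- archive dumps -------------------------------------------------------
  arch_acc <- list(circbase = list(), circrnadb = list())
  cb_rows <- keep(jinfo, ~"circbase" %in% .x$archives)
  cb_rows <- cb_rows[order(map_int(cb_rows, "start"), map_int(cb_rows, "end"))]
  cb_lines <- paste(c("circRNA_ID", "position", "strand", "gene_symbol"),
                    collapse = "\t")
  for (i in seq_along(cb_rows)) {
    ji <- cb_rows[[i]]
    acc <- sprintf("hsa_circ_%07d", i)
    arch_acc$circbase[[ji$key]] <- acc
    cb_lines <- c(cb_lines, paste(c(
      acc, sprintf("%s:%d-%d", ji$contig, ji$start + 1L, ji$end),
      ji$strand, ji$gene_symbol %||% "n/a"), collapse = "\t"))
  }
  cb_path <- file.path(out_dir, "circbase.tsv")
  writeLines(cb_lines, cb_path)

  db_rows <- keep(jinfo, ~"circrnadb" %in% .x$archives)
  db_rows <- db_rows[order(map_int(db_rows, "start"), map_int(db_rows, "end"))]
  db_lines <- paste(c("circRNA_ID", "chr", "start", "end", "strand",
                      "gene_symbol"), collapse = "\t")
  for (i in seq_along(db_rows)) {
    ji <- db_rows[[i]]
    acc <- sprintf("circdb_%05d", i)
    arch_acc$circrnadb[[ji$key]] <- acc
    db_lines <- c(db_lines, paste(c(
      acc, ji$contig, ji$start + 1L, ji$end, ji$strand,
      ji$gene_symbol %||% "n/a"), collapse = "\t"))
  }
  db_path <- file.path(out_dir, "circrnadb.tsv")
  writeLines(db_lines, db_path)

  ## ---- protein domains -----------------------------------------------------
  dom_path <- file.path(out_dir, "domains.tsv")
  writeLines(c(
    paste(c("protein_id", "feature_type", "description", "begin", "end"),
          collapse = "\t"),
    "TX_COMS\tDOMAIN\tphosphatase-like\t10\t30",
    "TX_COMS\tMOTIF\tcatalytic-loop\t40\t45"
  ), dom_path)

  ## ---- Venn bookkeeping (independent of reconcile()) -----------------------
  db_labels <- c("denovo", "circbase", "circrnadb")
  venn_db <- list()
  for (ji in jinfo) {
    member <- c(length(ji$compartments) > 0L,
                "circbase" %in% ji$archives,
                "circrnadb" %in% ji$archives)
    region <- paste(db_labels[member], collapse = "&")
    venn_db[[region]] <- (venn_db[[region]] %||% 0L) + 1L
  }
  venn_comp <- list()
  for (ji in keep(jinfo, ~length(.x$compartments) > 0L)) {
    region <- paste(COMPARTMENTS[COMPARTMENTS %in% ji$compartments],
                    collapse = "&")
    venn_comp[[region]] <- (venn_comp[[region]] %||% 0L) + 1L
  }

  ## ---- ground truth + config ----------------------------------------------
  truth <- list(
    seed = spec$seed,
    params = list(tolerance = 2L, min_reads = 2L, min_peptide = 1L),
    junctions = map(jinfo, function(ji) {
      list(id = ji$id, key = ji$key, contig = ji$contig, start = ji$start,
           end = ji$end, strand = ji$strand, name = ji$name,
           gene_symbol = ji$gene_symbol, exon_m = ji$exon_m,
           exon_n = ji$exon_n, transcript = ji$transcript,
           compartments = as.list(ji$compartments),
           archives = map(stats::setNames(ji$archives, ji$archives),
                          ~arch_acc[[.x]][[ji$key]]),
           scenario = ji$scenario, has_orf = ji$has_orf,
           circle_seq = ji$circle_seq, orf = ji$exp)
    }),
    venn_db = venn_db,
    venn_compartments = venn_comp,
    viz = list(gene = "PTPX", n_transcripts = 3L, n_circles = 12L),
    protein = list(id = "TX_COMS",
                   length = tx_layout[["TX_COMS"]]$cds_len %/% 3L - 1L)
  )
  truth_path <- file.path(out_dir, "ground_truth.json")
  jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)

  cfg <- list(
    genome = "genome.fa", gtf = "annotation.gtf",
    junctions = map(COMPARTMENTS, ~list(
      path = sprintf("ciri_%s.tsv", .x), dialect = "ciri",
      label = .x, compartment = .x)),
    archives = list(list(path = "circbase.tsv", dialect = "circbase"),
                    list(path = "circrnadb.tsv", dialect = "circrnadb")),
    domains = "domains.tsv",
    out_dir = "out", tolerance = 2L, min_reads = 2L, min_peptide = 1L
  )
  cfg_path <- file.path(out_dir, "config.yml")
  yaml::write_yaml(cfg, cfg_path)

  manifest <- tibble(
    file = c("genome.fa", "annotation.gtf",
             sprintf("ciri_%s.tsv", COMPARTMENTS), "circbase.tsv",
             "circrnadb.tsv", "domains.tsv", "ground_truth.json",
             "config.yml"),
    path = c(genome_path, gtf_path, ciri_paths, cb_path, db_path, dom_path,
             truth_path, cfg_path)
  )
  invisible(list(manifest = manifest, truth = truth,
                 transcripts = transcripts))
}

# internal: convert transcript-coordinate CDS [s,e) to genomic intervals
cds_to_genomic <- function(cds_t, offs, exon_lens, gexons, strand) {
  if (is.null(cds_t)) return(tibble(start = integer(), end = integer()))
  s <- cds_t[1L]; e <- cds_t[2L]
  cum <- cumsum(c(0L, exon_lens))
  out <- list()
  for (i in seq_along(exon_lens)) {
    o1 <- max(s, cum[i]); o2 <- min(e, cum[i] + exon_lens[i])
    if (o1 >= o2) next
    d1 <- o1 - cum[i]; d2 <- o2 - cum[i]
    ex <- gexons[gexons$index == i, ]
    if (strand == "+") {
      out[[length(out) + 1L]] <- tibble(start = ex$start + d1,
                                        end = ex$start + d2)
    } else {
      out[[length(out) + 1L]] <- tibble(start = ex$end - d2,
                                        end = ex$end - d1)
    }
  }
  res <- bind_rows(out)
  if (nrow(res) == 0L) res else arrange(res, .data$start)
}
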