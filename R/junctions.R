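#' The four subcellular compartment labels
#'
#' Fractionated RNA-seq junction calls are labelled with one of four
#' compartments: cytoplasm, nucleoplasm, chromatin (the insoluble part of the
#' nuclear lysate) and polysome (heavy sucrose-gradient fractions).
#' @export
COMPARTMENTS <- c("cytoplasm", "nucleoplasm", "chromatin", "polysome")

# internal: canonical empty junction tibble
empty_junction_table <- function() {
  tibble(
    contig = character(), start = integer(), end = integer(),
    strand = character(), sources = list(), read_support = list(),
    accessions = list()
  )
}

# internal: collapse duplicate keys, unioning sources/support/accessions
dedup_junctions <- function(df) {
  if (nrow(df) == 0L) return(empty_junction_table())
  for (col in c("sources", "read_support", "accessions")) {
    if (!col %in% names(df)) {
      df[[col]] <- map(seq_len(nrow(df)), ~list())
    }
  }
  df <- df[, c("contig", "start", "end", "strand", "sources",
               "read_support", "accessions")]
  df |>
    mutate(.key = junction_key(.data$contig, .data$start, .data$end, .data$strand)) |>
    group_by(.data$.key) |>
    summarise(
      contig = .data$contig[1L], start = .data$start[1L],
      end = .data$end[1L], strand = .data$strand[1L],
      sources = list(sort(unique(unlist(.data$sources)))),
      read_support = list(unlist_keep_first(.data$read_support)),
      accessions = list(unlist_keep_first(.data$accessions)),
      .groups = "drop"
    ) |>
    arrange(.data$contig, .data$start, .data$end, .data$strand) |>
    select(-".key")
}

# internal: merge named lists across records; first value wins per name
unlist_keep_first <- function(lst) {
  flat <- unlist(lst, recursive = FALSE)
  if (is.null(flat) || length(flat) == 0L) return(list())
  as.list(flat[!duplicated(names(flat))])
}

#' Merge junction tables on the exact key
#'
#' Rows with equal keys (`contig`, `start`, `end`, `strand`) are collapsed;
#' source labels are unioned and per-source read support and archive
#' accessions are kept side by side (never summed across sources).
#'
#' @param ... Junction tibbles as produced by the parsers.
#' @return A deduplicated junction tibble sorted by key.
#' @export
merge_junctions <- function(...) {
  dedup_junctions(bind_rows(...))
}

#' Parse a CIRI2-style backsplice junction table
#'
#' CIRI2 reports 1-based inclusive circRNA start/end; these are converted to
#' the internal 0-based half-open convention (`start - 1`, `end`). Rows whose
#' junction-read count is below `min_reads` are dropped. The default of 2
#' junction reads discards single-read calls, the usual weakly supported tail
#' of a CIRI2 run.
#'
#' @param path TSV file with a header row containing at least `circRNA_ID`,
#'   `chr`, `circRNA_start`, `circRNA_end`, `#junction_reads`, `strand`.
#' @param source_label Label under which read support is recorded
#'   (e.g. a compartment or sample name).
#' @param min_reads Minimum junction-read count to keep a row.
#' @return A junction tibble (see [merge_junctions()] for the columns).
#' @export
parse_ciri <- function(path, source_label, min_reads = 2L) {
  df <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                        progress = FALSE)
  assert_cols(df, c("circRNA_ID", "chr", "circRNA_start", "circRNA_end",
                    "#junction_reads", "strand"), "CIRI2 table")
  if (nrow(df) == 0L) return(empty_junction_table())
  start <- suppressWarnings(as.integer(df$circRNA_start))
  end <- suppressWarnings(as.integer(df$circRNA_end))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad) > 0L) {
    abort(sprintf("CIRI2 table: non-numeric coordinate at row %d", bad[1L]))
  }
  reads <- suppressWarnings(as.integer(df$`#junction_reads`))
  if (anyNA(reads)) {
    abort(sprintf("CIRI2 table: non-numeric #junction_reads at row %d",
                  which(is.na(reads))[1L]))
  }
  assert_strand(df$strand)
  out <- tibble(
    contig = df$chr, start = start - 1L, end = end,
    strand = df$strand,
    sources = map(seq_len(nrow(df)), ~source_label),
    read_support = map(reads, ~stats::setNames(list(.x), source_label)),
    accessions = map(seq_len(nrow(df)), ~list())
  ) |>
    filter(unlist(map_int(.data$read_support, ~.x[[1L]])) >= min_reads)
  dedup_junctions(out)
}

#' Parse a BED6 junction file
#'
#' BED is already 0-based half-open, so coordinates are adopted unchanged;
#' the score column is treated as junction-read support. Strand is mandatory:
#' a circle's sequence depends on it, so `.` is rejected rather than guessed.
#'
#' @param path BED6 file (chrom, chromStart, chromEnd, name, score, strand).
#' @param source_label Label under which read support is recorded.
#' @return A junction tibble.
#' @export
parse_bed <- function(path, source_label) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "track") &
                   !startsWith(lines, "#")]
  if (length(lines) == 0L) return(empty_junction_table())
  fields <- str_split(lines, "\t")
  if (any(lengths(fields) < 6L)) {
    abort(sprintf("BED6 requires >= 6 columns (line %d)",
                  which(lengths(fields) < 6L)[1L]))
  }
  m <- do.call(rbind, map(fields, ~.x[1:6]))
  assert_strand(m[, 6L])
  score <- suppressWarnings(as.integer(m[, 5L]))
  score[is.na(score)] <- 0L
  out <- tibble(
    contig = m[, 1L],
    start = as.integer(m[, 2L]), end = as.integer(m[, 3L]),
    strand = m[, 6L],
    sources = map(seq_len(nrow(m)), ~source_label),
    read_support = map(score, ~stats::setNames(list(.x), source_label)),
    accessions = map(seq_len(nrow(m)), ~list())
  )
  dedup_junctions(out)
}

#' Write normalized junctions to BED6
#'
#' @param junctions A junction tibble.
#' @param path Output path.
#' @param source_label Optional source whose read support fills the score
#'   column (defaults to the maximum support across sources, 0 if none).
#' @return `path`, invisibly.
#' @export
write_bed <- function(junctions, path, source_label = NULL) {
  score <- map_int(junctions$read_support, function(rs) {
    if (!is.null(source_label)) {
      as.integer(rs[[source_label]] %||% 0L)
    } else if (length(rs) == 0L) 0L else as.integer(max(unlist(rs)))
  })
  name <- junction_key(junctions)
  writeLines(sprintf("%s\t%d\t%d\t%s\t%d\t%s",
                     junctions$contig, junctions$start, junctions$end,
                     name, score, junctions$strand), path)
  invisible(path)
}

#' Parse an archived circRNA database dump
#'
#' Reads circBase- or circRNADb-style record tables. The accession of each
#' record (e.g. `hsa_circ_0000001`) is stored under the dialect's source
#' label so downstream annotation tables can echo in which database a
#' junction was archived. Coordinates are assumed 1-based inclusive unless
#' `column_map$coord_base = 0`.
#'
#' @param path TSV file with a header row.
#' @param dialect `"circbase"` (accession + `chrN:start-end` position column
#'   + strand) or `"circrnadb"` (accession + separate chrom/start/end
#'   columns + strand).
#' @param column_map Optional named list overriding column names and
#'   coordinate convention; recognised entries: `accession`, `position`,
#'   `chrom`, `start`, `end`, `strand`, `coord_base` (0 or 1).
#' @return A junction tibble; rows with unparsable positions are skipped with
#'   a warning, and the number skipped is recorded in the
#'   `skipped_rows` attribute.
#' @export
parse_archive <- function(path, dialect = c("circbase", "circrnadb"),
                          column_map = NULL) {
  dialect <- match.arg(dialect)
  defaults <- switch(dialect,
    circbase = list(accession = "circRNA_ID", position = "position",
                    strand = "strand", coord_base = 1L),
    circrnadb = list(accession = "circRNA_ID", chrom = "chr",
                     start = "start", end = "end", strand = "strand",
                     coord_base = 1L)
  )
  cmap <- utils::modifyList(defaults, as.list(column_map %||% list()))
  df <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                        progress = FALSE)
  skipped <- 0L
  if (!is.null(cmap$position) && cmap$position %in% names(df)) {
    assert_cols(df, c(cmap$accession, cmap$position, cmap$strand),
                sprintf("%s archive", dialect))
    m <- str_match(df[[cmap$position]], "^([^:]+):(\\d+)-(\\d+)$")
    bad <- is.na(m[, 1L])
    skipped <- sum(bad)
    if (skipped > 0L) {
      warn(sprintf("%s archive: skipped %d row(s) with unparsable position",
                   dialect, skipped))
    }
    df <- df[!bad, , drop = FALSE]
    m <- m[!bad, , drop = FALSE]
    contig <- m[, 2L]
    start <- as.integer(m[, 3L])
    end <- as.integer(m[, 4L])
  } else {
    assert_cols(df, c(cmap$accession, cmap$chrom, cmap$start, cmap$end,
                      cmap$strand), sprintf("%s archive", dialect))
    contig <- df[[cmap$chrom]]
    start <- suppressWarnings(as.integer(df[[cmap$start]]))
    end <- suppressWarnings(as.integer(df[[cmap$end]]))
    bad <- is.na(start) | is.na(end)
    skipped <- sum(bad)
    if (skipped > 0L) {
      warn(sprintf("%s archive: skipped %d row(s) with non-numeric coordinates",
                   dialect, skipped))
    }
    df <- df[!bad, , drop = FALSE]
    contig <- contig[!bad]; start <- start[!bad]; end <- end[!bad]
  }
  if (nrow(df) == 0L) {
    out <- empty_junction_table()
    attr(out, "skipped_rows") <- skipped
    return(out)
  }
  if (identical(as.integer(cmap$coord_base), 1L)) start <- start - 1L
  assert_strand(df[[cmap$strand]])
  out <- tibble(
    contig = contig, start = start, end = end, strand = df[[cmap$strand]],
    sources = map(seq_len(nrow(df)), ~dialect),
    read_support = map(seq_len(nrow(df)), ~list()),
    accessions = map(df[[cmap$accession]],
                     ~stats::setNames(list(.x), dialect))
  )
  out <- dedup_junctions(out)
  attr(out, "skipped_rows") <- skipped
  out
}

#' Reconcile junction sets into a Venn partition
#'
#' Junctions from different sources (databases, de novo calls) are compared
#' by exact key equality; the union is partitioned into the regions of the
#' Venn diagram over the labelled sets. Because matching is on normalized
#' coordinates rather than database accessions, sets with incompatible
#' accession schemes become directly comparable.
#'
#' @param sets Named list (>= 2 entries) of junction tibbles.
#' @return A tibble with one row per non-empty label subset: `region`
#'   (labels joined by `&`), `n_sets`, and `count`. Region counts sum to the
#'   number of distinct junction keys in the union.
#' @export
reconcile <- function(sets) {
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    abort("sets must be a named list")
  }
  if (length(sets) < 2L) abort("need >=2 sets to reconcile")
  labels <- names(sets)
  keysets <- map(sets, ~unique(junction_key(.x)))
  all_keys <- sort(unique(unlist(keysets)))
  member <- vapply(keysets, function(k) all_keys %in% k,
                   logical(length(all_keys)))
  if (length(all_keys) == 1L) member <- matrix(member, nrow = 1L)
  region <- apply(member, 1L, function(row) paste(labels[row], collapse = "&"))
  counts <- table(region)
  tibble(
    region = names(counts),
    n_sets = map_int(str_split(names(counts), "&"), length),
    count = as.integer(counts)
  ) |>
    arrange(.data$n_sets, .data$region)
}

#' Subcellular localization profiles
#'
#' Builds one presence profile per distinct junction key across the four
#' subcellular compartments: `present[compartment]` is `TRUE` iff the key
#' occurs in that compartment's junction calls.
#'
#' @param calls Named list mapping compartment labels (a subset of
#'   [COMPARTMENTS]) to junction tibbles.
#' @return A tibble with the junction key columns plus one logical column per
#'   compartment (all four always present, `FALSE` where the compartment was
#'   not supplied or the junction is absent from it).
#' @export
localization_profiles <- function(calls) {
  unknown <- setdiff(names(calls), COMPARTMENTS)
  if (length(unknown) > 0L) {
    abort(sprintf("unknown compartment label(s): %s (allowed: %s)",
                  paste(unknown, collapse = ", "),
                  paste(COMPARTMENTS, collapse = ", ")))
  }
  all_j <- dedup_junctions(bind_rows(calls))
  if (nrow(all_j) == 0L) {
    out <- all_j[, c("contig", "start", "end", "strand")]
    for (cp in COMPARTMENTS) out[[cp]] <- logical(0)
    return(out)
  }
  keys <- junction_key(all_j)
  out <- all_j[, c("contig", "start", "end", "strand")]
  for (cp in COMPARTMENTS) {
    ck <- if (cp %in% names(calls)) unique(junction_key(calls[[cp]])) else character(0)
    out[[cp]] <- keys %in% ck
  }
  out
}
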