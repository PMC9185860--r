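#' Read gene models from an Ensembl-dialect GTF
#'
#' Parses `exon` and `CDS` features into a tidy transcript-model table. GTF
#' coordinates (1-based, inclusive) are converted to the package-internal
#' convention, 0-based half-open on the forward genomic strand. Exon ordinals
#' are assigned in transcript 5'->3' order: ascending genomic start on the
#' plus strand, descending on the minus strand. A transcript is flagged
#' `has_ccds` when any of its features carries a `tag "CCDS"` or a `ccds_id`
#' attribute. All other feature types are ignored.
#'
#' @param path Path to a GTF file (tab-separated, 9 columns, attributes as
#'   `key "value";` pairs).
#' @return A tibble with one row per transcript: `transcript_id`, `gene_id`,
#'   `gene_symbol`, `contig`, `strand`, `has_ccds`, `n_exons`, `length`,
#'   and list-columns `exons` (tibble `start`, `end`, `index`) and `cds`
#'   (tibble `start`, `end`, genomic intervals).
#' @export
read_gtf <- function(path) {
  if (!file.exists(path)) abort(sprintf("GTF not found: %s", path))
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(lines) == 0L) {
    return(empty_transcript_table())
  }
  fields <- str_split(lines, "\t")
  nf <- lengths(fields)
  if (any(nf != 9L)) {
    abort(sprintf("malformed GTF: expected 9 tab-separated columns at line %d",
                  which(nf != 9L)[1L]))
  }
  m <- do.call(rbind, fields)
  feat <- m[, 3L]
  keep <- feat %in% c("exon", "CDS")
  if (!any(keep)) return(empty_transcript_table())
  m <- m[keep, , drop = FALSE]
  attrs <- m[, 9L]

  tx_id <- gtf_attr(attrs, "transcript_id")
  no_tx <- is.na(tx_id)
  if (any(no_tx)) {
    warn(sprintf("skipping %d GTF feature(s) without transcript_id", sum(no_tx)))
    m <- m[!no_tx, , drop = FALSE]
    attrs <- attrs[!no_tx]
    tx_id <- tx_id[!no_tx]
  }
  if (nrow(m) == 0L) return(empty_transcript_table())

  df <- tibble(
    contig = m[, 1L],
    feature = m[, 3L],
    start = suppressWarnings(as.integer(m[, 4L])) - 1L,  # 1-based -> 0-based
    end = suppressWarnings(as.integer(m[, 5L])),
    strand = m[, 7L],
    transcript_id = tx_id,
    gene_id = gtf_attr(attrs, "gene_id"),
    gene_symbol = gtf_attr(attrs, "gene_name"),
    ccds = !is.na(gtf_attr(attrs, "ccds_id")) |
      str_detect(attrs, "tag\\s+\"CCDS\"")
  )
  if (anyNA(df$start) || anyNA(df$end)) {
    abort("malformed GTF: non-numeric start/end coordinate")
  }
  assert_strand(df$strand)

  build_one <- function(d) {
    if (length(unique(d$strand)) > 1L || length(unique(d$contig)) > 1L) {
      abort(sprintf("inconsistent strand/contig within transcript '%s'",
                    d$transcript_id[1L]))
    }
    strand <- d$strand[1L]
    ex <- d[d$feature == "exon", c("start", "end")]
    ex <- ex[order(ex$start, decreasing = (strand == "-")), , drop = FALSE]
    ex$index <- seq_len(nrow(ex))
    cd <- d[d$feature == "CDS", c("start", "end")]
    cd <- cd[order(cd$start), , drop = FALSE]
    tibble(
      transcript_id = d$transcript_id[1L],
      gene_id = d$gene_id[1L] %||% NA_character_,
      gene_symbol = d$gene_symbol[1L] %||% d$gene_id[1L],
      contig = d$contig[1L],
      strand = strand,
      has_ccds = any(d$ccds),
      n_exons = nrow(ex),
      length = sum(ex$end - ex$start),
      exons = list(as_tibble(ex)),
      cds = list(as_tibble(cd))
    )
  }
  out <- df |>
    mutate(gene_symbol = ifelse(is.na(.data$gene_symbol),
                                .data$gene_id, .data$gene_symbol)) |>
    group_by(.data$transcript_id) |>
    dplyr::group_map(~ build_one(dplyr::bind_cols(.x, .y))) |>
    bind_rows() |>
    arrange(.data$transcript_id)
  out
}

empty_transcript_table <- function() {
  tibble(
    transcript_id = character(), gene_id = character(),
    gene_symbol = character(), contig = character(), strand = character(),
    has_ccds = logical(), n_exons = integer(), length = integer(),
    exons = list(), cds = list()
  )
}

# internal: extract one `key "value"` attribute from GTF column 9
gtf_attr <- function(attrs, key) {
  str_match(attrs, paste0("(?:^|;)\\s*", key, "\\s+\"([^\"]*)\""))[, 2L]
}

#' Write transcript models back to GTF
#'
#' Inverse of [read_gtf()]: emits one `exon` line per exon (in transcript
#' order, with `exon_number`) and one `CDS` line per CDS interval, converting
#' internal 0-based half-open coordinates back to GTF 1-based inclusive.
#' Transcripts flagged `has_ccds` carry a `ccds_id` attribute.
#'
#' @param transcripts Transcript table as returned by [read_gtf()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(transcripts, path) {
  lines <- character(0)
  for (i in seq_len(nrow(transcripts))) {
    tr <- as_transcript_row(transcripts[i, ])
    base_attr <- sprintf('gene_id "%s"; transcript_id "%s"; gene_name "%s";',
                         tr$gene_id, tr$transcript_id, tr$gene_symbol)
    if (isTRUE(tr$has_ccds)) {
      base_attr <- paste0(base_attr, sprintf(' ccds_id "CCDS_%s";', tr$transcript_id))
    }
    ex <- tr$exons
    lines <- c(lines, sprintf(
      "%s\tcircann\texon\t%d\t%d\t.\t%s\t.\t%s exon_number \"%d\";",
      tr$contig, ex$start + 1L, ex$end, tr$strand, base_attr, ex$index))
    cd <- tr$cds
    if (nrow(cd) > 0L) {
      # GTF frame: bases to skip before the first full codon of the block
      ord <- if (tr$strand == "+") order(cd$start) else order(-cd$start)
      cd <- cd[ord, , drop = FALSE]
      cum <- cumsum(c(0L, (cd$end - cd$start)[-nrow(cd)]))
      frame <- (3L - cum %% 3L) %% 3L
      lines <- c(lines, sprintf(
        "%s\tcircann\tCDS\t%d\t%d\t.\t%s\t%d\t%s",
        tr$contig, cd$start + 1L, cd$end, tr$strand, frame, base_attr))
    }
  }
  writeLines(lines, path)
  invisible(path)
}
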