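#' Read a genome FASTA into a named sequence set
#'
#' Loads a (multi-record) FASTA file as an uppercase `DNAStringSet`. Lowercase
#' soft-masked bases are uppercased; contig names are taken as the first
#' whitespace-delimited token of each header and must be unique.
#'
#' @param path Path to a FASTA file.
#' @return A [Biostrings::DNAStringSet] named by contig.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">chrT", "ACGT"), fa)
#' read_genome(fa)
#' @export
read_genome <- function(path) {
  if (!file.exists(path)) abort(sprintf("genome FASTA not found: %s", path))
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) abort(sprintf("no records in FASTA: %s", path))
  if (!startsWith(first, ">")) {
    abort(sprintf("malformed FASTA (line 1 does not start with '>'): %s", path))
  }
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0L) abort(sprintf("no records in FASTA: %s", path))
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(names(seqs))) {
    dup <- unique(names(seqs)[duplicated(names(seqs))])
    abort(sprintf("duplicate contig name(s) in FASTA: %s",
                  paste(dup, collapse = ", ")))
  }
  Biostrings::DNAStringSet(toupper(seqs))
}

# internal: fetch [start, end) (0-based half-open) from one contig, forward strand
genome_slice <- function(genome, contig, start, end) {
  if (!contig %in% names(genome)) {
    abort(sprintf("contig '%s' not present in genome", contig))
  }
  len <- length(genome[[contig]])
  if (start < 0L || end > len || start >= end) {
    abort(sprintf("interval [%d,%d) out of range for contig '%s' (length %d)",
                  start, end, contig, len))
  }
  as.character(Biostrings::subseq(genome[[contig]], start + 1L, end))
}

#' Spliced transcript sequence
#'
#' Concatenates the exon sequences of a transcript in transcript (5'->3')
#' order. For minus-strand transcripts each genomic block is
#' reverse-complemented and blocks are taken in transcript order.
#'
#' @param transcript One row of a transcript model table (see [read_gtf()]),
#'   or a list with fields `contig`, `strand` and `exons`.
#' @param genome A genome as returned by [read_genome()].
#' @param exon_range Optional contiguous range of exon ordinals
#'   (e.g. `2:3`); defaults to all exons.
#' @return A single nucleotide string.
#' @export
spliced_sequence <- function(transcript, genome, exon_range = NULL) {
  tr <- as_transcript_row(transcript)
  exons <- tr$exons
  if (is.null(exon_range)) exon_range <- seq_len(nrow(exons))
  exon_range <- sort(unique(as.integer(exon_range)))
  if (length(exon_range) == 0L ||
      any(exon_range < 1L) || any(exon_range > nrow(exons))) {
    abort(sprintf("exon ordinal range out of bounds for transcript '%s' (%d exons)",
                  tr$transcript_id, nrow(exons)))
  }
  if (!identical(exon_range, seq(min(exon_range), max(exon_range)))) {
    abort("exon_range must be a contiguous range of ordinals")
  }
  exons <- exons[match(exon_range, exons$index), , drop = FALSE]
  blocks <- map_chr(seq_len(nrow(exons)), function(i) {
    s <- genome_slice(genome, tr$contig, exons$start[i], exons$end[i])
    if (tr$strand == "-") revcomp(s) else s
  })
  paste(blocks, collapse = "")
}

# internal: accept a one-row tibble or list describing a transcript
as_transcript_row <- function(transcript) {
  if (is.data.frame(transcript)) {
    if (nrow(transcript) != 1L) abort("expected exactly one transcript row")
    list(
      transcript_id = transcript$transcript_id,
      gene_id = transcript$gene_id,
      gene_symbol = transcript$gene_symbol,
      contig = transcript$contig,
      strand = transcript$strand,
      has_ccds = transcript$has_ccds,
      length = transcript$length,
      exons = transcript$exons[[1L]],
      cds = transcript$cds[[1L]]
    )
  } else if (is.list(transcript)) {
    transcript
  } else {
    abort("transcript must be a one-row data frame or a list")
  }
}

#' Mirror a genome (reverse-complement every contig)
#'
#' Utility for strand-correctness checks: reverse-complements every contig.
#' Used together with [mirror_transcripts()] and [mirror_junctions()], the
#' mirrored data describe the same molecules on flipped strands, so all
#' spliced and circular sequences must be invariant.
#'
#' @param genome A [Biostrings::DNAStringSet].
#' @return A mirrored `DNAStringSet`.
#' @export
mirror_genome <- function(genome) {
  Biostrings::reverseComplement(genome)
}

#' @rdname mirror_genome
#' @param transcripts A transcript model table from [read_gtf()].
#' @export
mirror_transcripts <- function(transcripts, genome) {
  clen <- stats::setNames(Biostrings::width(genome), names(genome))
  transcripts |>
    mutate(
      strand = ifelse(.data$strand == "+", "-", "+"),
      exons = map2(.data$exons, .data$contig, function(ex, ctg) {
        L <- clen[[ctg]]
        tibble(
          start = L - ex$end, end = L - ex$start, index = ex$index
        ) |> arrange(.data$index)
      }),
      cds = map2(.data$cds, .data$contig, function(cd, ctg) {
        if (nrow(cd) == 0L) return(cd)
        L <- clen[[ctg]]
        tibble(start = L - cd$end, end = L - cd$start) |> arrange(.data$start)
      })
    )
}

#' @rdname mirror_genome
#' @param junctions A junction table (see [parse_ciri()]).
#' @export
mirror_junctions <- function(junctions, genome) {
  clen <- stats::setNames(Biostrings::width(genome), names(genome))
  L <- clen[junctions$contig]
  junctions |>
    mutate(
      start2 = L - .data$end, end2 = L - .data$start,
      strand = ifelse(.data$strand == "+", "-", "+")
    ) |>
    mutate(start = .data$start2, end = .data$end2) |>
    select(-"start2", -"end2")
}
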