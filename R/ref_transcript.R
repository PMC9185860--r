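#' Match a backsplice junction to candidate transcripts
#'
#' A transcript matches a junction when the circle's 5' end lies within
#' `tolerance` nt of some exon's transcript-5' boundary (the acceptor side)
#' and the circle's 3' end within `tolerance` nt of some exon's
#' transcript-3' boundary (the donor side), with acceptor exon ordinal M <=
#' donor exon ordinal N. On the plus strand the circle's 5' end is the
#' genomic-left junction end; on the minus strand the genomic-left end maps
#' to the donor side and the genomic-right end to the acceptor.
#'
#' Offsets are signed in transcript orientation: a positive acceptor offset
#' means the circle starts downstream of (inside) the acceptor exon's 5'
#' boundary; a positive donor offset means the circle extends past the donor
#' exon's 3' boundary. `total_offset = |acceptor| + |donor|` is zero iff both
#' junction ends coincide exactly with annotated exon boundaries.
#'
#' @param junction One junction (one-row tibble or list with `contig`,
#'   `start`, `end`, `strand`).
#' @param transcripts Transcript model table ([read_gtf()]).
#' @param tolerance Maximum absolute per-end offset in nt. The default of
#'   2 nt absorbs aligner wobble at splice boundaries.
#' @return A tibble of matches: `transcript_id`, `gene_id`, `gene_symbol`,
#'   `acceptor_exon` (M), `donor_exon` (N), `acceptor_offset`,
#'   `donor_offset`, `total_offset`, `has_ccds`, `n_exons`, `length`.
#'   Zero rows when nothing matches.
#' @export
match_transcripts <- function(junction, transcripts, tolerance = 2L) {
  j <- if (is.data.frame(junction)) as.list(junction[1L, ]) else junction
  cand <- transcripts |>
    filter(.data$contig == j$contig, .data$strand == j$strand)
  if (nrow(cand) == 0L) return(empty_match_table())
  rows <- map(seq_len(nrow(cand)), function(i) {
    tr <- as_transcript_row(cand[i, ])
    ex <- tr$exons
    if (tr$strand == "+") {
      acc_off <- j$start - ex$start   # circle 5' end vs exon 5' boundary
      don_off <- j$end - ex$end       # circle 3' end vs exon 3' boundary
    } else {
      acc_off <- ex$end - j$end
      don_off <- ex$start - j$start
    }
    acc_ok <- which(abs(acc_off) <= tolerance)
    don_ok <- which(abs(don_off) <= tolerance)
    if (length(acc_ok) == 0L || length(don_ok) == 0L) return(NULL)
    # nearest boundary on each side; ties broken toward the smaller ordinal
    acc_i <- acc_ok[order(abs(acc_off[acc_ok]), ex$index[acc_ok])][1L]
    don_i <- don_ok[order(abs(don_off[don_ok]), ex$index[don_ok])][1L]
    m <- ex$index[acc_i]; n <- ex$index[don_i]
    if (m > n) return(NULL)
    tibble(
      transcript_id = tr$transcript_id, gene_id = tr$gene_id,
      gene_symbol = tr$gene_symbol,
      acceptor_exon = m, donor_exon = n,
      acceptor_offset = as.integer(acc_off[acc_i]),
      donor_offset = as.integer(don_off[don_i]),
      total_offset = abs(acc_off[acc_i]) + abs(don_off[don_i]),
      has_ccds = tr$has_ccds, n_exons = nrow(ex), length = tr$length
    )
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0L) empty_match_table() else arrange(out, .data$transcript_id)
}

empty_match_table <- function() {
  tibble(
    transcript_id = character(), gene_id = character(),
    gene_symbol = character(), acceptor_exon = integer(),
    donor_exon = integer(), acceptor_offset = integer(),
    donor_offset = integer(), total_offset = integer(),
    has_ccds = logical(), n_exons = integer(), length = integer()
  )
}

#' Assign each junction a representative reference transcript
#'
#' Two-pass deterministic procedure. Pass one collects every
#' junction-transcript match and computes each transcript's *commonness*:
#' the number of distinct junctions of its gene that it matches. Pass two
#' ranks each junction's candidates lexicographically and takes the first:
#'
#' 1. `total_offset` ascending (best junction fit first — an ill-fitting
#'    transcript cannot define a valid exon pair);
#' 2. `has_ccds` (CCDS-tagged transcripts first);
#' 3. commonness descending (prefer the transcript already carrying the
#'    gene's other junctions, minimising reference transcripts per gene);
#' 4. exon count descending;
#' 5. transcript length descending;
#' 6. `transcript_id` ascending (total order; ties impossible beyond here).
#'
#' @param junctions Junction tibble.
#' @param transcripts Transcript model table.
#' @param tolerance Per-end matching tolerance in nt (see
#'   [match_transcripts()]).
#' @param criteria Character vector ordering the ranking criteria; any
#'   permutation of `c("offset", "ccds", "commonness", "n_exons", "length")`.
#' @return A tibble with one row per junction: key columns, `assigned`,
#'   `gene_id`, `gene_symbol`, `transcript_id`, `exon_m`, `exon_n`,
#'   `acceptor_offset`, `donor_offset`, `name` (see [circ_name()]),
#'   `competing_matches`. Unmatched junctions have `assigned = FALSE` and NA
#'   annotation fields.
#' @export
rank_and_assign <- function(junctions, transcripts, tolerance = 2L,
                            criteria = c("offset", "ccds", "commonness",
                                         "n_exons", "length")) {
  criteria <- match.arg(criteria, several.ok = TRUE,
                        choices = c("offset", "ccds", "commonness",
                                    "n_exons", "length"))
  junctions <- dedup_junctions(junctions)
  if (nrow(junctions) == 0L) {
    return(tibble(
      contig = character(), start = integer(), end = integer(),
      strand = character(), assigned = logical(), gene_id = character(),
      gene_symbol = character(), transcript_id = character(),
      exon_m = integer(), exon_n = integer(), acceptor_offset = integer(),
      donor_offset = integer(), name = character(),
      competing_matches = integer()
    ))
  }
  keys <- junction_key(junctions)
  matches <- map(seq_len(nrow(junctions)), function(i) {
    m <- match_transcripts(junctions[i, ], transcripts, tolerance)
    if (nrow(m) > 0L) m$.jkey <- keys[i]
    m
  })
  all_m <- bind_rows(matches)
  commonness <- if (nrow(all_m) > 0L) {
    all_m |>
      distinct(.data$transcript_id, .data$.jkey) |>
      dplyr::count(.data$transcript_id, name = "commonness")
  } else {
    tibble(transcript_id = character(), commonness = integer())
  }
  crit_cols <- c(offset = "total_offset", ccds = "has_ccds",
                 commonness = "commonness", n_exons = "n_exons",
                 length = "length")
  rows <- map(seq_len(nrow(junctions)), function(i) {
    j <- junctions[i, ]
    base <- tibble(
      contig = j$contig, start = j$start, end = j$end, strand = j$strand
    )
    m <- matches[[i]]
    if (nrow(m) == 0L) {
      return(mutate(base, assigned = FALSE, gene_id = NA_character_,
                    gene_symbol = NA_character_,
                    transcript_id = NA_character_,
                    exon_m = NA_integer_, exon_n = NA_integer_,
                    acceptor_offset = NA_integer_, donor_offset = NA_integer_,
                    name = NA_character_, competing_matches = 0L))
    }
    m <- left_join(m, commonness, by = "transcript_id")
    ord_args <- map(criteria, function(cr) {
      v <- m[[crit_cols[[cr]]]]
      if (cr == "offset") v else -xtfrm(v)   # offset ascending, rest descending
    })
    ord <- do.call(order, c(ord_args, list(m$transcript_id)))
    best <- m[ord[1L], ]
    mutate(base, assigned = TRUE, gene_id = best$gene_id,
           gene_symbol = best$gene_symbol,
           transcript_id = best$transcript_id,
           exon_m = best$acceptor_exon, exon_n = best$donor_exon,
           acceptor_offset = best$acceptor_offset,
           donor_offset = best$donor_offset,
           name = circ_name_chr(best$gene_symbol, best$acceptor_exon,
                                best$donor_exon),
           competing_matches = nrow(m))
  })
  bind_rows(rows)
}

# internal vectorized name builder
circ_name_chr <- function(symbol, m, n) {
  ifelse(m == n,
         sprintf("%s_e%d", symbol, m),
         sprintf("%s_e%d-e%d", symbol, m, n))
}

#' CircRNA display name
#'
#' The backsplice exon pair is appended to the gene symbol:
#' `SYMBOL_eM-eN` for a multi-exon circle, `SYMBOL_eM` when M = N. Example:
#' exon pair (2, 3) of gene PTP4A2 is displayed as `PTP4A2_e2-e3`.
#'
#' @param assignments Assignment tibble from [rank_and_assign()], or a
#'   gene symbol (with `m`, `n` given).
#' @param m,n Exon ordinals when `assignments` is a gene symbol.
#' @return Character vector of names.
#' @export
circ_name <- function(assignments, m = NULL, n = NULL) {
  if (is.character(assignments)) {
    return(circ_name_chr(assignments, as.integer(m), as.integer(n)))
  }
  if (any(!assignments$assigned)) {
    abort("cannot name unassigned junctions")
  }
  circ_name_chr(assignments$gene_symbol, assignments$exon_m,
                assignments$exon_n)
}
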