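STOP_CODONS <- c("TAA", "TAG", "TGA")

# internal: accept a circ_sequence object or plain string
circle_seq <- function(circle) {
  if (is.character(circle)) str_to_upper(circle) else circle$seq
}

#' Assemble the circular sequence for an assigned junction
#'
#' Concatenates exons M..N of the representative transcript (reverse
#' complemented per block for minus-strand transcripts, blocks in transcript
#' order) and adjusts both ends by the match offsets, so the circle reflects
#' the junction's actual genomic coordinates rather than the annotated exon
#' boundaries. Position 0 of the circle is the first base of the acceptor
#' exon (the circle's 5' end); the backsplice junction sits between position
#' L-1 and 0.
#'
#' @param assignment One assigned row from [rank_and_assign()].
#' @param transcripts Transcript model table.
#' @param genome Genome from [read_genome()].
#' @return An object of class `circ_sequence`: a list with `seq`, `L`,
#'   `blocks` (tibble `circle_start`, `circle_end`, `exon_index`,
#'   `genomic_start`, `genomic_end`), `contig`, `strand`, `transcript_id`,
#'   `name`.
#' @export
build_circle <- function(assignment, transcripts, genome) {
  a <- if (is.data.frame(assignment)) as.list(assignment[1L, ]) else assignment
  if (!isTRUE(a$assigned)) abort("cannot build a circle for an unassigned junction")
  tr_row <- transcripts[transcripts$transcript_id == a$transcript_id, ]
  if (nrow(tr_row) != 1L) {
    abort(sprintf("transcript '%s' not found in models", a$transcript_id))
  }
  tr <- as_transcript_row(tr_row)
  ords <- a$exon_m:a$exon_n
  ex <- tr$exons[match(ords, tr$exons$index), , drop = FALSE]
  gs <- ex$start
  ge <- ex$end
  acc <- as.integer(a$acceptor_offset %||% 0L)
  don <- as.integer(a$donor_offset %||% 0L)
  n <- nrow(ex)
  if (tr$strand == "+") {
    gs[1L] <- gs[1L] + acc          # positive acceptor offset shrinks the 5' end
    ge[n] <- ge[n] + don            # positive donor offset extends the 3' end
  } else {
    ge[1L] <- ge[1L] - acc
    gs[n] <- gs[n] - don
  }
  if (any(gs >= ge)) {
    abort("match offsets push a junction end outside its exon (empty block)")
  }
  blocks <- map_chr(seq_len(n), function(i) {
    s <- genome_slice(genome, tr$contig, gs[i], ge[i])
    if (tr$strand == "-") revcomp(s) else s
  })
  widths <- ge - gs
  cend <- cumsum(widths)
  structure(list(
    seq = paste(blocks, collapse = ""),
    L = sum(widths),
    blocks = tibble(
      circle_start = cend - widths, circle_end = cend,
      exon_index = ex$index, genomic_start = gs, genomic_end = ge
    ),
    contig = tr$contig, strand = tr$strand,
    transcript_id = tr$transcript_id,
    name = a$name %||% NA_character_
  ), class = "circ_sequence")
}

#' @export
print.circ_sequence <- function(x, ...) {
  cat(sprintf("<circ_sequence> %s (%s, %s strand, L=%d nt, %d exon block(s))\n",
              x$name %||% "?", x$transcript_id, x$strand, x$L,
              nrow(x$blocks)))
  invisible(x)
}

#' Enumerate ORFs on a circular sequence
#'
#' Rolling-circle ORF scan: the circle is unrolled (four copies plus two
#' bases, so that from any start in the first copy a full 3L nt of
#' lookahead is available) and scanned in all three frames. An ORF starts at
#' each ATG not preceded in-frame by another open ATG (maximal-ORF
#' convention: first ATG after a stop) and ends at the first in-frame stop
#' (TAA/TAG/TGA), stop codon included in `length_nt`. If no stop occurs
#' within 3L nt of a start, the reading has returned to the same circle
#' position in the same frame without terminating, which proves the ORF is
#' endless. Results are deduplicated on (start mod L, length).
#'
#' Junction crossings are computed by the closed form
#' `floor((start + length_nt - 1) / L)`; an ORF of length at most `L - start`
#' never touches the junction (0C), each additional wrap of the unrolled
#' reading adds one crossing, and an endless ORF crosses infinitely often.
#'
#' @param circle A `circ_sequence` or plain nucleotide string (L >= 3).
#' @param min_peptide Minimum peptide length (aa, stop excluded) to report a
#'   finite ORF. Endless ORFs are never dropped. The pipeline default of
#'   20 aa suppresses spurious micro-ORFs; tests typically use 1.
#' @return A tibble: `start` (0-based circle position of the A of ATG),
#'   `length_nt` (multiple of 3, 0 denotes endless), `crossings` (`Inf` for
#'   endless), `endless`, `orf_class` (`0C`, `1C5'`, `1C3'`, `2C`, `edlsC`;
#'   one-crossing ORFs are provisionally `1C3'` until
#'   [classify_novelty()] sees the parental CDS), `peptide` (for endless
#'   ORFs, one minimal period of the repeating peptide), `novel_n`,
#'   `novel_c`, `qualifier` (all NA until novelty classification).
#' @export
enumerate_orfs <- function(circle, min_peptide = 20L) {
  seq <- circle_seq(circle)
  L <- nchar(seq)
  if (L < 3L) abort("circle length must be >= 3 nt")
  if (!grepl("^[ACGTN]*$", seq)) abort("circle sequence must be A/C/G/T/N")
  unroll <- paste0(strrep(seq, 4L), substr(seq, 1L, 2L))
  W <- nchar(unroll)
  hits <- list()
  for (f in 0:2) {
    starts <- seq.int(f + 1L, W - 2L, by = 3L)           # 1-based codon starts
    codons <- substring(unroll, starts, starts + 2L)
    n <- length(codons)
    is_stop <- codons %in% STOP_CODONS
    atgs <- which(codons == "ATG")
    stops <- which(is_stop)
    if (length(atgs) == 0L) next
    # maximal-ORF convention: the first ATG after each stop opens an ORF
    grp <- findInterval(atgs - 1L, stops)   # index of last stop before each ATG
    opens <- atgs[!duplicated(grp)]
    for (o in opens) {
      ns_i <- findInterval(o, stops) + 1L   # first stop at or after the ATG
      ns <- if (ns_i <= length(stops)) stops[ns_i] else NA_integer_
      if (!is.na(ns) && ns - o + 1L <= L) {
        hits[[length(hits) + 1L]] <- c((starts[o] - 1L) %% L,
                                       (ns - o + 1L) * 3L, 0L)
      } else if (n - o >= L - 1L) {
        # L codons (3L nt) scanned without a stop: the reading is back at
        # the same circle position and frame, so the ORF is endless
        hits[[length(hits) + 1L]] <- c((starts[o] - 1L) %% L, 0L, 1L)
      }
    }
  }
  if (length(hits) == 0L) return(empty_orf_table())
  h <- do.call(rbind, hits)
  h <- h[!duplicated(h[, 1L] * 1e10 + h[, 2L] * 10 + h[, 3L]), , drop = FALSE]
  s <- h[, 1L]; len <- h[, 2L]; endless <- h[, 3L] == 1L
  ncod_endless <- if (L %% 3L == 0L) L %/% 3L else L
  pep_nt <- ifelse(endless, 3L * ncod_endless, len - 3L)
  peps <- character(nrow(h))
  nonzero <- pep_nt > 0L
  if (any(nonzero)) {
    frags <- substring(unroll, s[nonzero] + 1L, s[nonzero] + pep_nt[nonzero])
    peps[nonzero] <- if (any(grepl("N", frags, fixed = TRUE))) {
      as.character(Biostrings::translate(Biostrings::DNAStringSet(frags),
                                         no.init.codon = TRUE,
                                         if.fuzzy.codon = "solve"))
    } else {
      as.character(Biostrings::translate(Biostrings::DNAStringSet(frags),
                                         no.init.codon = TRUE))
    }
  }
  if (any(endless)) {
    peps[endless] <- vapply(peps[endless], minimal_period, character(1L),
                            USE.NAMES = FALSE)
  }
  len[endless] <- 0L
  keep <- endless | nchar(peps) >= min_peptide
  s <- s[keep]; len <- len[keep]; endless <- endless[keep]
  peps <- peps[keep]
  if (length(s) == 0L) return(empty_orf_table())
  ord <- order(s, len)
  s <- s[ord]; len <- len[ord]; endless <- endless[ord]; peps <- peps[ord]
  cross <- ifelse(endless, Inf, (s + len - 1) %/% L)
  cls <- ifelse(endless, "edlsC",
                ifelse(cross == 0, "0C", ifelse(cross == 1, "1C3'", "2C")))
  tibble(
    start = as.integer(s), length_nt = as.integer(len),
    crossings = as.numeric(cross), endless = endless, orf_class = cls,
    peptide = peps, novel_n = NA, novel_c = NA, qualifier = NA_character_
  )
}

empty_orf_table <- function() {
  tibble(start = integer(), length_nt = integer(), crossings = double(),
         endless = logical(), orf_class = character(), peptide = character(),
         novel_n = logical(), novel_c = logical(), qualifier = character())
}

# internal: minimal repeating unit of a string
minimal_period <- function(x) {
  n <- nchar(x)
  for (d in seq_len(n)) {
    if (n %% d == 0L &&
        strrep(substr(x, 1L, d), n %/% d) == x) {
      return(substr(x, 1L, d))
    }
  }
  x
}

#' Project the parental CDS onto a circle
#'
#' Intersects the representative transcript's annotated CDS with the
#' circle's exon blocks and maps it into circle coordinates, recording the
#' codon phase so ORF codons can be tested for being "parental" (identical
#' in position and frame to codons of the parental protein).
#'
#' @param assignment One assigned row from [rank_and_assign()].
#' @param circle The matching `circ_sequence` from [build_circle()].
#' @param transcripts Transcript model table.
#' @return A list of class `cds_projection`: `present` (any CDS on the
#'   circle), `intervals` (tibble `circle_start`, `circle_end`, `phase`,
#'   `cds_offset`: phase is the codon position 0/1/2 of the interval's first
#'   base, `cds_offset` its 0-based position in the full CDS), and `cds_pos`
#'   (integer vector over circle positions, NA outside the CDS).
#' @export
project_cds <- function(assignment, circle, transcripts) {
  a <- if (is.data.frame(assignment)) as.list(assignment[1L, ]) else assignment
  tr_row <- transcripts[transcripts$transcript_id == a$transcript_id, ]
  if (nrow(tr_row) != 1L) {
    abort(sprintf("transcript '%s' not found in models", a$transcript_id))
  }
  tr <- as_transcript_row(tr_row)
  cd <- tr$cds
  L <- circle$L
  empty <- structure(list(
    present = FALSE,
    intervals = tibble(circle_start = integer(), circle_end = integer(),
                       phase = integer(), cds_offset = integer()),
    cds_pos = rep(NA_integer_, L)
  ), class = "cds_projection")
  if (is.null(cd) || nrow(cd) == 0L) return(empty)
  # CDS blocks in translation order with cumulative offsets
  ord <- if (tr$strand == "+") order(cd$start) else order(-cd$start)
  cd <- cd[ord, , drop = FALSE]
  cum <- cumsum(c(0L, (cd$end - cd$start)[-nrow(cd)]))
  cds_pos <- rep(NA_integer_, L)
  for (b in seq_len(nrow(circle$blocks))) {
    blk <- circle$blocks[b, ]
    for (p in blk$circle_start:(blk$circle_end - 1L)) {
      g <- if (circle$strand == "+") {
        blk$genomic_start + (p - blk$circle_start)
      } else {
        blk$genomic_end - 1L - (p - blk$circle_start)
      }
      k <- which(cd$start <= g & g < cd$end)
      if (length(k) == 1L) {
        cds_pos[p + 1L] <- if (circle$strand == "+") {
          cum[k] + (g - cd$start[k])
        } else {
          cum[k] + (cd$end[k] - 1L - g)
        }
      }
    }
  }
  if (all(is.na(cds_pos))) return(empty)
  # maximal runs of consecutive circle positions with consecutive CDS positions
  runs <- list()
  rs <- NA_integer_
  for (p in 0:(L - 1L)) {
    here <- !is.na(cds_pos[p + 1L])
    cont <- here && !is.na(rs) &&
      p > 0L && !is.na(cds_pos[p]) && cds_pos[p + 1L] == cds_pos[p] + 1L
    if (here && is.na(rs)) {
      rs <- p
    } else if (here && !cont) {
      runs[[length(runs) + 1L]] <- c(rs, p)
      rs <- p
    } else if (!here && !is.na(rs)) {
      runs[[length(runs) + 1L]] <- c(rs, p)
      rs <- NA_integer_
    }
  }
  if (!is.na(rs)) runs[[length(runs) + 1L]] <- c(rs, L)
  intervals <- map(runs, function(r) {
    tibble(circle_start = r[1L], circle_end = r[2L],
           phase = cds_pos[r[1L] + 1L] %% 3L,
           cds_offset = cds_pos[r[1L] + 1L])
  }) |> bind_rows()
  structure(list(present = TRUE, intervals = intervals, cds_pos = cds_pos),
            class = "cds_projection")
}

# internal: is the codon whose first base sits at circle position c parental?
codon_parental <- function(c, cds_pos, L) {
  if (c + 2L > L - 1L) return(FALSE)         # straddles the junction
  v <- cds_pos[(c + 1L):(c + 3L)]
  !anyNA(v) && v[2L] == v[1L] + 1L && v[3L] == v[2L] + 1L && v[1L] %% 3L == 0L
}

#' Finalize ORF classes and terminal novelty against the parental CDS
#'
#' A codon of an ORF is *parental* when it coincides, in position and frame,
#' with a codon of the annotated CDS projected onto the circle. For ORFs
#' crossing the junction once, the pre- and post-junction segments are each
#' tested: a parental pre-junction segment with a novel post-junction
#' segment is a `1C3'` ORF (novel C terminus); the reverse is `1C5'` (novel
#' N terminus); both parental (an in-frame junction) stays `1C3'` with the
#' qualifier `frame-preserving` and no novelty; neither parental — or no CDS
#' on the host — stays `1C3'` with qualifier `no-parental-frame` and both
#' termini novel. Zero-crossing ORFs are indistinguishable from parental
#' ORFs (no novelty); two-or-more-crossing ORFs are novel at both ends;
#' endless ORFs (`edlsC`) are entirely junction-dependent and flagged novel
#' at both ends.
#'
#' @param orfs ORF tibble from [enumerate_orfs()].
#' @param projection `cds_projection` from [project_cds()].
#' @param L Circle length (taken from the projection's `cds_pos` if omitted).
#' @return The ORF tibble with `orf_class`, `novel_n`, `novel_c` and
#'   `qualifier` finalized.
#' @export
classify_novelty <- function(orfs, projection, L = length(projection$cds_pos)) {
  if (nrow(orfs) == 0L) return(orfs)
  cds_pos <- projection$cds_pos
  res <- map(seq_len(nrow(orfs)), function(i) {
    o <- orfs[i, ]
    if (o$endless) {
      o$orf_class <- "edlsC"; o$novel_n <- TRUE; o$novel_c <- TRUE
      o$qualifier <- NA_character_
      return(o)
    }
    cross <- o$crossings
    if (cross == 0) {
      o$orf_class <- "0C"; o$novel_n <- FALSE; o$novel_c <- FALSE
      o$qualifier <- NA_character_
      return(o)
    }
    if (cross >= 2) {
      o$orf_class <- "2C"; o$novel_n <- TRUE; o$novel_c <- TRUE
      o$qualifier <- NA_character_
      return(o)
    }
    # one crossing: compare each segment's codons with the parental frame
    u <- seq.int(o$start, o$start + o$length_nt - 3L, by = 3L)
    pre <- u[u + 2L <= L - 1L]
    post <- u[u >= L]
    par_ok <- function(us) {
      length(us) > 0L &&
        all(map_lgl(us, ~codon_parental(.x %% L, cds_pos, L)))
    }
    pre_par <- projection$present && par_ok(pre)
    post_par <- projection$present && par_ok(post)
    if (pre_par && !post_par) {
      o$orf_class <- "1C3'"; o$novel_n <- FALSE; o$novel_c <- TRUE
      o$qualifier <- NA_character_
    } else if (post_par && !pre_par) {
      o$orf_class <- "1C5'"; o$novel_n <- TRUE; o$novel_c <- FALSE
      o$qualifier <- NA_character_
    } else if (pre_par && post_par) {
      o$orf_class <- "1C3'"; o$novel_n <- FALSE; o$novel_c <- FALSE
      o$qualifier <- "frame-preserving"
    } else {
      o$orf_class <- "1C3'"; o$novel_n <- TRUE; o$novel_c <- TRUE
      o$qualifier <- "no-parental-frame"
    }
    o
  })
  bind_rows(res)
}

#' Align a circular ORF to its parental protein
#'
#' Converts the ORF's run of parental codons into a 1-based residue interval
#' on the parent protein by coordinate arithmetic (parental codons are exact
#' copies by construction, so no sequence alignment is needed). The stop
#' codon encodes no residue and is excluded from both the interval and the
#' overhang counts.
#'
#' @param orf One ORF row (finite) with finalized novelty.
#' @param projection `cds_projection` of the same circle.
#' @param parent_protein_length Parent protein length in residues.
#' @param L Circle length.
#' @return A one-row tibble: `parental_start`, `parental_end` (1-based
#'   residues, NA when no codon is parental), `n_overhang`, `c_overhang`
#'   (novel codons on each side), `aligned`.
#' @export
map_orf_to_protein <- function(orf, projection, parent_protein_length,
                               L = length(projection$cds_pos)) {
  o <- if (is.data.frame(orf)) as.list(orf[1L, ]) else orf
  if (isTRUE(o$endless)) abort("endless ORFs have no finite protein alignment")
  cds_pos <- projection$cds_pos
  u <- seq.int(o$start, o$start + o$length_nt - 3L, by = 3L)
  u <- u[-length(u)]                      # drop the stop codon
  if (length(u) == 0L) {
    return(tibble(parental_start = NA_integer_, parental_end = NA_integer_,
                  n_overhang = 0L, c_overhang = 0L, aligned = FALSE))
  }
  par <- map_lgl(u, ~codon_parental(.x %% L, cds_pos, L))
  if (!projection$present || !any(par)) {
    nc <- length(u)
    return(tibble(parental_start = NA_integer_, parental_end = NA_integer_,
                  n_overhang = nc, c_overhang = nc, aligned = FALSE))
  }
  # longest run of parental codons
  r <- rle(par)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  best <- runs[which.max(r$lengths[runs])]
  i1 <- starts[best]; i2 <- ends[best]
  res1 <- cds_pos[(u[i1] %% L) + 1L] %/% 3L + 1L
  res2 <- cds_pos[(u[i2] %% L) + 1L] %/% 3L + 1L
  tibble(parental_start = res1,
         parental_end = min(res2, parent_protein_length),
         n_overhang = i1 - 1L,
         c_overhang = length(u) - i2,
         aligned = TRUE)
}
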