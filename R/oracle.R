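#' Brute-force reference ORF scan (independent oracle)
#'
#' A deliberately naive reference implementation used to validate
#' [enumerate_orfs()] and to compute fixture ground truth: the circle is
#' unrolled into an explicit character vector of four copies plus two bases
#' and walked codon by codon in each frame, counting junction passages one
#' by one (every time the reading steps over a multiple of L) instead of
#' using the closed form. Endlessness is declared when L codons pass without
#' a stop. Kept intentionally independent of the engine's vectorized
#' implementation.
#'
#' @param seq Nucleotide string (the circle).
#' @param min_peptide Minimum peptide length in aa for finite ORFs.
#' @return A tibble: `start`, `length_nt`, `crossings` (counted, `Inf` for
#'   endless), `endless`, `peptide`.
#' @export
orf_scan_reference <- function(seq, min_peptide = 1L) {
  seq <- str_to_upper(seq)
  L <- nchar(seq)
  if (L < 3L) abort("circle length must be >= 3 nt")
  unrolled <- paste0(strrep(seq, 4L), substr(seq, 1L, 2L))
  W <- nchar(unrolled)
  found <- list()
  for (f in 0:2) {
    upos <- seq.int(f, W - 3L, by = 3L)  # 0-based first bases of frame codons
    cods <- substring(unrolled, upos + 1L, upos + 3L)
    i <- 1L
    open_start <- NA_integer_
    ncod <- 0L
    while (i <= length(cods)) {
      cod <- cods[i]
      if (is.na(open_start)) {
        if (cod == "ATG") {
          open_start <- upos[i]
          ncod <- 1L
        }
      } else {
        ncod <- ncod + 1L
        if (cod %in% c("TAA", "TAG", "TGA")) {
          len <- ncod * 3L
          s <- open_start %% L
          # count the junction passages over the span [s, s + len - 1]:
          # one passage per multiple of L the reading steps over
          span <- s:(s + len - 1L)
          passages <- sum(span > 0L & span %% L == 0L)
          pep <- codon_table_translate(
            substring(unrolled, s + 1L + 3L * (0:(ncod - 2L)),
                      s + 3L + 3L * (0:(ncod - 2L))))
          found[[length(found) + 1L]] <-
            list(start = s, length_nt = len, crossings = passages,
                 endless = FALSE, peptide = pep)
          open_start <- NA_integer_
          ncod <- 0L
        } else if (ncod >= L) {
          s <- open_start %% L
          per <- if (L %% 3L == 0L) L %/% 3L else L
          pep <- codon_table_translate(
            substring(unrolled, s + 1L + 3L * (0:(per - 1L)),
                      s + 3L + 3L * (0:(per - 1L))))
          # reduce to the minimal repeating unit by direct search
          best <- pep
          for (d in seq_len(nchar(pep))) {
            if (nchar(pep) %% d == 0L) {
              unit <- substr(pep, 1L, d)
              if (paste(rep(unit, nchar(pep) %/% d), collapse = "") == pep) {
                best <- unit
                break
              }
            }
          }
          found[[length(found) + 1L]] <-
            list(start = s, length_nt = 0L, crossings = Inf,
                 endless = TRUE, peptide = best)
          break
        }
      }
      i <- i + 1L
    }
  }
  if (length(found) == 0L) {
    return(tibble(start = integer(), length_nt = integer(),
                  crossings = double(), endless = logical(),
                  peptide = character()))
  }
  out <- bind_rows(map(found, as_tibble))
  out <- out[!duplicated(out[, c("start", "length_nt", "endless")]), ]
  out <- out[out$endless | nchar(out$peptide) >= min_peptide, ]
  out[order(out$start, out$length_nt), ]
}

# internal: direct standard-genetic-code lookup (route independent of
# Biostrings::translate, which the engine uses)
codon_table_translate <- function(codons) {
  aa <- Biostrings::GENETIC_CODE[codons]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}
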