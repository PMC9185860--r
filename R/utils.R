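#' @importFrom rlang %||% abort warn .data
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate filter select arrange group_by ungroup summarise
#'   bind_rows distinct left_join n row_number across all_of desc pull rename
#' @importFrom purrr map map2 map_chr map_int map_lgl pmap imap keep
#' @importFrom stringr str_detect str_match str_split str_sub str_to_upper
NULL

# internal: reverse complement of a plain character DNA string
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# internal: translate a DNA string (standard code); trailing stop stripped
translate_dna <- function(x) {
  if (nchar(x) < 3) return("")
  x <- substr(x, 1L, nchar(x) - nchar(x) %% 3L)
  aa <- if (grepl("N", x, fixed = TRUE)) {
    as.character(Biostrings::translate(Biostrings::DNAStringSet(x),
                                       no.init.codon = TRUE,
                                       if.fuzzy.codon = "solve"))
  } else {
    as.character(Biostrings::translate(Biostrings::DNAStringSet(x),
                                       no.init.codon = TRUE))
  }
  sub("\\*$", "", aa)
}

#' Canonical junction key
#'
#' Backsplice junctions are identified everywhere in the package by the exact
#' key `contig:start-end:strand` (0-based half-open coordinates). Two records
#' are the same junction if and only if their keys are equal.
#'
#' @param contig,start,end,strand Vectors of equal length (or a data frame
#'   given as `contig` with those columns).
#' @return Character vector of keys.
#' @export
junction_key <- function(contig, start = NULL, end = NULL, strand = NULL) {
  if (is.data.frame(contig)) {
    df <- contig
    return(junction_key(df$contig, df$start, df$end, df$strand))
  }
  paste0(contig, ":", start, "-", end, ":", strand)
}

# internal: stopifnot-with-message helpers
assert_cols <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf("%s: missing required column(s): %s",
                  what, paste(missing, collapse = ", ")))
  }
  invisible(df)
}

assert_strand <- function(strand) {
  bad <- !strand %in% c("+", "-")
  if (any(bad)) {
    abort(sprintf("strand required: must be '+' or '-' (got: %s)",
                  paste(unique(strand[bad]), collapse = ", ")))
  }
  invisible(strand)
}
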