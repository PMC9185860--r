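#' Default track colors
#'
#' Named hex colors for the visual classes: reference transcript tracks,
#' circRNAs with at least one predicted ORF, circRNAs without, protein
#' domains, and ORF segments aligned to the parental protein.
#' @export
TRACK_COLORS <- c(reference = "#CC0000", orf_positive = "#2E8B57",
                  orf_negative = "#1F6FB2", domain = "#E8A33D",
                  orf_segment = "#555FA8")

#' Read a protein domain feature table
#'
#' UniProt-flat-derived dialect: tab-separated with columns `protein_id`,
#' `feature_type`, `description`, `begin`, `end` (1-based inclusive
#' residues).
#'
#' @param path TSV path.
#' @return A tibble of domain features.
#' @export
read_domains <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                        progress = FALSE)
  assert_cols(df, c("protein_id", "feature_type", "description",
                    "begin", "end"), "domain table")
  out <- df |>
    mutate(begin = as.integer(.data$begin), end = as.integer(.data$end))
  if (any(is.na(out$begin) | is.na(out$end) | out$begin < 1L |
            out$begin > out$end)) {
    abort("domain table: begin/end must satisfy 1 <= begin <= end")
  }
  out
}

# internal: fixed-format coordinate for byte-stable SVG output
fmt <- function(x) sprintf("%.2f", x)

# internal: append an SVG element with attributes
svg_el <- function(parent, name, ...) {
  node <- xml2::xml_add_child(parent, name)
  attrs <- list(...)
  for (a in names(attrs)) xml2::xml_set_attr(node, a, as.character(attrs[[a]]))
  node
}

# internal: new SVG root with fixed size
svg_root <- function(width, height) {
  doc <- xml2::xml_new_root(
    "svg", xmlns = "http://www.w3.org/2000/svg",
    width = as.character(width), height = as.character(height),
    viewBox = sprintf("0 0 %d %d", width, height),
    "font-family" = "monospace", "font-size" = "10")
  doc
}

#' Transcript-track plot (SVG)
#'
#' One red row per distinct representative transcript (exon boxes joined by
#' an intron line at half exon height, genomic x-axis, to scale); below each
#' transcript, one row per circRNA spanning its backsplice exon pair —
#' green when any ORF was predicted for it, blue otherwise. Row order is
#' deterministic (transcript_id, then junction key), and identical inputs
#' produce byte-identical files. Every displayed entity is a `<g>` element
#' whose `class` attribute is its color class (`reference`,
#' `orf_positive`, `orf_negative`), so the file is structurally testable.
#'
#' @param assignments Assigned junctions of a single gene, with a `has_orf`
#'   logical column.
#' @param transcripts Transcript model table.
#' @param path Output SVG path.
#' @param colors Named color overrides (see [TRACK_COLORS]).
#' @return `path`, invisibly.
#' @export
plot_transcripts <- function(assignments, transcripts, path,
                             colors = TRACK_COLORS) {
  if (nrow(assignments) == 0L) abort("no assignments to plot")
  if (length(unique(assignments$gene_symbol)) != 1L) {
    abort("all assignments must belong to one gene")
  }
  colors <- utils::modifyList(as.list(TRACK_COLORS), as.list(colors))
  tx_ids <- sort(unique(assignments$transcript_id))
  trs <- transcripts[match(tx_ids, transcripts$transcript_id), ]
  if (anyNA(trs$transcript_id)) abort("assignment references unknown transcript")
  xmin <- min(map_int(trs$exons, ~min(.x$start)), assignments$start)
  xmax <- max(map_int(trs$exons, ~max(.x$end)), assignments$end)
  pad <- max(1L, round((xmax - xmin) * 0.02))
  xmin <- xmin - pad; xmax <- xmax + pad
  width <- 900L
  margin <- 120L
  sx <- function(g) margin + (g - xmin) / (xmax - xmin) * (width - margin - 20L)
  rowh <- 14L; gap <- 6L
  n_rows <- length(tx_ids) + nrow(assignments)
  height <- 20L + n_rows * (rowh + gap) + 20L
  doc <- svg_root(width, height)
  y <- 20L
  for (ti in seq_along(tx_ids)) {
    tr <- as_transcript_row(trs[ti, ])
    g <- svg_el(doc, "g", class = "reference", fill = colors$reference,
                stroke = colors$reference)
    # intron line through the transcript span at half exon height
    svg_el(g, "line",
           x1 = fmt(sx(min(tr$exons$start))), x2 = fmt(sx(max(tr$exons$end))),
           y1 = fmt(y + rowh / 2), y2 = fmt(y + rowh / 2),
           "stroke-width" = "1")
    for (e in seq_len(nrow(tr$exons))) {
      svg_el(g, "rect",
             x = fmt(sx(tr$exons$start[e])), y = fmt(y),
             width = fmt(sx(tr$exons$end[e]) - sx(tr$exons$start[e])),
             height = fmt(rowh), stroke = "none")
    }
    svg_el(g, "text", x = "5", y = fmt(y + rowh - 3L),
           fill = "#000000", stroke = "none")
    xml2::xml_set_text(xml2::xml_child(g, xml2::xml_length(g)),
                       tr$transcript_id)
    y <- y + rowh + gap
    circles <- assignments |>
      filter(.data$transcript_id == tx_ids[ti]) |>
      arrange(.data$contig, .data$start, .data$end, .data$strand)
    for (ci in seq_len(nrow(circles))) {
      cls <- if (isTRUE(circles$has_orf[ci])) "orf_positive" else "orf_negative"
      gc <- svg_el(doc, "g", class = cls, fill = colors[[cls]])
      svg_el(gc, "rect",
             x = fmt(sx(circles$start[ci])), y = fmt(y + 3L),
             width = fmt(sx(circles$end[ci]) - sx(circles$start[ci])),
             height = fmt(rowh - 6L), stroke = "none")
      svg_el(gc, "text", x = "5", y = fmt(y + rowh - 3L),
             fill = "#000000", stroke = "none")
      xml2::xml_set_text(xml2::xml_child(gc, xml2::xml_length(gc)),
                         circles$name[ci])
      y <- y + rowh + gap
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Protein-domain alignment plot (SVG)
#'
#' Top row: the full-length parental protein as a bar with its annotated
#' domain boxes and labels. Below: one bar per circRNA-derived ORF at its
#' parental residue interval, with novel N/C overhangs drawn as hatched
#' extensions; bars are color-coded by source transcript in order of first
#' appearance. The x-axis is in residues. Entities are `<g>` elements
#' classed `reference`, `domain` and `orf_segment`.
#'
#' @param protein_length Parent protein length in residues.
#' @param domains Tibble of domain features for this protein (may be NULL).
#' @param alignments Tibble from [map_orf_to_protein()] rows, with optional
#'   `label` and `source_tx` columns.
#' @param path Output SVG path.
#' @param colors Named color overrides.
#' @return `path`, invisibly.
#' @export
plot_protein <- function(protein_length, domains, alignments, path,
                         colors = TRACK_COLORS) {
  colors <- utils::modifyList(as.list(TRACK_COLORS), as.list(colors))
  domains <- domains %||% tibble(protein_id = character(),
                                 feature_type = character(),
                                 description = character(),
                                 begin = integer(), end = integer())
  if (any(domains$end > protein_length)) {
    abort("domain outside protein length")
  }
  width <- 900L; margin <- 40L
  # residue r occupies [r-1, r) on the axis
  sx <- function(r) margin + r / protein_length * (width - margin - 20L)
  rowh <- 16L; gap <- 8L
  n_rows <- 1L + nrow(alignments)
  height <- 30L + n_rows * (rowh + gap) + 20L
  doc <- svg_root(width, height)
  defs <- svg_el(doc, "defs")
  pat <- svg_el(defs, "pattern", id = "hatch", width = "4", height = "4",
                patternUnits = "userSpaceOnUse",
                patternTransform = "rotate(45)")
  svg_el(pat, "rect", x = "0", y = "0", width = "2", height = "4",
         fill = "#888888")
  y <- 30L
  gp <- svg_el(doc, "g", class = "reference", fill = colors$reference)
  svg_el(gp, "rect", x = fmt(sx(0)), y = fmt(y),
         width = fmt(sx(protein_length) - sx(0)), height = fmt(rowh),
         stroke = "none")
  svg_el(gp, "text", x = fmt(sx(0)), y = fmt(y - 4L), fill = "#000000")
  xml2::xml_set_text(xml2::xml_child(gp, xml2::xml_length(gp)),
                     sprintf("protein (%d aa)", protein_length))
  for (d in seq_len(nrow(domains))) {
    gd <- svg_el(doc, "g", class = "domain", fill = colors$domain)
    svg_el(gd, "rect", x = fmt(sx(domains$begin[d] - 1L)), y = fmt(y - 2L),
           width = fmt(sx(domains$end[d]) - sx(domains$begin[d] - 1L)),
           height = fmt(rowh + 4L), stroke = "#000000",
           "stroke-width" = "0.5")
    svg_el(gd, "text", x = fmt(sx(domains$begin[d] - 1L)),
           y = fmt(y + rowh + 12L), fill = "#000000")
    xml2::xml_set_text(xml2::xml_child(gd, xml2::xml_length(gd)),
                       domains$description[d])
  }
  y <- y + rowh + gap + 10L
  src <- unique(alignments$source_tx %||% rep("orf", nrow(alignments)))
  palette <- c("#555FA8", "#A85555", "#55A87A", "#A8A155", "#7A55A8")
  for (a in seq_len(nrow(alignments))) {
    al <- alignments[a, ]
    col_i <- match(al$source_tx %||% "orf", src)
    ga <- svg_el(doc, "g", class = "orf_segment",
                 fill = palette[(col_i - 1L) %% length(palette) + 1L])
    aa_w <- (width - margin - 20L) / protein_length   # axis units per residue
    x1 <- sx(al$parental_start - 1L)
    x2 <- sx(al$parental_end)
    svg_el(ga, "rect", x = fmt(x1), y = fmt(y),
           width = fmt(x2 - x1), height = fmt(rowh - 4L), stroke = "none")
    if (al$n_overhang > 0L) {
      svg_el(ga, "rect", x = fmt(x1 - al$n_overhang * aa_w), y = fmt(y),
             width = fmt(al$n_overhang * aa_w), height = fmt(rowh - 4L),
             fill = "url(#hatch)", class = "overhang", stroke = "none")
    }
    if (al$c_overhang > 0L) {
      svg_el(ga, "rect", x = fmt(x2), y = fmt(y),
             width = fmt(al$c_overhang * aa_w), height = fmt(rowh - 4L),
             fill = "url(#hatch)", class = "overhang", stroke = "none")
    }
    if (!is.null(al$label)) {
      svg_el(ga, "text", x = "5", y = fmt(y + rowh - 6L), fill = "#000000")
      xml2::xml_set_text(xml2::xml_child(ga, xml2::xml_length(ga)), al$label)
    }
    y <- y + rowh + gap
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Count SVG entities per color class
#'
#' Structural helper for testing and reporting: counts the `<g>` elements of
#' each color class in an SVG written by [plot_transcripts()] or
#' [plot_protein()].
#'
#' @param path SVG path.
#' @return Named integer vector over the classes present.
#' @export
svg_class_counts <- function(path) {
  doc <- xml2::read_xml(path)
  gs <- xml2::xml_find_all(doc, ".//*[local-name()='g'][@class]")
  cls <- xml2::xml_attr(gs, "class")
  cls <- cls[cls %in% names(TRACK_COLORS)]
  tab <- table(cls)
  stats::setNames(as.integer(tab), names(tab))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' ORF class composition plot
#'
#' Bar chart of ORF records per crossing class from an [annotate_run()]
#' result or an ORF table.
#'
#' @param object A `circann_result` or ORF tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.circann_result <- function(object, ...) {
  orfs <- object$orfs
  ggplot2::ggplot(orfs, ggplot2::aes(x = .data$class, fill = .data$class)) +
    ggplot2::geom_bar() +
    ggplot2::scale_fill_manual(values = stats::setNames(
      rep(unname(TRACK_COLORS["orf_segment"]), 5L),
      c("0C", "1C5'", "1C3'", "2C", "edlsC")), guide = "none") +
    ggplot2::labs(x = "junction-crossing class", y = "ORF records") +
    ggplot2::theme_minimal()
}

#' Localization presence heatmap
#'
#' Tile plot of the per-junction compartment presence matrix.
#'
#' @param localization Tibble from [localization_profiles()].
#' @return A ggplot object.
#' @export
plot_localization <- function(localization) {
  long <- localization |>
    mutate(key = junction_key(.data$contig, .data$start, .data$end,
                              .data$strand)) |>
    tidyr::pivot_longer(all_of(COMPARTMENTS), names_to = "compartment",
                        values_to = "present")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$compartment, y = .data$key,
                                     fill = .data$present)) +
    ggplot2::geom_tile(color = "white") +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#2E8B57",
                                          `FALSE` = "#DDDDDD")) +
    ggplot2::labs(x = NULL, y = NULL, fill = "present") +
    ggplot2::theme_minimal()
}
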