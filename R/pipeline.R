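#' Load and validate a pipeline configuration
#'
#' A configuration is a flat YAML file (or equivalent named list) with paths
#' and parameters. Relative paths are resolved against the config file's
#' directory. Recognised keys:
#'
#' * `genome`, `gtf` — required input paths;
#' * `junctions` — list of entries `path`, `dialect` (`ciri` or `bed`),
#'   `label`, and optional `compartment` (one of [COMPARTMENTS]);
#' * `archives` — list of entries `path`, `dialect`
#'   (`circbase`/`circrnadb`);
#' * `domains` — optional protein-domain feature TSV;
#' * `out_dir` — default output directory;
#' * `tolerance` (nt, default 2), `min_reads` (default 2), `min_peptide`
#'   (aa, default 20).
#'
#' @param config Path to a YAML file or a named list.
#' @return A validated config list with absolute paths.
#' @export
load_config <- function(config) {
  base <- "."
  if (is.character(config)) {
    if (!file.exists(config)) abort(sprintf("config not found: %s", config))
    base <- dirname(normalizePath(config))
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) abort("config must be a path or a named list")
  resolve <- function(p) {
    if (is.null(p)) return(NULL)
    if (!grepl("^(/|[A-Za-z]:)", p)) file.path(base, p) else p
  }
  cfg <- config
  cfg$genome <- resolve(cfg$genome)
  cfg$gtf <- resolve(cfg$gtf)
  cfg$domains <- resolve(cfg$domains)
  cfg$junctions <- map(cfg$junctions %||% list(), function(j) {
    j$path <- resolve(j$path)
    j
  })
  cfg$archives <- map(cfg$archives %||% list(), function(a) {
    a$path <- resolve(a$path)
    a
  })
  cfg$out_dir <- resolve(cfg$out_dir %||% "out")
  cfg$tolerance <- as.integer(cfg$tolerance %||% 2L)
  cfg$min_reads <- as.integer(cfg$min_reads %||% 2L)
  cfg$min_peptide <- as.integer(cfg$min_peptide %||% 20L)
  if (is.null(cfg$genome)) abort("config error: 'genome' is required")
  if (is.null(cfg$gtf)) abort("config error: 'gtf' is required")
  for (p in c(cfg$genome, cfg$gtf,
              map_chr(cfg$junctions, "path"),
              map_chr(cfg$archives, "path"))) {
    if (!file.exists(p)) abort(sprintf("config error: input does not exist: %s", p))
  }
  cps <- unlist(map(cfg$junctions, "compartment"))
  bad <- setdiff(cps, COMPARTMENTS)
  if (length(bad) > 0L) {
    abort(sprintf("config error: unknown compartment(s): %s",
                  paste(bad, collapse = ", ")))
  }
  cfg
}

# internal: parse all junction inputs of a config
parse_inputs <- function(cfg) {
  calls <- list()
  parsed <- list()
  for (j in cfg$junctions) {
    label <- j$label %||% j$compartment %||% basename(j$path)
    jt <- switch(j$dialect %||% "ciri",
      ciri = parse_ciri(j$path, label, cfg$min_reads),
      bed = parse_bed(j$path, label),
      abort(sprintf("unknown junction dialect '%s'", j$dialect))
    )
    parsed[[length(parsed) + 1L]] <- jt
    if (!is.null(j$compartment)) {
      calls[[j$compartment]] <- if (is.null(calls[[j$compartment]])) {
        jt
      } else {
        merge_junctions(calls[[j$compartment]], jt)
      }
    }
  }
  archives <- list()
  for (a in cfg$archives) {
    archives[[a$dialect]] <- suppressWarnings(
      parse_archive(a$path, dialect = a$dialect, column_map = a$column_map))
  }
  list(calls = calls, parsed = parsed, archives = archives)
}

#' Run the full annotation pipeline
#'
#' Chains the toolkit end to end: parse junction calls and archive dumps,
#' merge on the exact junction key, build subcellular localization profiles,
#' assign representative transcripts and exon pairs, assemble each circle
#' and enumerate/classify its ORFs, and emit the annotation table, ORF table
#' and localization matrix as TSV (plus normalized junctions as BED6 and ORF
#' peptides as FASTA). Stage counts are logged via `message()`.
#'
#' The annotation table has the fixed column order: `name`, `contig`,
#' `start`, `end`, `strand`, `gene_symbol`, `ref_transcript`, `exon_M`,
#' `exon_N`, `cytoplasm`, `nucleoplasm`, `chromatin`, `polysome`, `has_orf`,
#' then one accession column per archive dialect.
#'
#' @param config Config path or list (see [load_config()]).
#' @param out_dir Output directory; overrides the config's `out_dir`.
#'   `NULL` with `write = FALSE` runs fully in memory.
#' @param write Write output files (default TRUE).
#' @return Invisibly, a `circann_result` list: `annotation`, `orfs`,
#'   `localization`, `assignments`, `junctions` (master set),
#'   `transcripts`, `config`.
#' @export
annotate_run <- function(config, out_dir = NULL, write = TRUE) {
  cfg <- load_config(config)
  out_dir <- out_dir %||% cfg$out_dir
  genome <- read_genome(cfg$genome)
  transcripts <- read_gtf(cfg$gtf)
  inp <- parse_inputs(cfg)
  master <- merge_junctions(bind_rows(c(inp$parsed, unname(inp$archives))))
  message(sprintf("junctions: %d distinct after merging %d input table(s)",
                  nrow(master), length(inp$parsed) + length(inp$archives)))
  loc <- localization_profiles(inp$calls)
  assignments <- rank_and_assign(master, transcripts,
                                 tolerance = cfg$tolerance)
  message(sprintf("assigned: %d / %d junctions (tolerance %d nt)",
                  sum(assignments$assigned), nrow(assignments),
                  cfg$tolerance))

  keys <- junction_key(assignments)
  orf_rows <- list()
  has_orf <- rep(NA, nrow(assignments))
  for (i in seq_len(nrow(assignments))) {
    if (!assignments$assigned[i]) next
    circle <- build_circle(assignments[i, ], transcripts, genome)
    orfs <- enumerate_orfs(circle, min_peptide = cfg$min_peptide)
    proj <- project_cds(assignments[i, ], circle, transcripts)
    orfs <- classify_novelty(orfs, proj, L = circle$L)
    has_orf[i] <- nrow(orfs) > 0L
    if (nrow(orfs) > 0L) {
      orfs <- orfs |>
        mutate(name = assignments$name[i], key = keys[i],
               orf_index = row_number()) |>
        select("name", "key", "orf_index", "start", "length_nt",
               "crossings", class = "orf_class", "novel_n", "novel_c",
               "qualifier", "peptide")
      orf_rows[[length(orf_rows) + 1L]] <- orfs
    }
  }
  orf_table <- if (length(orf_rows) > 0L) bind_rows(orf_rows) else {
    tibble(name = character(), key = character(), orf_index = integer(),
           start = integer(), length_nt = integer(), crossings = double(),
           class = character(), novel_n = logical(), novel_c = logical(),
           qualifier = character(), peptide = character())
  }
  cls_counts <- table(orf_table$class)
  message(sprintf("ORFs: %d total%s", nrow(orf_table),
                  if (length(cls_counts) > 0L) {
                    paste0(" (", paste(sprintf("%s: %d", names(cls_counts),
                                               as.integer(cls_counts)),
                                       collapse = ", "), ")")
                  } else ""))

  loc_keys <- junction_key(loc)
  loc_at <- match(keys, loc_keys)
  annotation <- tibble(
    name = assignments$name,
    contig = assignments$contig, start = assignments$start,
    end = assignments$end, strand = assignments$strand,
    gene_symbol = assignments$gene_symbol,
    ref_transcript = assignments$transcript_id,
    exon_M = assignments$exon_m, exon_N = assignments$exon_n
  )
  for (cp in COMPARTMENTS) {
    annotation[[cp]] <- ifelse(is.na(loc_at), FALSE, loc[[cp]][loc_at])
  }
  annotation$has_orf <- has_orf
  for (dialect in names(inp$archives)) {
    annotation[[dialect]] <- map_chr(master$accessions, function(acc) {
      as.character(acc[[dialect]] %||% "")
    })
  }

  result <- structure(list(
    annotation = annotation, orfs = orf_table, localization = loc,
    assignments = assignments, junctions = master,
    transcripts = transcripts, config = cfg
  ), class = "circann_result")

  if (isTRUE(write)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_tsv(annotation, file.path(out_dir, "annotation.tsv"),
                     escape = "none")
    readr::write_tsv(orf_table, file.path(out_dir, "orfs.tsv"),
                     escape = "none")
    readr::write_tsv(loc, file.path(out_dir, "localization.tsv"),
                     escape = "none")
    write_bed(master, file.path(out_dir, "junctions.bed"))
    write_peptides(orf_table, file.path(out_dir, "peptides.fa"))
    message(sprintf("wrote outputs to %s", out_dir))
  }
  invisible(result)
}

#' @export
print.circann_result <- function(x, ...) {
  cat(sprintf(paste0("<circann_result> %d junction(s), %d assigned, ",
                     "%d ORF record(s)\n"),
              nrow(x$annotation), sum(x$assignments$assigned),
              nrow(x$orfs)))
  invisible(x)
}

# internal: ORF peptides as FASTA, headers "name|orf_index|class"
write_peptides <- function(orf_table, path) {
  finite <- orf_table
  lines <- character(0)
  for (i in seq_len(nrow(finite))) {
    lines <- c(lines,
               sprintf(">%s|%d|%s", finite$name[i], finite$orf_index[i],
                       finite$class[i]),
               finite$peptide[i])
  }
  writeLines(lines, path)
  invisible(path)
}

#' Venn reconciliation report
#'
#' Builds the labelled junction sets (the union of de novo compartment calls
#' as `denovo`, plus each archive dialect) or the per-compartment sets, and
#' writes the region-count table of their Venn partition.
#'
#' @param config Config path or list.
#' @param groups `"databases"` (de novo vs archives) or `"compartments"`.
#' @param out_dir Output directory; `NULL` to skip writing.
#' @return The Venn partition tibble (see [reconcile()]).
#' @export
venn_run <- function(config, groups = c("databases", "compartments"),
                     out_dir = NULL) {
  groups <- match.arg(groups)
  cfg <- load_config(config)
  inp <- parse_inputs(cfg)
  sets <- if (groups == "databases") {
    c(list(denovo = merge_junctions(bind_rows(inp$parsed))), inp$archives)
  } else {
    inp$calls[order(match(names(inp$calls), COMPARTMENTS))]
  }
  if (length(sets) < 2L) abort("need >=2 labeled sets for a Venn report")
  part <- reconcile(sets)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_tsv(part, file.path(out_dir, sprintf("venn_%s.tsv", groups)),
                     escape = "none")
  }
  part
}

#' Render the plots for one gene
#'
#' Runs the annotation in memory, then renders the transcript-track SVG for
#' the gene's representative transcripts and their circRNAs, and — when the
#' gene's circles carry finite ORFs on a CDS-bearing transcript — the
#' protein-domain alignment SVG per such transcript.
#'
#' @param config Config path or list.
#' @param gene Gene symbol to plot.
#' @param out_dir Output directory for the SVG files.
#' @param result Optional precomputed [annotate_run()] result (avoids
#'   re-running the pipeline).
#' @return Character vector of written SVG paths.
#' @export
plot_run <- function(config, gene, out_dir = NULL, result = NULL) {
  cfg <- load_config(config)
  out_dir <- out_dir %||% cfg$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  res <- result %||% annotate_run(cfg, write = FALSE)
  ann <- res$annotation |> filter(!is.na(.data$gene_symbol))
  if (!gene %in% ann$gene_symbol) {
    abort(sprintf("unknown gene '%s'; available: %s", gene,
                  paste(sort(unique(ann$gene_symbol)), collapse = ", ")))
  }
  sub <- res$assignments |>
    filter(.data$assigned, .data$gene_symbol == gene) |>
    mutate(has_orf = res$annotation$has_orf[match(
      junction_key(.data$contig, .data$start, .data$end, .data$strand),
      junction_key(res$annotation$contig, res$annotation$start,
                   res$annotation$end, res$annotation$strand))])
  paths <- character(0)
  tpath <- file.path(out_dir, sprintf("%s_transcripts.svg", gene))
  plot_transcripts(sub, res$transcripts, tpath)
  paths <- c(paths, tpath)

  domains <- if (!is.null(cfg$domains)) read_domains(cfg$domains) else NULL
  genome <- read_genome(cfg$genome)
  for (tx in sort(unique(sub$transcript_id))) {
    tr <- res$transcripts[res$transcripts$transcript_id == tx, ]
    cds_len <- sum(tr$cds[[1L]]$end - tr$cds[[1L]]$start)
    if (cds_len < 6L) next
    plen <- cds_len %/% 3L - 1L
    keys <- junction_key(sub)
    aligns <- list()
    for (i in which(sub$transcript_id == tx)) {
      circle <- build_circle(sub[i, ], res$transcripts, genome)
      proj <- project_cds(sub[i, ], circle, res$transcripts)
      orfs <- res$orfs |> filter(.data$key == keys[i], !.data$crossings == Inf)
      for (k in seq_len(nrow(orfs))) {
        al <- map_orf_to_protein(
          orfs[k, ] |> rename(orf_class = "class"), proj, plen,
          L = circle$L)
        al$label <- sprintf("%s|%d", orfs$name[k], orfs$orf_index[k])
        al$source_tx <- tx
        aligns[[length(aligns) + 1L]] <- al
      }
    }
    aligns <- bind_rows(aligns)
    if (nrow(aligns) == 0L || !any(aligns$aligned)) next
    dsub <- if (!is.null(domains)) {
      domains |> filter(.data$protein_id == tx)
    } else NULL
    ppath <- file.path(out_dir, sprintf("%s_%s_protein.svg", gene, tx))
    plot_protein(plen, dsub, aligns |> filter(.data$aligned), ppath)
    paths <- c(paths, ppath)
  }
  paths
}
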