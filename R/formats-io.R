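# Readers and writers for the standard formats the pipeline touches.
# Everything is normalized to 0-based half-open coordinates on the way in
# and converted back on the way out.

#' The transposable-element superfamily set
#'
#' RepeatMasker `repClass` labels that count as transposable elements.
#' Trailing `?` markers are stripped before matching, so `LTR?` matches
#' `LTR`. Non-TE repeat classes (Simple_repeat, Low_complexity, tRNA,
#' Satellite, ...) are excluded by [read_repeatmasker()] when
#' `te_only = TRUE`. `RC` (rolling-circle, e.g. Helitron) is kept as a TE
#' class and folded into `DNA` in superfamily summaries.
#'
#' @return Character vector of repClass labels.
#' @export
te_superfamilies <- function() {
  c("LINE", "SINE", "LTR", "DNA", "RC", "Retroposon")
}

strip_class <- function(x) sub("\\?$", "", x)

#' Read a RepeatMasker annotation into a repeat-element tibble
#'
#' Supports the UCSC Genome Browser `rmsk` table dump (tab-separated,
#' header line, 0-based half-open `genoStart`/`genoEnd`) and the native
#' RepeatMasker `.out` report (whitespace columns, 1-based inclusive
#' positions, `C` for the minus strand).
#'
#' @param path File path.
#' @param dialect `"ucsc_table"` or `"rm_out"`.
#' @param te_only Drop elements whose (`?`-stripped) repClass is not in
#'   `te_classes`? Non-TE repeats such as simple repeats and tRNAs are
#'   excluded this way. Default `TRUE`.
#' @param te_classes The repClass set treated as TE; see
#'   [te_superfamilies()].
#' @return A tibble with columns `chrom`, `start`, `end` (0-based
#'   half-open), `strand` (`+`/`-`/`.`), `subfamily`, `family`,
#'   `superfamily` (`?`-stripped repClass), `element_id`
#'   (`subfamily|chrom|start|end`) and `genic_context` (`"unset"` until
#'   [label_genic_context()] is applied).
#' @export
read_repeatmasker <- function(path, dialect = c("ucsc_table", "rm_out"),
                              te_only = TRUE, te_classes = te_superfamilies()) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(paste0("RepeatMasker file not found: ", path))
  tbl <- switch(dialect,
    ucsc_table = parse_rmsk_ucsc(path),
    rm_out = parse_rmsk_out(path)
  )
  tbl <- tbl %>%
    mutate(
      superfamily = strip_class(.data$repClass),
      element_id = paste(.data$subfamily, .data$chrom, .data$start, .data$end,
                         sep = "|"),
      genic_context = "unset"
    )
  if (te_only) tbl <- filter(tbl, .data$superfamily %in% te_classes)
  tbl %>%
    select("chrom", "start", "end", "strand", "subfamily",
           family = "repFamily", "superfamily", "element_id", "genic_context")
}

parse_rmsk_ucsc <- function(path) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  need <- c("genoName", "genoStart", "genoEnd", "strand", "repName",
            "repClass", "repFamily")
  missing <- setdiff(need, names(tbl))
  if (length(missing) > 0) {
    abort(paste0("ucsc_table is missing required columns: ",
                 paste(missing, collapse = ", ")))
  }
  start <- suppressWarnings(as.integer(tbl$genoStart))
  end <- suppressWarnings(as.integer(tbl$genoEnd))
  bad <- which(is.na(start) | is.na(end) | start < 0 | start >= end)
  if (length(bad) > 0) {
    abort(paste0("Malformed ucsc_table row at line ", bad[1] + 1L,
                 " (non-numeric or inverted genoStart/genoEnd)"))
  }
  tibble(
    chrom = tbl$genoName, start = start, end = end,
    strand = ifelse(tbl$strand %in% c("+", "-"), tbl$strand, "."),
    subfamily = tbl$repName, repClass = tbl$repClass, repFamily = tbl$repFamily
  )
}

parse_rmsk_out <- function(path) {
  lines <- readLines(path)
  first_tok <- vapply(lines, function(l) {
    t <- strsplit(trimws(l), "\\s+")[[1]]
    if (length(t) == 0) "" else t[1]
  }, character(1), USE.NAMES = FALSE)
  body <- which(grepl("^[0-9]+$", first_tok))
  out <- purrr::map(body, function(i) {
    tok <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(tok) < 11) {
      abort(paste0("Malformed RepeatMasker .out row at line ", i,
                   " (expected >= 11 fields, got ", length(tok), ")"))
    }
    begin <- suppressWarnings(as.integer(tok[6]))
    end <- suppressWarnings(as.integer(tok[7]))
    if (is.na(begin) || is.na(end) || begin < 1 || begin > end) {
      abort(paste0("Malformed RepeatMasker .out row at line ", i,
                   " (bad begin/end coordinates)"))
    }
    cf <- strsplit(tok[11], "/", fixed = TRUE)[[1]]
    tibble(
      chrom = tok[5],
      start = begin - 1L,     # 1-based inclusive -> 0-based half-open
      end = end,
      strand = if (tok[9] == "C") "-" else if (tok[9] == "+") "+" else ".",
      subfamily = tok[10],
      repClass = cf[1],
      repFamily = if (length(cf) > 1) cf[2] else cf[1]
    )
  })
  bind_rows(out)
}

#' Read a GTF annotation into an exon-level transcript tibble
#'
#' Parses transcript/exon features (via `rtracklayer`), converts the
#' 1-based inclusive GTF coordinates to the internal 0-based half-open
#' convention, and returns one row per exon. Transcript order follows
#' first appearance in the file; exons are sorted by start within each
#' transcript.
#'
#' @param path GTF file path.
#' @param source_kind Value for the `source_kind` column
#'   (`"nonTE_gene"` or `"TE_derived"`); annotations read from a plain
#'   gene GTF default to `"nonTE_gene"`.
#' @return Tibble with columns `transcript_id`, `gene_id`, `chrom`,
#'   `start`, `end`, `strand`, `source_kind`.
#' @export
read_gtf <- function(path, source_kind = "nonTE_gene") {
  if (!file.exists(path)) abort(paste0("GTF not found: ", path))
  gr <- rtracklayer::import(path, format = "gtf")
  df <- as.data.frame(gr, stringsAsFactors = FALSE)
  ex <- df[df$type == "exon", , drop = FALSE]
  if (nrow(ex) > 0 && (!"transcript_id" %in% names(ex) ||
                       anyNA(ex$transcript_id))) {
    abort("GTF exon feature lacks a transcript_id attribute")
  }
  if (nrow(ex) == 0) {
    return(tibble(transcript_id = character(), gene_id = character(),
                  chrom = character(), start = integer(), end = integer(),
                  strand = character(), source_kind = character()))
  }
  if (!"gene_id" %in% names(ex)) ex$gene_id <- ex$transcript_id
  out <- tibble(
    transcript_id = as.character(ex$transcript_id),
    gene_id = as.character(ex$gene_id),
    chrom = as.character(ex$seqnames),
    start = as.integer(ex$start) - 1L,   # GTF 1-based inclusive -> 0-based
    end = as.integer(ex$end),
    strand = chartr("*", ".", as.character(ex$strand)),
    source_kind = source_kind
  )
  out <- out %>%
    mutate(.tx_order = match(.data$transcript_id, unique(.data$transcript_id))) %>%
    arrange(.data$.tx_order, .data$start) %>%
    select(-".tx_order")
  # validate against declared transcript spans when present
  tx <- df[df$type == "transcript", , drop = FALSE]
  if (nrow(tx) > 0) {
    spans <- tibble(transcript_id = as.character(tx$transcript_id),
                    tx_start = as.integer(tx$start) - 1L,
                    tx_end = as.integer(tx$end))
    chk <- out %>%
      group_by(.data$transcript_id) %>%
      summarise(lo = min(.data$start), hi = max(.data$end), .groups = "drop") %>%
      left_join(spans, by = "transcript_id") %>%
      filter(!is.na(.data$tx_start) &
               (.data$lo < .data$tx_start | .data$hi > .data$tx_end))
    if (nrow(chk) > 0) {
      abort(paste0("Exon outside declared transcript span for: ",
                   paste(chk$transcript_id, collapse = ", ")))
    }
  }
  validate_exon_tbl(out)
  out
}

validate_exon_tbl <- function(exons) {
  bad <- exons %>%
    group_by(.data$transcript_id) %>%
    summarise(
      ok = all(diff(.data$start) > 0) && all(head(.data$end, -1) <= tail(.data$start, -1)) &&
        length(unique(.data$chrom)) == 1 && length(unique(.data$strand)) == 1,
      .groups = "drop"
    ) %>%
    filter(!.data$ok)
  if (nrow(bad) > 0) {
    abort(paste0("Overlapping or inconsistent exons in transcript(s): ",
                 paste(bad$transcript_id, collapse = ", ")))
  }
  invisible(exons)
}

#' Collapse an exon tibble to one span row per transcript
#'
#' @param exons Exon-level tibble as returned by [read_gtf()].
#' @return Tibble with one row per transcript: `transcript_id`,
#'   `gene_id`, `chrom`, `start`, `end`, `strand`, `n_exons`,
#'   `mature_length` (sum of exon widths, bp).
#' @export
transcript_spans <- function(exons) {
  if (!"source_kind" %in% names(exons)) exons$source_kind <- NA_character_
  if (nrow(exons) == 0) {
    return(tibble(transcript_id = character(), gene_id = character(),
                  source_kind = character(), chrom = character(),
                  start = integer(), end = integer(), strand = character(),
                  n_exons = integer(), mature_length = integer()))
  }
  exons %>%
    group_by(.data$transcript_id) %>%
    summarise(
      gene_id = first(.data$gene_id),
      source_kind = first(.data$source_kind),
      chrom = first(.data$chrom),
      strand = first(.data$strand),
      n_exons = n(),
      mature_length = sum(.data$end - .data$start),
      start = min(.data$start),
      end = max(.data$end),
      .groups = "drop"
    ) %>%
    select("transcript_id", "gene_id", "source_kind", "chrom", "start",
           "end", "strand", "n_exons", "mature_length") %>%
    arrange(match(.data$transcript_id, unique(exons$transcript_id)))
}

#' Write an exon-level transcript tibble as GTF
#'
#' Emits one `transcript` line plus its `exon` lines per transcript with
#' 1-based inclusive coordinates. `read_gtf(write_gtf(x))` reproduces `x`
#' (round trip). Extra per-transcript attributes can be attached via
#' `attributes_tbl`.
#'
#' @param exons Exon tibble (see [read_gtf()] for the schema).
#' @param path Output path.
#' @param source Value of the GTF source column.
#' @param attributes_tbl Optional tibble keyed by `transcript_id` whose
#'   remaining columns become transcript-line attributes.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(exons, path, source = "telokit", attributes_tbl = NULL) {
  validate_exon_tbl(exons)
  spans <- select(transcript_spans(exons), -"n_exons", -"mature_length")
  if (!is.null(attributes_tbl)) {
    spans <- left_join(spans, attributes_tbl, by = "transcript_id")
  }
  fmt_attr <- function(keys, vals) {
    keep <- !is.na(vals)
    paste(paste0(keys[keep], ' "', vals[keep], '";'), collapse = " ")
  }
  extra_cols <- if (is.null(attributes_tbl)) character() else
    setdiff(names(attributes_tbl), "transcript_id")
  tx_lines <- vapply(seq_len(nrow(spans)), function(i) {
    r <- spans[i, ]
    keys <- c("gene_id", "transcript_id", extra_cols)
    vals <- c(r$gene_id, r$transcript_id,
              vapply(extra_cols, function(k) as.character(r[[k]]), character(1)))
    paste(r$chrom, source, "transcript", r$start + 1L, r$end, ".",
          chartr(".", ".", r$strand), ".", fmt_attr(keys, vals), sep = "\t")
  }, character(1))
  ex_lines <- vapply(seq_len(nrow(exons)), function(i) {
    r <- exons[i, ]
    paste(r$chrom, source, "exon", r$start + 1L, r$end, ".", r$strand, ".",
          fmt_attr(c("gene_id", "transcript_id"),
                   c(r$gene_id, r$transcript_id)), sep = "\t")
  }, character(1))
  # interleave: transcript line, then its exons, preserving input order
  ord <- unique(exons$transcript_id)
  lines <- unlist(purrr::map(ord, function(id) {
    c(tx_lines[match(id, spans$transcript_id)], ex_lines[exons$transcript_id == id])
  }))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c("##gff-version 2", lines), con, sep = "\n")
  invisible(path)
}

#' Read a genome FASTA
#'
#' Sequences are uppercased; names are truncated at the first whitespace.
#'
#' @param path FASTA file path.
#' @return A [Biostrings::DNAStringSet].
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort(paste0("FASTA not found: ", path))
  x <- Biostrings::readDNAStringSet(path)
  names(x) <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(names(x)) > 0) {
    abort(paste0("Duplicate sequence names in FASTA: ",
                 paste(unique(names(x)[duplicated(names(x))]), collapse = ", ")))
  }
  Biostrings::DNAStringSet(toupper(as.character(x)))
}

#' Chromosome-size table of a genome
#'
#' @param genome A [Biostrings::DNAStringSet] (e.g. from [read_fasta()]).
#' @return Named integer vector, chromosome name to length (bp).
#' @export
chrom_sizes <- function(genome) {
  setNames(Biostrings::width(genome), names(genome))
}
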