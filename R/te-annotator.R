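# From an assembler's GTF to the TE-derived transcript annotation:
# per-transcript TE composition, subfamily-sorted display names,
# superfamily assignment, and the annotation-level summary.

superfamily_tie_order <- c("LINE", "SINE", "LTR", "DNA", "Retroposon")

#' Build the assembly guide annotation
#'
#' The guide for TE transcriptome assembly is the nonTE gene annotation
#' plus one single-exon transcript per repeat element (its `element_id`
#' serving as both gene and transcript id).
#'
#' @param gene_exons Exon tibble of the nonTE gene annotation.
#' @param repeats TE-only repeat tibble.
#' @param sizes Optional chromosome-size vector; when given, repeats on
#'   unknown chromosomes or beyond chromosome ends are an error.
#' @return Exon tibble of the combined guide annotation.
#' @export
build_guide_annotation <- function(gene_exons, repeats, sizes = NULL) {
  if (!is.null(sizes) && nrow(repeats) > 0) {
    unknown <- setdiff(unique(repeats$chrom), names(sizes))
    if (length(unknown) > 0) {
      abort(paste0("Repeat on chromosome absent from size table: ",
                   paste(unknown, collapse = ", ")))
    }
    if (any(repeats$end > sizes[repeats$chrom])) {
      abort("Repeat interval exceeds chromosome length")
    }
  }
  rep_exons <- tibble(
    transcript_id = repeats$element_id,
    gene_id = repeats$element_id,
    chrom = repeats$chrom,
    start = repeats$start,
    end = repeats$end,
    strand = repeats$strand,
    source_kind = "TE_derived"
  )
  bind_rows(
    mutate(gene_exons, source_kind = "nonTE_gene"),
    rep_exons
  )
}

#' Command line for the external transcript assembler
#'
#' The transcriptome assembly stage is delegated to StringTie2 run in
#' long-read mode against the guide annotation; this helper only formats
#' the documented invocation (it never executes it, and no part of the
#' package requires the assembler to be present).
#'
#' @param bam Merged categories-1..3 alignment file.
#' @param guide_gtf Guide annotation written by [build_guide_annotation()]
#'   + [write_gtf()].
#' @param out_gtf Output GTF path.
#' @param threads Thread count substituted into `-p`.
#' @return The command as a single string.
#' @export
stringtie_command <- function(bam, guide_gtf, out_gtf, threads = 12) {
  paste("stringtie", bam, "-L -G", guide_gtf, "-v -p", threads,
        "-j 1 -g 0 -f 0.01 -l STRG -m 50 -t -c 1.5 -s 1.5 -o", out_gtf)
}

reduced_exon_ranges <- function(exons_tx) {
  IRanges::reduce(IRanges::IRanges(exons_tx$start + 1L, exons_tx$end))
}

#' TE composition of one transcript
#'
#' Exon-wise overlap of a transcript with the repeat annotation:
#' intronic repeat bases do not count, overlapping copies of the same
#' subfamily are merged (union of exonic bases, no double counting), and
#' percentages are relative to the mature transcript length (sum of exon
#' widths). The result is sorted by decreasing percentage, subfamily
#' name breaking ties.
#'
#' @param exons_tx Exon tibble of a single transcript.
#' @param repeats Repeat tibble (TE-only) on the same assembly.
#' @return Tibble `subfamily`, `superfamily`, `overlap_bp`,
#'   `overlap_pct`; zero rows when the transcript overlaps no TE.
#' @export
te_composition <- function(exons_tx, repeats) {
  stopifnot(length(unique(exons_tx$transcript_id)) <= 1)
  empty <- tibble(subfamily = character(), superfamily = character(),
                  overlap_bp = integer(), overlap_pct = double())
  if (nrow(exons_tx) == 0) return(empty)
  chr <- exons_tx$chrom[1]
  ex <- reduced_exon_ranges(exons_tx)
  mature_len <- sum(IRanges::width(ex))
  reps <- repeats[repeats$chrom == chr, , drop = FALSE]
  if (nrow(reps) == 0) return(empty)
  comp <- reps %>%
    group_by(.data$subfamily, .data$superfamily) %>%
    summarise(
      overlap_bp = {
        r <- IRanges::reduce(IRanges::IRanges(.data$start + 1L, .data$end))
        as.integer(sum(IRanges::width(IRanges::intersect(ex, r))))
      },
      .groups = "drop"
    ) %>%
    filter(.data$overlap_bp > 0) %>%
    mutate(overlap_pct = 100 * .data$overlap_bp / mature_len) %>%
    arrange(desc(.data$overlap_pct), .data$subfamily)
  comp
}

#' Display name of a TE-derived transcript
#'
#' Combines the assembler's gene label (e.g. `STRG.1`) with the
#' composition's subfamily names in composition order, joined by `_`.
#' Subfamily names are sanitized by replacing characters outside
#' `[A-Za-z0-9.-]` with `-`.
#'
#' @param gene_label Assembler gene label.
#' @param composition Tibble from [te_composition()]; must be non-empty.
#' @return A single string.
#' @export
name_transcript <- function(gene_label, composition) {
  if (nrow(composition) == 0) {
    abort("Cannot name a transcript with an empty TE composition")
  }
  subs <- gsub("[^A-Za-z0-9.-]", "-", composition$subfamily)
  paste(c(gene_label, subs), collapse = "_")
}

#' Superfamily of a TE-derived transcript
#'
#' The class with the greatest summed overlap; `RC` is reported as
#' `DNA`; ties are broken by the fixed order LINE > SINE > LTR > DNA >
#' Retroposon.
#'
#' @param composition Tibble from [te_composition()] (needs
#'   `superfamily` and `overlap_bp`); must be non-empty.
#' @return One of `"LINE"`, `"SINE"`, `"LTR"`, `"DNA"`, `"Retroposon"`.
#' @export
assign_superfamily <- function(composition) {
  if (nrow(composition) == 0) {
    abort("Cannot assign a superfamily to an empty TE composition")
  }
  tot <- composition %>%
    mutate(class = if_else(.data$superfamily == "RC", "DNA",
                           .data$superfamily)) %>%
    group_by(.data$class) %>%
    summarise(bp = sum(.data$overlap_bp), .groups = "drop") %>%
    mutate(rank = match(.data$class, superfamily_tie_order)) %>%
    arrange(desc(.data$bp), .data$rank)
  tot$class[1]
}

#' Length, span and transcription-end-site metrics
#'
#' @param exons_tx Exon tibble of a single transcript.
#' @return One-row tibble: `mature_length` (sum of exon widths, bp),
#'   `genomic_span` (bp), `tes_coordinate` (1-based genomic position of
#'   the transcription end site: last exon end on `+`, first exon start
#'   on `-`).
#' @export
transcript_metrics <- function(exons_tx) {
  strand <- exons_tx$strand[1]
  tibble(
    mature_length = sum(exons_tx$end - exons_tx$start),
    genomic_span = max(exons_tx$end) - min(exons_tx$start),
    tes_coordinate = if (identical(strand, "-")) min(exons_tx$start) + 1L
                     else max(exons_tx$end)
  )
}

#' Annotate assembled transcripts as TE-derived transcripts
#'
#' Computes each assembled transcript's TE composition; transcripts with
#' no exonic TE overlap are dropped (they are not TE-derived). Survivors
#' get a subfamily-sorted display name, a superfamily, and length
#' metrics.
#'
#' @param assembled_exons Exon tibble of the assembler's GTF
#'   ([read_gtf()]).
#' @param repeats TE-only repeat tibble.
#' @return A `te_annotation` object: tibble with one row per TE-derived
#'   transcript (`transcript_id`, `gene_id`, `chrom`, `strand`,
#'   `mature_length`, `genomic_span`, `tes_coordinate`, `superfamily`,
#'   `display_name`, `te_subfamilies` comma-joined in composition order,
#'   `composition` list-column); the input exon rows of the survivors are
#'   attached as attribute `"exons"`.
#' @export
annotate_te_transcripts <- function(assembled_exons, repeats) {
  ids <- unique(assembled_exons$transcript_id)
  rows <- purrr::map(ids, function(id) {
    ex <- assembled_exons[assembled_exons$transcript_id == id, , drop = FALSE]
    comp <- te_composition(ex, repeats)
    if (nrow(comp) == 0) return(NULL)
    bind_cols(
      tibble(transcript_id = id, gene_id = ex$gene_id[1], chrom = ex$chrom[1],
             strand = ex$strand[1]),
      transcript_metrics(ex),
      tibble(superfamily = assign_superfamily(comp),
             display_name = name_transcript(ex$gene_id[1], comp),
             te_subfamilies = paste(comp$subfamily, collapse = ","),
             composition = list(comp))
    )
  })
  anno <- bind_rows(purrr::compact(rows))
  exons <- assembled_exons %>%
    filter(.data$transcript_id %in% anno$transcript_id) %>%
    mutate(source_kind = "TE_derived")
  structure(anno, exons = exons, class = c("te_annotation", class(anno)))
}

#' Write a TE annotation as GTF
#'
#' Transcript lines carry `te_subfamilies` (comma list in composition
#' order), `te_superfamily` and `mature_length` attributes.
#'
#' @param anno A `te_annotation` from [annotate_te_transcripts()].
#' @param path Output GTF path.
#' @return `path`, invisibly.
#' @export
write_te_gtf <- function(anno, path) {
  attrs <- tibble(
    transcript_id = anno$transcript_id,
    te_subfamilies = anno$te_subfamilies,
    te_superfamily = anno$superfamily,
    mature_length = anno$mature_length
  )
  write_gtf(attr(anno, "exons"), path, source = "telokit",
            attributes_tbl = attrs)
}

#' Summarize a TE-derived transcript annotation
#'
#' Gene-level isoform histogram plus transcript-level superfamily counts
#' and proportions — the annotation-summary view of the catalog.
#'
#' @param anno A `te_annotation` (or any tibble with `gene_id`,
#'   `transcript_id`, `superfamily`).
#' @return A `te_annotation_summary` object: list with `n_genes`,
#'   `n_transcripts`, `isoform_histogram` (tibble `n_isoforms`,
#'   `n_genes`), `superfamilies` (tibble `superfamily`, `n`,
#'   `proportion` over LTR/LINE/SINE/DNA/Retroposon).
#' @export
summarize_annotation <- function(anno) {
  if (nrow(anno) == 0) {
    return(structure(list(
      n_genes = 0L, n_transcripts = 0L,
      isoform_histogram = tibble(n_isoforms = integer(), n_genes = integer()),
      superfamilies = tibble(superfamily = superfamily_tie_order, n = 0L,
                             proportion = 0)),
      class = "te_annotation_summary"))
  }
  per_gene <- anno %>%
    group_by(.data$gene_id) %>%
    summarise(n_isoforms = dplyr::n_distinct(.data$transcript_id),
              .groups = "drop")
  hist <- per_gene %>%
    count(.data$n_isoforms, name = "n_genes") %>%
    arrange(.data$n_isoforms)
  sf <- tibble(superfamily = superfamily_tie_order) %>%
    left_join(count(anno, .data$superfamily), by = "superfamily") %>%
    mutate(n = if_else(is.na(.data$n), 0L, .data$n),
           proportion = .data$n / sum(.data$n))
  structure(list(n_genes = nrow(per_gene), n_transcripts = nrow(anno),
                 isoform_histogram = hist, superfamilies = sf),
            class = "te_annotation_summary")
}

#' @export
print.te_annotation_summary <- function(x, ...) {
  cat("<te_annotation_summary> ", x$n_genes, " genes, ", x$n_transcripts,
      " transcripts\n", sep = "")
  print(x$superfamilies)
  invisible(x)
}

#' @rdname summarize_annotation
#' @param x A `te_annotation_summary`.
#' @param ... Unused.
#' @export
tidy.te_annotation_summary <- function(x, ...) {
  x$superfamilies
}

#' @rdname summarize_annotation
#' @export
glance.te_annotation_summary <- function(x, ...) {
  single <- x$isoform_histogram$n_genes[x$isoform_histogram$n_isoforms == 1]
  tibble(
    n_genes = x$n_genes,
    n_transcripts = x$n_transcripts,
    prop_single_isoform = if (length(single) == 0) 0
                          else single / max(x$n_genes, 1L)
  )
}

#' @rdname summarize_annotation
#' @param object A `te_annotation_summary`.
#' @export
autoplot.te_annotation_summary <- function(object, ...) {
  ggplot2::ggplot(object$superfamilies,
                  ggplot2::aes(x = .data$superfamily, y = .data$n,
                               fill = .data$superfamily)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::labs(x = "TE superfamily", y = "TE-derived transcripts") +
    ggplot2::theme_minimal()
}
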