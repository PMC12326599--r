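# Long-read alignment filtering and four-way classification against the
# TE / exon genome masks.
#
# Categories (decided in precedence order 1 -> 3 -> 2 -> 4):
#   1_intergenic  exon_bp == 0, intergenic-TE overlap > 0, no intragenic TE
#   3_fusion      exon overlap and intergenic-TE overlap (fusion candidate)
#   2_intragenic  exon overlap and intragenic TE covering > 80% (strict)
#                 of the aligned length
#   4_other       every remaining TE-overlapping read

#' Reference-consuming blocks of a CIGAR string
#'
#' `M`, `=`, `X` and `D` advance the reference and are included in blocks
#' (deletions bridge, never split); `N` advances the reference and splits
#' blocks; `I` and `S` consume no reference; `H` only flags the read as
#' hard-clipped. The aligned length is the total width of the returned
#' blocks, so it includes deleted reference bases and excludes skipped
#' introns, insertions and clips.
#'
#' @param pos 0-based leftmost reference position of the alignment.
#' @param cigar CIGAR string.
#' @param chrom Optional chromosome name copied onto the blocks.
#' @return List with `blocks` (tibble `chrom`/`start`/`end`),
#'   `aligned_len`, `has_hard_clip` and `query_len` (bases of read
#'   sequence consumed: M/I/S/=/X).
#' @export
blocks_from_cigar <- function(pos, cigar, chrom = NA_character_) {
  stopifnot(pos >= 0)
  m <- stringr::str_match_all(cigar, "(\\d+)([MIDNSHP=X])")[[1]]
  if (nrow(m) == 0 || paste(m[, 1], collapse = "") != cigar) {
    abort(paste0("Invalid CIGAR string: ", cigar))
  }
  len <- as.integer(m[, 2])
  op <- m[, 3]
  starts <- integer(0); ends <- integer(0)
  cur_start <- pos; cur_end <- pos
  flush <- function() {
    if (cur_end > cur_start) {
      starts <<- c(starts, cur_start); ends <<- c(ends, cur_end)
    }
  }
  for (i in seq_along(op)) {
    o <- op[i]
    if (o %in% c("M", "=", "X", "D")) {
      cur_end <- cur_end + len[i]
    } else if (o == "N") {
      flush()
      cur_start <- cur_end + len[i]
      cur_end <- cur_start
    }
  }
  flush()
  list(
    blocks = tibble(chrom = chrom, start = starts, end = ends),
    aligned_len = as.integer(sum(ends - starts)),
    has_hard_clip = any(op == "H"),
    query_len = as.integer(sum(len[op %in% c("M", "I", "S", "=", "X")]))
  )
}

#' Alignment-level filters
#'
#' A read passes iff it is a mapped primary alignment with
#' `mapq >= mapq_min` and no hard clipping. Hard-clipped reads are
#' excluded because long-read aligners hard-clip when realigning
#' poor-quality reads; MAPQ >= 30 on a primary alignment is the
#' operational definition of "uniquely mapped".
#'
#' @param is_unmapped,is_secondary,is_supplementary,has_hard_clip Logical
#'   record flags.
#' @param mapq Mapping quality.
#' @param mapq_min Threshold (default 30).
#' @return Logical (vectorized).
#' @export
passes_filters <- function(is_unmapped, is_secondary, is_supplementary,
                           has_hard_clip, mapq, mapq_min = 30) {
  !is_unmapped & !is_secondary & !is_supplementary &
    !has_hard_clip & !is.na(mapq) & mapq >= mapq_min
}

#' Classify one TE-overlapping read
#'
#' @param blocks Reference-consuming blocks of the read (tibble
#'   `chrom`/`start`/`end`), e.g. from [blocks_from_cigar()].
#' @param masks The four masks from [build_te_masks()].
#' @param te_frac_min Intragenic-TE fraction a category-2 read must
#'   exceed (strictly). Default 0.8.
#' @return One-row tibble: `category`, `te_bp`, `exon_bp`, `inter_te_bp`,
#'   `intra_te_bp`, `aligned_len`, `te_fraction`
#'   (`intra_te_bp / aligned_len`). Calling this on a read with zero TE
#'   overlap is an error: such reads are outside the classification.
#' @export
classify_read <- function(blocks, masks, te_frac_min = 0.8) {
  aligned_len <- sum(blocks$end - blocks$start)
  te_bp <- overlap_bp(blocks, masks$TE_all)
  if (te_bp == 0) {
    abort("classify_read() requires a TE-overlapping read (te_bp > 0)")
  }
  exon_bp <- overlap_bp(blocks, masks$EXON)
  inter_te_bp <- overlap_bp(blocks, masks$TE_intergenic)
  intra_te_bp <- overlap_bp(blocks, masks$TE_intragenic)
  te_fraction <- intra_te_bp / aligned_len
  category <-
    if (exon_bp == 0 && inter_te_bp > 0 && intra_te_bp == 0) "1_intergenic"
    else if (exon_bp > 0 && inter_te_bp > 0) "3_fusion"
    else if (exon_bp > 0 && te_fraction > te_frac_min) "2_intragenic"
    else "4_other"
  tibble(category = category, te_bp = te_bp, exon_bp = exon_bp,
         inter_te_bp = inter_te_bp, intra_te_bp = intra_te_bp,
         aligned_len = as.integer(aligned_len), te_fraction = te_fraction)
}

ensure_bam <- function(path) {
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    Rsamtools::asBam(path, dest, indexDestination = FALSE)
  } else {
    path
  }
}

#' Read alignments into a tibble
#'
#' Reads a SAM or BAM file (SAM is converted through `Rsamtools`
#' internally) and reduces each record to the fields the classifier
#' needs. Blocks are attached as a list-column.
#'
#' @param path SAM or BAM file.
#' @return Tibble: `read_id`, `flag`, `chrom`, `pos` (0-based), `mapq`,
#'   `cigar`, flag booleans, `blocks` (list of tibbles), `aligned_len`,
#'   `has_hard_clip`.
#' @export
read_alignments <- function(path) {
  if (!file.exists(path)) abort(paste0("Alignment file not found: ", path))
  bam <- ensure_bam(path)
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "mapq", "cigar"))
  rec <- Rsamtools::scanBam(bam, param = p)[[1]]
  n <- length(rec$qname)
  flag <- rec$flag
  is_unmapped <- bitwAnd(flag, 4L) > 0L
  parsed <- purrr::map(seq_len(n), function(i) {
    if (is_unmapped[i] || is.na(rec$cigar[i])) {
      list(blocks = tibble(chrom = character(), start = integer(),
                           end = integer()),
           aligned_len = 0L, has_hard_clip = FALSE, query_len = 0L)
    } else {
      blocks_from_cigar(rec$pos[i] - 1L, rec$cigar[i],
                        as.character(rec$rname[i]))
    }
  })
  tibble(
    read_id = rec$qname,
    flag = flag,
    chrom = as.character(rec$rname),
    pos = rec$pos - 1L,
    mapq = rec$mapq,
    cigar = rec$cigar,
    is_unmapped = is_unmapped,
    is_secondary = bitwAnd(flag, 256L) > 0L,
    is_supplementary = bitwAnd(flag, 2048L) > 0L,
    has_hard_clip = vapply(parsed, `[[`, logical(1), "has_hard_clip"),
    blocks = purrr::map(parsed, "blocks"),
    aligned_len = vapply(parsed, `[[`, integer(1), "aligned_len")
  )
}

#' Classify every read in an alignment file
#'
#' Applies [passes_filters()] and [classify_read()] to each record,
#' optionally writing one alignment file per category plus a merged
#' categories-1..3 file (the input to downstream transcript assembly)
#' and a report. Pass-filter reads with zero TE overlap get category
#' `"not_te"`; filtered records get `"discarded"`. Duplicate identical
#' records are counted (and written) as many times as they occur.
#'
#' @param path SAM or BAM file of long-read alignments.
#' @param masks Masks from [build_te_masks()].
#' @param output_dir If non-NULL, per-category files (`category_1`..
#'   `category_4`, `categories_1_2_3`; BAM for BAM input, SAM for SAM
#'   input) plus `report.tsv` and `report.json` are written here.
#' @param mapq_min,te_frac_min Thresholds (defaults 30 and 0.8).
#' @return A `te_read_classification` object: list with `reads` (per-
#'   record tibble incl. `category`), `report` (per-category counts and
#'   proportions of the uniquely-mapped pass-filter total), `params`,
#'   `files`.
#' @export
classify_alignments <- function(path, masks, output_dir = NULL,
                                mapq_min = 30, te_frac_min = 0.8) {
  reads <- read_alignments(path)
  pass <- passes_filters(reads$is_unmapped, reads$is_secondary,
                         reads$is_supplementary, reads$has_hard_clip,
                         reads$mapq, mapq_min)
  cls <- purrr::map(seq_len(nrow(reads)), function(i) {
    if (!pass[i]) {
      return(tibble(category = "discarded", te_bp = NA_integer_,
                    exon_bp = NA_integer_, inter_te_bp = NA_integer_,
                    intra_te_bp = NA_integer_,
                    aligned_len = reads$aligned_len[i],
                    te_fraction = NA_real_))
    }
    blocks <- reads$blocks[[i]]
    if (overlap_bp(blocks, masks$TE_all) == 0) {
      return(tibble(category = "not_te", te_bp = 0L, exon_bp = NA_integer_,
                    inter_te_bp = NA_integer_, intra_te_bp = NA_integer_,
                    aligned_len = reads$aligned_len[i], te_fraction = 0))
    }
    classify_read(blocks, masks, te_frac_min)
  })
  reads <- bind_cols(reads, select(bind_rows(cls), -"aligned_len"))
  uniquely_mapped <- sum(pass)
  cats <- c("1_intergenic", "2_intragenic", "3_fusion", "4_other")
  counts <- vapply(cats, function(k) sum(reads$category == k), integer(1))
  report <- tibble(
    category = c(cats, "not_te", "discarded"),
    n_reads = c(counts, sum(reads$category == "not_te"),
                sum(reads$category == "discarded")),
    proportion_of_uniquely_mapped =
      c(if (uniquely_mapped > 0) counts / uniquely_mapped else rep(0, 4),
        NA_real_, NA_real_)
  )
  files <- NULL
  if (!is.null(output_dir)) {
    files <- write_category_files(path, reads, report, output_dir,
                                  uniquely_mapped,
                                  mapq_min = mapq_min,
                                  te_frac_min = te_frac_min)
  }
  structure(
    list(reads = reads, report = report, uniquely_mapped = uniquely_mapped,
         params = list(mapq_min = mapq_min, te_frac_min = te_frac_min),
         files = files),
    class = "te_read_classification")
}

write_category_files <- function(path, reads, report, output_dir,
                                 uniquely_mapped, mapq_min, te_frac_min) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  input_is_sam <- grepl("\\.sam$", path, ignore.case = TRUE)
  bam <- ensure_bam(path)
  key <- function(qname, rname, pos, cigar, flag) {
    paste(qname, rname, pos, cigar, flag, sep = "\r")
  }
  read_keys <- key(reads$read_id, reads$chrom, reads$pos + 1L, reads$cigar,
                   reads$flag)
  sets <- list(
    category_1 = read_keys[reads$category == "1_intergenic"],
    category_2 = read_keys[reads$category == "2_intragenic"],
    category_3 = read_keys[reads$category == "3_fusion"],
    category_4 = read_keys[reads$category == "4_other"],
    categories_1_2_3 = read_keys[reads$category %in%
                                   c("1_intergenic", "2_intragenic", "3_fusion")]
  )
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "mapq", "cigar"))
  files <- purrr::imap(sets, function(keys, nm) {
    dest_bam <- file.path(output_dir, paste0(nm, ".bam"))
    rule <- S4Vectors::FilterRules(list(in_set = function(df) {
      key(df$qname, as.character(df$rname), df$pos, df$cigar, df$flag) %in% keys
    }))
    Rsamtools::filterBam(Rsamtools::BamFile(bam), dest_bam, filter = rule,
                         param = param, indexDestination = FALSE)
    if (input_is_sam) {
      dest_sam <- Rsamtools::asSam(dest_bam,
                                   file.path(output_dir, nm),
                                   overwrite = TRUE)
      unlink(dest_bam)
      dest_sam
    } else {
      dest_bam
    }
  })
  report_tsv <- file.path(output_dir, "report.tsv")
  readr::write_tsv(report, report_tsv)
  report_json <- file.path(output_dir, "report.json")
  jsonlite::write_json(
    list(uniquely_mapped_pass_filter = uniquely_mapped,
         params = list(mapq_min = mapq_min, te_frac_min = te_frac_min),
         categories = setNames(as.list(report$n_reads), report$category),
         proportions = setNames(
           as.list(report$proportion_of_uniquely_mapped), report$category)),
    report_json, auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
  c(files, list(report_tsv = report_tsv, report_json = report_json))
}

#' @export
print.te_read_classification <- function(x, ...) {
  cat("<te_read_classification> ", nrow(x$reads), " records, ",
      x$uniquely_mapped, " uniquely mapped pass-filter\n", sep = "")
  print(x$report)
  invisible(x)
}

#' @rdname classify_alignments
#' @param x A `te_read_classification`.
#' @param ... Unused.
#' @export
tidy.te_read_classification <- function(x, ...) {
  select(x$reads, -"blocks")
}

#' @rdname classify_alignments
#' @export
glance.te_read_classification <- function(x, ...) {
  wide <- setNames(as.list(x$report$n_reads),
                   paste0("n_", x$report$category))
  bind_cols(tibble(n_records = nrow(x$reads),
                   uniquely_mapped = x$uniquely_mapped),
            as_tibble(wide))
}
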