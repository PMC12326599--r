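# Per-cell quantification of genes, isoforms and repeat elements from a
# barcoded alignment file, after the conservative TE/gene annotation
# reconciliation. Output is a 10x-style sparse feature-barcode matrix.

#' Sparse feature-barcode count matrix
#'
#' @param counts A features x barcodes sparse matrix
#'   ([Matrix::sparseMatrix]) of non-negative integer UMI counts.
#' @param features Tibble with `id`, `name`, `kind`
#'   (`gene`/`isoform`/`repeat_element`) and `is_te` (logical); row order
#'   matches `counts`.
#' @param barcodes Character vector matching `counts` columns.
#' @return A `te_count_matrix` object.
#' @export
te_count_matrix <- function(counts, features, barcodes) {
  counts <- methods::as(methods::as(counts, "CsparseMatrix"), "generalMatrix")
  stopifnot(nrow(counts) == nrow(features),
            ncol(counts) == length(barcodes),
            all(c("id", "name", "kind", "is_te") %in% names(features)))
  if (anyDuplicated(features$id) > 0) abort("Feature ids must be unique")
  if (any(counts@x < 0)) abort("Counts must be non-negative")
  dimnames(counts) <- list(features$id, barcodes)
  structure(list(counts = counts, features = as_tibble(features),
                 barcodes = barcodes, normalized = NULL),
            class = "te_count_matrix")
}

#' @export
print.te_count_matrix <- function(x, ...) {
  cat("<te_count_matrix> ", nrow(x$features), " features x ",
      length(x$barcodes), " barcodes, ", sum(x$counts), " UMIs",
      if (!is.null(x$normalized)) " (normalized layer present)", "\n",
      sep = "")
  invisible(x)
}

#' @rdname te_count_matrix
#' @param x A `te_count_matrix`.
#' @param layer `"counts"` or `"normalized"`.
#' @param ... Unused.
#' @export
tidy.te_count_matrix <- function(x, layer = "counts", ...) {
  m <- if (layer == "normalized") x$normalized else x$counts
  if (is.null(m)) abort("Requested layer is absent; run normalize_log1p()")
  tm <- Matrix::summary(m)
  tibble(feature_id = x$features$id[tm$i], barcode = x$barcodes[tm$j],
         value = tm$x) %>%
    arrange(.data$barcode, .data$feature_id)
}

#' @rdname te_count_matrix
#' @export
glance.te_count_matrix <- function(x, ...) {
  tibble(n_features = nrow(x$features), n_barcodes = length(x$barcodes),
         n_te_features = sum(x$features$is_te), total_umis = sum(x$counts),
         has_normalized = !is.null(x$normalized))
}

#' Reconcile a TE annotation with the reference gene annotation
#'
#' The conservative step before single-cell quantification: TE-derived
#' transcripts with >= 1 bp of exonic overlap against any nonTE gene
#' exon (strand-agnostic) are removed, so reads in shared regions go to
#' the nonTE gene annotation. Survivors are concatenated with the gene
#' annotation.
#'
#' @param te_exons Exon tibble of the TE-derived annotation
#'   (`source_kind` `"TE_derived"`).
#' @param gene_exons Exon tibble of the nonTE gene annotation.
#' @return List: `merged` (exon tibble with `source_kind` set),
#'   `removed_transcripts` (character).
#' @export
reconcile_annotations <- function(te_exons, gene_exons) {
  removed <- character(0)
  if (nrow(te_exons) > 0 && nrow(gene_exons) > 0) {
    hits <- logical(nrow(te_exons))
    for (chr in unique(te_exons$chrom)) {
      ti <- which(te_exons$chrom == chr)
      ge <- gene_exons[gene_exons$chrom == chr, , drop = FALSE]
      if (nrow(ge) == 0) next
      hits[ti] <- IRanges::overlapsAny(
        IRanges::IRanges(te_exons$start[ti] + 1L, te_exons$end[ti]),
        IRanges::IRanges(ge$start + 1L, ge$end))
    }
    removed <- unique(te_exons$transcript_id[hits])
  }
  survivors <- filter(te_exons, !.data$transcript_id %in% removed) %>%
    mutate(source_kind = "TE_derived")
  merged <- bind_rows(mutate(gene_exons, source_kind = "nonTE_gene"),
                      survivors)
  dup <- intersect(unique(gene_exons$transcript_id),
                   unique(survivors$transcript_id))
  if (length(dup) > 0) {
    abort(paste0("Duplicate feature ids after merge: ",
                 paste(head(dup, 5), collapse = ", ")))
  }
  list(merged = merged, removed_transcripts = removed)
}

#' Build the per-chromosome feature index
#'
#' Interval index over two layers: transcript exons (nonTE genes + TE
#' transcripts) and repeat elements. Queries return exactly what a
#' linear scan would.
#'
#' @param merged_exons Merged exon tibble from [reconcile_annotations()].
#' @param repeats Repeat tibble (may have zero rows to skip the repeat
#'   layer).
#' @return A `feature_index` object.
#' @export
feature_index <- function(merged_exons, repeats = NULL) {
  if (is.null(repeats)) {
    repeats <- tibble(chrom = character(), start = integer(),
                      end = integer(), element_id = character())
  }
  chroms <- union(unique(merged_exons$chrom), unique(repeats$chrom))
  idx <- lapply(chroms, function(chr) {
    ex <- merged_exons[merged_exons$chrom == chr, , drop = FALSE]
    rp <- repeats[repeats$chrom == chr, , drop = FALSE]
    list(
      exon_ranges = IRanges::IRanges(ex$start + 1L, ex$end),
      exon_meta = select(ex, "transcript_id", "gene_id", "source_kind"),
      repeat_ranges = IRanges::IRanges(rp$start + 1L, rp$end),
      repeat_ids = rp$element_id
    )
  })
  names(idx) <- chroms
  structure(list(chrom_index = idx), class = "feature_index")
}

#' Assign one read to features
#'
#' Transcript layer: candidate transcripts are collected by block/exon
#' overlap; if any candidate is a nonTE gene all TE candidates are
#' dropped; the surviving gene id must be unique (else the read is
#' ambiguous and unassigned in this layer); the read then counts toward
#' that gene and toward the single transcript with maximal overlap bp
#' (transcript tie: gene only, no isoform count). Repeat layer: the read
#' counts toward every repeat element it overlaps by >= 1 bp.
#'
#' @param blocks Reference-consuming blocks tibble of one read.
#' @param index A `feature_index`.
#' @return List: `status` (`assigned`/`ambiguous`/`no_feature`),
#'   `gene_id`, `transcript_id` (NA on tie), `repeat_ids`.
#' @export
assign_read <- function(blocks, index) {
  chr <- blocks$chrom[1]
  ci <- index$chrom_index[[chr]]
  if (is.null(ci)) {
    return(list(status = "no_feature", gene_id = NA_character_,
                transcript_id = NA_character_, repeat_ids = character()))
  }
  q <- IRanges::IRanges(blocks$start + 1L, blocks$end)
  rep_ids <- character()
  if (length(ci$repeat_ranges) > 0) {
    rh <- IRanges::findOverlaps(q, ci$repeat_ranges)
    rep_ids <- unique(ci$repeat_ids[S4Vectors::subjectHits(rh)])
  }
  if (length(ci$exon_ranges) == 0) {
    return(list(status = "no_feature", gene_id = NA_character_,
                transcript_id = NA_character_, repeat_ids = rep_ids))
  }
  h <- IRanges::findOverlaps(q, ci$exon_ranges)
  if (length(h) == 0) {
    return(list(status = "no_feature", gene_id = NA_character_,
                transcript_id = NA_character_, repeat_ids = rep_ids))
  }
  ov_bp <- IRanges::width(IRanges::pintersect(
    q[S4Vectors::queryHits(h)], ci$exon_ranges[S4Vectors::subjectHits(h)]))
  cand <- ci$exon_meta[S4Vectors::subjectHits(h), , drop = FALSE] %>%
    mutate(bp = ov_bp) %>%
    group_by(.data$transcript_id, .data$gene_id, .data$source_kind) %>%
    summarise(bp = sum(.data$bp), .groups = "drop")
  if (any(cand$source_kind == "nonTE_gene")) {
    cand <- filter(cand, .data$source_kind == "nonTE_gene")
  }
  genes <- unique(cand$gene_id)
  if (length(genes) > 1) {
    return(list(status = "ambiguous", gene_id = NA_character_,
                transcript_id = NA_character_, repeat_ids = rep_ids))
  }
  best <- cand$bp == max(cand$bp)
  tx <- if (sum(best) == 1) cand$transcript_id[best] else NA_character_
  list(status = "assigned", gene_id = genes, transcript_id = tx,
       repeat_ids = rep_ids)
}

#' Quantify genes, isoforms and repeat elements per cell barcode
#'
#' Scans a barcoded SAM/BAM (10x-style `CB` cell barcode and `UB` UMI
#' tags), applies the same alignment filters as the bulk classifier,
#' assigns reads with [assign_read()], and collapses duplicate molecules:
#' one increment per distinct (barcode, feature, UMI) triple. Reads
#' lacking `CB` or `UB` are skipped and tallied; with a whitelist, other
#' barcodes are discarded. Gene + isoform counts land in one matrix;
#' repeat-element counts in a separate one.
#'
#' @param path Barcoded SAM/BAM.
#' @param merged_exons Merged annotation from [reconcile_annotations()].
#' @param repeats Repeat tibble for the repeat-element layer (or NULL).
#' @param barcode_whitelist Optional character vector of allowed
#'   barcodes (also fixes the column order of the output).
#' @param mapq_min MAPQ threshold, default 30.
#' @return A `te_sc_counts` object: list with `matrix` (genes +
#'   isoforms, `te_count_matrix`), `repeat_matrix`, and `stats`
#'   (partition of scanned records: `filtered`, `no_tag`,
#'   `not_whitelisted`, `no_feature`, `ambiguous`, `assigned`; their sum
#'   equals `total_records`).
#' @export
quantify_cells <- function(path, merged_exons, repeats = NULL,
                           barcode_whitelist = NULL, mapq_min = 30) {
  idx <- feature_index(merged_exons, repeats)
  bam <- ensure_bam(path)
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "mapq", "cigar"),
    tag = c("CB", "UB"))
  rec <- Rsamtools::scanBam(bam, param = p)[[1]]
  n <- length(rec$qname)
  cb <- rec$tag$CB %||% rep(NA_character_, n)
  ub <- rec$tag$UB %||% rep(NA_character_, n)
  flag <- rec$flag
  stats <- c(total_records = n, filtered = 0L, no_tag = 0L,
             not_whitelisted = 0L, no_feature = 0L, ambiguous = 0L,
             assigned = 0L)
  triples <- vector("list", n)
  rep_triples <- vector("list", n)
  for (i in seq_len(n)) {
    unmapped <- bitwAnd(flag[i], 4L) > 0L
    info <- if (unmapped || is.na(rec$cigar[i])) NULL else
      blocks_from_cigar(rec$pos[i] - 1L, rec$cigar[i],
                        as.character(rec$rname[i]))
    ok <- !unmapped && !is.null(info) &&
      passes_filters(FALSE, bitwAnd(flag[i], 256L) > 0L,
                     bitwAnd(flag[i], 2048L) > 0L, info$has_hard_clip,
                     rec$mapq[i], mapq_min)
    if (!ok) { stats["filtered"] <- stats["filtered"] + 1L; next }
    if (is.na(cb[i]) || is.na(ub[i]) || cb[i] == "" || ub[i] == "") {
      stats["no_tag"] <- stats["no_tag"] + 1L; next
    }
    if (!is.null(barcode_whitelist) && !cb[i] %in% barcode_whitelist) {
      stats["not_whitelisted"] <- stats["not_whitelisted"] + 1L; next
    }
    a <- assign_read(info$blocks, idx)
    if (length(a$repeat_ids) > 0) {
      rep_triples[[i]] <- tibble(barcode = cb[i], feature = a$repeat_ids,
                                 umi = ub[i])
    }
    if (a$status != "assigned") {
      stats[a$status] <- stats[a$status] + 1L; next
    }
    stats["assigned"] <- stats["assigned"] + 1L
    feats <- c(a$gene_id, if (!is.na(a$transcript_id)) a$transcript_id)
    triples[[i]] <- tibble(barcode = cb[i], feature = feats, umi = ub[i])
  }
  feature_tbl <- sc_feature_table(merged_exons)
  empty_triple <- tibble(barcode = character(), feature = character(),
                         umi = character())
  barcodes <- if (!is.null(barcode_whitelist)) barcode_whitelist else
    sort(unique(c(bind_rows(empty_triple, triples)$barcode,
                  bind_rows(empty_triple, rep_triples)$barcode)))
  build <- function(tr_list, feats) {
    tr <- bind_rows(empty_triple, tr_list)
    tr <- distinct(tr, .data$barcode, .data$feature, .data$umi)
    tr <- filter(tr, .data$feature %in% feats$id, .data$barcode %in% barcodes)
    cnt <- count(tr, .data$barcode, .data$feature)
    m <- Matrix::sparseMatrix(
      i = match(cnt$feature, feats$id), j = match(cnt$barcode, barcodes),
      x = cnt$n, dims = c(nrow(feats), length(barcodes)))
    te_count_matrix(m, feats, barcodes)
  }
  rep_feats <- if (is.null(repeats) || nrow(repeats) == 0) {
    tibble(id = character(), name = character(), kind = character(),
           is_te = logical())
  } else {
    tibble(id = repeats$element_id, name = repeats$subfamily,
           kind = "repeat_element", is_te = TRUE)
  }
  structure(list(matrix = build(triples, feature_tbl),
                 repeat_matrix = build(rep_triples, rep_feats),
                 stats = as.list(stats)),
            class = "te_sc_counts")
}

#' @export
print.te_sc_counts <- function(x, ...) {
  cat("<te_sc_counts>\n  transcript layer: ")
  print(x$matrix)
  cat("  repeat layer: ")
  print(x$repeat_matrix)
  cat("  stats:", paste(names(x$stats), unlist(x$stats), sep = "=",
                        collapse = " "), "\n")
  invisible(x)
}

#' @rdname quantify_cells
#' @param x A `te_sc_counts`.
#' @param ... Unused.
#' @export
glance.te_sc_counts <- function(x, ...) {
  as_tibble(x$stats)
}

gzip_copy <- function(src, dest) {
  con <- gzfile(dest, open = "wb")
  on.exit(close(con))
  writeLines(readLines(src), con)
  invisible(dest)
}

#' Write / read a 10x-style matrix directory
#'
#' `write_matrix()` emits `matrix.mtx.gz` (MatrixMarket coordinate
#' format), `features.tsv.gz` (`id`, `name`, `kind`, `is_te`) and
#' `barcodes.tsv.gz`; `read_matrix()` reverses it exactly, and a second
#' `write_matrix()` of the result is byte-identical.
#'
#' @param matrix A `te_count_matrix`.
#' @param dir Output directory (created if needed).
#' @return `write_matrix()`: `dir`, invisibly. `read_matrix()`: a
#'   `te_count_matrix`.
#' @export
write_matrix <- function(matrix, dir) {
  stopifnot(inherits(matrix, "te_count_matrix"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tmp <- tempfile(fileext = ".mtx")
  m <- matrix$counts
  dimnames(m) <- NULL
  Matrix::writeMM(m, tmp)
  gzip_copy(tmp, file.path(dir, "matrix.mtx.gz"))
  unlink(tmp)
  fcon <- gzfile(file.path(dir, "features.tsv.gz"), "wb")
  writeLines(paste(matrix$features$id, matrix$features$name,
                   matrix$features$kind,
                   ifelse(matrix$features$is_te, "TE", "nonTE"),
                   sep = "\t"), fcon)
  close(fcon)
  bcon <- gzfile(file.path(dir, "barcodes.tsv.gz"), "wb")
  writeLines(matrix$barcodes, bcon)
  close(bcon)
  invisible(dir)
}

#' @rdname write_matrix
#' @export
read_matrix <- function(dir) {
  mtx <- file.path(dir, "matrix.mtx.gz")
  if (!file.exists(mtx)) abort(paste0("No matrix.mtx.gz under ", dir))
  m <- Matrix::readMM(gzfile(mtx))
  feat_lines <- readLines(gzfile(file.path(dir, "features.tsv.gz")))
  parts <- strsplit(feat_lines, "\t", fixed = TRUE)
  features <- tibble(
    id = vapply(parts, `[`, character(1), 1),
    name = vapply(parts, `[`, character(1), 2),
    kind = vapply(parts, `[`, character(1), 3),
    is_te = vapply(parts, `[`, character(1), 4) == "TE"
  )
  barcodes <- readLines(gzfile(file.path(dir, "barcodes.tsv.gz")))
  if (nrow(m) != nrow(features) || ncol(m) != length(barcodes)) {
    abort("Matrix dimensions do not match features/barcodes tables")
  }
  te_count_matrix(m, features, barcodes)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
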