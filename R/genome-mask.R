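# Whole-genome binary masks: one bit per base, per chromosome. These are
# the classifier's O(1) overlap oracle — a base is 1 iff it is covered by
# at least one of the intervals the mask was built from.

#' Build a whole-genome binary mask from intervals
#'
#' @param intervals Tibble with `chrom`, `start`, `end` (0-based
#'   half-open). Strand is ignored: masks are unstranded.
#' @param sizes Named integer vector of chromosome lengths (bp), e.g.
#'   from [chrom_sizes()].
#' @param label Free-text label recorded on the mask (e.g. `"TE_all"`).
#' @return A `genome_mask` object.
#' @export
build_genome_mask <- function(intervals, sizes, label = "mask") {
  stopifnot(is.numeric(sizes), !is.null(names(sizes)), all(sizes > 0))
  if (nrow(intervals) > 0) {
    unknown <- setdiff(unique(intervals$chrom), names(sizes))
    if (length(unknown) > 0) {
      abort(paste0("Interval on unknown chromosome(s): ",
                   paste(unknown, collapse = ", ")))
    }
    over <- intervals$end > sizes[intervals$chrom] | intervals$start < 0
    if (any(over)) {
      abort(paste0(sum(over), " interval(s) exceed chromosome bounds (first: ",
                   intervals$chrom[which(over)[1]], ":",
                   intervals$start[which(over)[1]], "-",
                   intervals$end[which(over)[1]], ")"))
    }
  }
  bits <- lapply(names(sizes), function(chr) {
    m <- logical(sizes[[chr]])
    sub <- intervals[intervals$chrom == chr, , drop = FALSE]
    for (i in seq_len(nrow(sub))) {
      m[(sub$start[i] + 1L):sub$end[i]] <- TRUE
    }
    m
  })
  names(bits) <- names(sizes)
  structure(list(bits = bits, sizes = sizes, label = label),
            class = "genome_mask")
}

#' @export
print.genome_mask <- function(x, ...) {
  cat("<genome_mask '", x$label, "'> ", length(x$bits), " chromosome(s), ",
      format(sum(x$sizes), big.mark = ","), " bp, popcount ",
      format(mask_popcount(x), big.mark = ","), "\n", sep = "")
  invisible(x)
}

#' Number of set bits in a mask
#'
#' Equals the length of the union of the intervals the mask was built
#' from.
#'
#' @param mask A `genome_mask`.
#' @param chrom Optional single chromosome to restrict to.
#' @return Integer base count.
#' @export
mask_popcount <- function(mask, chrom = NULL) {
  stopifnot(inherits(mask, "genome_mask"))
  if (is.null(chrom)) return(sum(vapply(mask$bits, sum, numeric(1))))
  if (!chrom %in% names(mask$bits)) {
    abort(paste0("Chromosome absent from mask: ", chrom))
  }
  sum(mask$bits[[chrom]])
}

#' Count block bases covered by a mask
#'
#' @param blocks Tibble with `chrom`, `start`, `end` (0-based half-open);
#'   typically the reference-consuming blocks of one read.
#' @param mask A `genome_mask`.
#' @return Integer: number of block bases whose mask bit is 1. Querying a
#'   chromosome absent from the mask, or outside its bounds, is an error.
#' @export
overlap_bp <- function(blocks, mask) {
  stopifnot(inherits(mask, "genome_mask"))
  if (nrow(blocks) == 0) return(0L)
  total <- 0L
  for (i in seq_len(nrow(blocks))) {
    chr <- blocks$chrom[i]
    bits <- mask$bits[[chr]]
    if (is.null(bits)) abort(paste0("Chromosome absent from mask: ", chr))
    s <- blocks$start[i]; e <- blocks$end[i]
    if (s < 0 || e > length(bits) || s >= e) {
      abort(paste0("Block outside chromosome bounds: ", chr, ":", s, "-", e))
    }
    total <- total + sum(bits[(s + 1L):e])
  }
  as.integer(total)
}

#' Label repeat elements as intergenic or intragenic
#'
#' An element is `intragenic` iff it overlaps any nonTE gene span by at
#' least 1 bp (half-open touching is not overlap), else `intergenic`.
#' Labeling is element-level against full gene spans, so intronic repeats
#' are intragenic. Input order is preserved.
#'
#' @param repeats Repeat tibble from [read_repeatmasker()].
#' @param gene_spans Tibble with `chrom`, `start`, `end` — full transcript
#'   spans of nonTE genes (e.g. [transcript_spans()] output).
#' @return `repeats` with `genic_context` filled in.
#' @export
label_genic_context <- function(repeats, gene_spans) {
  if (nrow(repeats) == 0) return(repeats)
  ctx <- rep("intergenic", nrow(repeats))
  for (chr in unique(repeats$chrom)) {
    ri <- which(repeats$chrom == chr)
    gs <- gene_spans[gene_spans$chrom == chr, , drop = FALSE]
    if (nrow(gs) == 0) next
    hits <- IRanges::overlapsAny(
      IRanges::IRanges(repeats$start[ri] + 1L, repeats$end[ri]),
      IRanges::IRanges(gs$start + 1L, gs$end)
    )
    ctx[ri[hits]] <- "intragenic"
  }
  repeats$genic_context <- ctx
  repeats
}

#' Build the four classification masks
#'
#' Builds the masks the read classifier consumes: all TE bases, TE bases
#' split by genic context of the element, and nonTE gene exon bases.
#' `TE_all` equals `TE_intergenic OR TE_intragenic` by construction.
#'
#' @param repeats TE-only repeat tibble ([read_repeatmasker()] with
#'   `te_only = TRUE`).
#' @param gene_exons Exon tibble of the nonTE gene annotation
#'   ([read_gtf()]).
#' @param sizes Named chromosome-size vector.
#' @return Named list of `genome_mask`: `TE_all`, `TE_intergenic`,
#'   `TE_intragenic`, `EXON`. The context-labeled repeat tibble is
#'   attached as attribute `"repeats"`.
#' @export
build_te_masks <- function(repeats, gene_exons, sizes) {
  spans <- transcript_spans(gene_exons)
  labeled <- label_genic_context(repeats, spans)
  masks <- list(
    TE_all = build_genome_mask(labeled, sizes, "TE_all"),
    TE_intergenic = build_genome_mask(
      filter(labeled, .data$genic_context == "intergenic"), sizes, "TE_intergenic"),
    TE_intragenic = build_genome_mask(
      filter(labeled, .data$genic_context == "intragenic"), sizes, "TE_intragenic"),
    EXON = build_genome_mask(gene_exons, sizes, "EXON")
  )
  attr(masks, "repeats") <- labeled
  masks
}
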