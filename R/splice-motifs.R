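# Splice-site sequence extraction and position-wise information-content
# matrices. The donor window covers the last exonic bases plus the first
# intronic bases of each intron (so canonical introns show G,T at
# intronic positions 1-2); the acceptor window covers the last intronic
# plus first exonic bases (A,G at intronic positions -2,-1).

#' Extract splice donor and acceptor sequences
#'
#' For every intron of every multi-exon transcript, windows around the
#' two splice sites are cut from the genome. On the minus strand the
#' positions are mirrored and the sequences reverse-complemented so that
#' all sites read 5'->3' in transcript orientation. Sites whose window
#' would run off the chromosome are skipped with a warning. Sequences
#' containing `N` are retained.
#'
#' @param exons Exon tibble ([read_gtf()]).
#' @param genome A [Biostrings::DNAStringSet] ([read_fasta()]).
#' @param donor_window `c(exonic, intronic)` widths, default `c(3, 6)`.
#' @param acceptor_window `c(intronic, exonic)` widths, default
#'   `c(6, 3)`.
#' @return A `splice_site_set`: list with `donors`, `acceptors`
#'   (character vectors of fixed-width sequences) and `windows`.
#' @export
extract_splice_sites <- function(exons, genome,
                                 donor_window = c(3, 6),
                                 acceptor_window = c(6, 3)) {
  introns <- exons %>%
    group_by(.data$transcript_id) %>%
    filter(n() > 1) %>%
    arrange(.data$start, .by_group = TRUE) %>%
    summarise(chrom = first(.data$chrom), strand = first(.data$strand),
              istart = list(head(.data$end, -1)),
              iend = list(tail(.data$start, -1)),
              .groups = "drop") %>%
    tidyr::unnest(c("istart", "iend"))
  if (nrow(introns) == 0) {
    return(structure(list(donors = character(), acceptors = character(),
                          windows = list(donor = donor_window,
                                         acceptor = acceptor_window)),
                     class = "splice_site_set"))
  }
  de <- donor_window[1]; di <- donor_window[2]
  ai <- acceptor_window[1]; ae <- acceptor_window[2]
  # 0-based half-open genome windows per intron (istart/iend are the
  # intron's half-open bounds on the forward strand)
  win <- introns %>%
    mutate(
      donor_s = if_else(.data$strand == "-", .data$iend - di, .data$istart - de),
      donor_e = if_else(.data$strand == "-", .data$iend + de, .data$istart + di),
      accept_s = if_else(.data$strand == "-", .data$istart - ae, .data$iend - ai),
      accept_e = if_else(.data$strand == "-", .data$istart + ai, .data$iend + ae)
    )
  cut_seq <- function(chrom, s, e, minus) {
    len <- chrom_sizes(genome)[chrom]
    if (is.na(len) || s < 0 || e > len) return(NA_character_)
    seq <- Biostrings::subseq(genome[[chrom]], start = s + 1L, end = e)
    if (minus) seq <- Biostrings::reverseComplement(seq)
    as.character(seq)
  }
  donors <- vapply(seq_len(nrow(win)), function(i) {
    cut_seq(win$chrom[i], win$donor_s[i], win$donor_e[i],
            win$strand[i] == "-")
  }, character(1))
  acceptors <- vapply(seq_len(nrow(win)), function(i) {
    cut_seq(win$chrom[i], win$accept_s[i], win$accept_e[i],
            win$strand[i] == "-")
  }, character(1))
  n_skip <- sum(is.na(donors)) + sum(is.na(acceptors))
  if (n_skip > 0) {
    warn(paste0(n_skip, " splice-site window(s) exceeded chromosome bounds",
                " and were skipped"))
  }
  structure(list(donors = donors[!is.na(donors)],
                 acceptors = acceptors[!is.na(acceptors)],
                 windows = list(donor = donor_window,
                                acceptor = acceptor_window)),
            class = "splice_site_set")
}

#' @export
print.splice_site_set <- function(x, ...) {
  cat("<splice_site_set> ", length(x$donors), " donors, ",
      length(x$acceptors), " acceptors\n", sep = "")
  invisible(x)
}

#' Position-wise nucleotide count matrix
#'
#' @param sequences Character vector of equal-width sequences over
#'   `A,C,G,T,N`; `N` is not counted.
#' @return A `motif_matrix` (positions x A/C/G/T numeric matrix) with
#'   attribute `layer = "counts"`.
#' @export
counts_matrix <- function(sequences) {
  if (length(sequences) == 0) abort("No sequences to tally")
  if (length(unique(nchar(sequences))) != 1) {
    abort("Sequences must all have the same width")
  }
  cm <- Biostrings::consensusMatrix(Biostrings::DNAStringSet(sequences),
                                    baseOnly = TRUE)
  m <- t(cm[c("A", "C", "G", "T"), , drop = FALSE])  # drops the N/other row
  rownames(m) <- seq_len(nrow(m))
  structure(m, layer = "counts", class = c("motif_matrix", class(m)))
}

#' Information-content transform of a count matrix
#'
#' Per position `i` with column total `n_i > 0`:
#' `p(b,i) = counts(b,i)/n_i`, Shannon entropy
#' `H_i = -sum_b p log2 p` (with `0 log 0 = 0`), and information content
#' `IC(b,i) = p(b,i) * (2 - H_i)` bits. Positions with `n_i = 0` are
#' all-zero. No pseudocounts are added. The transform is invariant to
#' scaling all counts by a positive constant.
#'
#' @param counts A `motif_matrix` with layer `"counts"`.
#' @param layer `"information"` (default) or `"probability"`.
#' @return A `motif_matrix` of the requested layer.
#' @export
information_matrix <- function(counts, layer = c("information", "probability")) {
  layer <- match.arg(layer)
  stopifnot(inherits(counts, "motif_matrix"),
            identical(attr(counts, "layer"), "counts"))
  n <- rowSums(counts)
  p <- counts / ifelse(n > 0, n, 1)
  if (layer == "probability") {
    return(structure(p, layer = "probability",
                     class = c("motif_matrix", "matrix", "array")))
  }
  plogp <- ifelse(p > 0, p * log2(p), 0)
  H <- -rowSums(plogp)
  ic <- p * (2 - H)
  ic[n == 0, ] <- 0
  structure(ic, layer = "information", class = c("motif_matrix", "matrix", "array"))
}

#' Long-format motif table for a splice-site set
#'
#' Positions are signed relative to the splice junction: donors run from
#' `-exonic .. -1` (exon) to `1 .. intronic` (intron); acceptors from
#' `-intronic .. -1` (intron) to `1 .. exonic` (exon).
#'
#' @param sites A `splice_site_set`.
#' @return Tibble `site_type`, `position`, `region`, `base`, `count`,
#'   `probability`, `information_bits`, with class
#'   `splice_motif_tbl` for plotting.
#' @export
motif_table <- function(sites) {
  stopifnot(inherits(sites, "splice_site_set"))
  one <- function(seqs, site_type, left, right, left_region, right_region) {
    if (length(seqs) == 0) return(NULL)
    cnt <- counts_matrix(seqs)
    pr <- information_matrix(cnt, "probability")
    ic <- information_matrix(cnt, "information")
    pos <- c(seq(-left, -1), seq_len(right))
    region <- c(rep(left_region, left), rep(right_region, right))
    purrr::map(c("A", "C", "G", "T"), function(b) {
      tibble(site_type = site_type, position = pos, region = region,
             base = b, count = as.vector(cnt[, b]),
             probability = as.vector(pr[, b]),
             information_bits = as.vector(ic[, b]))
    }) %>% bind_rows() %>% arrange(.data$position, .data$base)
  }
  out <- bind_rows(
    one(sites$donors, "donor", sites$windows$donor[1],
        sites$windows$donor[2], "exon", "intron"),
    one(sites$acceptors, "acceptor", sites$windows$acceptor[1],
        sites$windows$acceptor[2], "intron", "exon")
  )
  class(out) <- c("splice_motif_tbl", class(out))
  out
}

#' @rdname motif_table
#' @param object A `splice_motif_tbl`.
#' @param ... Unused.
#' @export
autoplot.splice_motif_tbl <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = factor(.data$position),
                               y = .data$information_bits,
                               fill = .data$base, label = .data$base)) +
    ggplot2::geom_col(position = "stack", width = 0.8) +
    ggplot2::facet_wrap(~ .data$site_type, ncol = 1, scales = "free_x") +
    ggplot2::labs(x = "position relative to splice junction",
                  y = "information content (bits)", fill = "base") +
    ggplot2::ylim(0, 2) +
    ggplot2::theme_minimal()
}
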