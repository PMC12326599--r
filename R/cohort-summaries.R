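# Downstream statistics on feature-barcode count matrices: total-count
# normalization, per-cell TE fraction, tissue-level TE sets, class
# composition, and one-vs-rest Wilcoxon marker detection.

#' Total-count normalization followed by log1p
#'
#' Each cell is scaled so its total equals the median of per-cell totals
#' (computed over cells with nonzero totals), then transformed with
#' `log(1 + x)`. Zero-total cells are left at zero with a warning. The
#' result is stored as the `normalized` layer of the matrix.
#'
#' @param matrix A `te_count_matrix` of raw integer counts.
#' @param target_sum Override the median target (e.g. `1e4`).
#' @return The matrix with a `normalized` layer.
#' @export
normalize_log1p <- function(matrix, target_sum = NULL) {
  stopifnot(inherits(matrix, "te_count_matrix"))
  totals <- Matrix::colSums(matrix$counts)
  if (any(totals == 0)) {
    warn(paste0(sum(totals == 0), " cell(s) have zero total counts; ",
                "left at zero"))
  }
  if (all(totals == 0)) {
    matrix$normalized <- matrix$counts
    return(matrix)
  }
  target <- target_sum %||% median(totals[totals > 0])
  scale <- ifelse(totals > 0, target / totals, 0)
  norm <- matrix$counts %*% Matrix::Diagonal(x = scale)
  matrix$normalized <- log1p(methods::as(norm, "CsparseMatrix"))
  dimnames(matrix$normalized) <- dimnames(matrix$counts)
  matrix
}

#' Per-cell TE fraction
#'
#' In `features` mode, the fraction of a cell's detected (nonzero)
#' features that are TE-derived; in `umis` mode, the TE share of the
#' cell's UMIs. Cells with zero detected features are excluded from
#' group means and reported.
#'
#' @param matrix A `te_count_matrix`.
#' @param metadata Optional tibble `barcode`, `tissue` (and/or other
#'   labels); when given, per-tissue means are returned too.
#' @param mode `"features"` (default) or `"umis"`.
#' @return List: `per_cell` (tibble `barcode`, `n_detected`,
#'   `fraction`), `group_means` (tibble or NULL), `n_empty_cells`.
#' @export
te_fraction_per_cell <- function(matrix, metadata = NULL,
                                 mode = c("features", "umis")) {
  mode <- match.arg(mode)
  is_te <- matrix$features$is_te
  m <- matrix$counts
  if (mode == "features") {
    nz <- m > 0
    te_part <- Matrix::colSums(nz[is_te, , drop = FALSE])
    total <- Matrix::colSums(nz)
  } else {
    te_part <- Matrix::colSums(m[is_te, , drop = FALSE])
    total <- Matrix::colSums(m)
  }
  per_cell <- tibble(
    barcode = matrix$barcodes,
    n_detected = as.integer(Matrix::colSums(m > 0)),
    fraction = unname(ifelse(total > 0, te_part / total, 0))
  )
  group_means <- NULL
  if (!is.null(metadata)) {
    group_means <- per_cell %>%
      filter(.data$n_detected > 0) %>%
      left_join(metadata, by = "barcode") %>%
      group_by(.data$tissue) %>%
      summarise(mean_te_fraction = mean(.data$fraction), n_cells = n(),
                .groups = "drop")
  }
  list(per_cell = per_cell, group_means = group_means,
       n_empty_cells = sum(per_cell$n_detected == 0))
}

#' Tissue-level TE feature sets and their intersections
#'
#' Per tissue, the TE features whose summed normalized expression over
#' the tissue's cells reaches `threshold`; plus the exact exclusive
#' (UpSet-style) intersection sizes over all tissue combinations.
#'
#' @param matrix A `te_count_matrix` with a `normalized` layer (see
#'   [normalize_log1p()]); set `layer = "counts"` for raw sums.
#' @param metadata Tibble `barcode`, `tissue`.
#' @param threshold Minimum summed expression, default 100.
#' @param layer `"normalized"` (default) or `"counts"`.
#' @return List: `sets` (named list of TE feature-id vectors),
#'   `intersections` (tibble `tissues` (`&`-joined combination), `size`;
#'   an exact partition of the union of all sets).
#' @export
tissue_te_sets <- function(matrix, metadata, threshold = 100,
                           layer = c("normalized", "counts")) {
  layer <- match.arg(layer)
  m <- if (layer == "normalized") matrix$normalized else matrix$counts
  if (is.null(m)) abort("Normalized layer absent; run normalize_log1p()")
  te_ids <- matrix$features$id[matrix$features$is_te]
  tissues <- sort(unique(metadata$tissue))
  sets <- lapply(tissues, function(ts) {
    bcs <- metadata$barcode[metadata$tissue == ts]
    cols <- matrix$barcodes %in% bcs
    if (!any(cols)) return(character(0))
    sums <- Matrix::rowSums(m[, cols, drop = FALSE])
    names(sums) <- matrix$features$id
    intersect(te_ids, names(sums)[sums >= threshold])
  })
  names(sets) <- tissues
  universe <- unique(unlist(sets))
  inter <- if (length(universe) == 0) {
    tibble(tissues = character(), size = integer())
  } else {
    membership <- vapply(sets, function(s) universe %in% s,
                         logical(length(universe)))
    membership <- matrix(membership, nrow = length(universe))
    combo <- apply(membership, 1, function(r) paste(tissues[r], collapse = "&"))
    tibble(tissues = combo) %>% count(.data$tissues, name = "size") %>%
      arrange(desc(.data$size))
  }
  list(sets = sets, intersections = inter)
}

#' Superfamily composition of feature sets
#'
#' @param sets Named list of TE feature-id vectors (e.g. from
#'   [tissue_te_sets()], or significant markers per cell type).
#' @param superfamily_map Named character vector, feature id ->
#'   superfamily. Every feature in `sets` must be mapped.
#' @return Tibble `group`, `superfamily`, `n`, `proportion` (zeros with
#'   `empty = TRUE` for empty groups).
#' @export
class_composition_per_group <- function(sets, superfamily_map) {
  unmapped <- setdiff(unique(unlist(sets)), names(superfamily_map))
  if (length(unmapped) > 0) {
    abort(paste0("TE feature(s) without a superfamily mapping: ",
                 paste(head(unmapped, 10), collapse = ", ")))
  }
  purrr::imap(sets, function(ids, group) {
    base <- tibble(group = group, superfamily = superfamily_tie_order)
    if (length(ids) == 0) {
      return(mutate(base, n = 0L, proportion = 0, empty = TRUE))
    }
    tal <- count(tibble(superfamily = unname(superfamily_map[ids])),
                 .data$superfamily)
    base %>%
      left_join(tal, by = "superfamily") %>%
      mutate(n = if_else(is.na(.data$n), 0L, .data$n),
             proportion = .data$n / sum(.data$n), empty = FALSE)
  }) %>% bind_rows()
}

# Tie-corrected normal-approximation rank-sum z for every row of a dense
# matrix, group vs rest. R1 = rank sum of the group.
rank_sum_z <- function(X, in_group) {
  n1 <- sum(in_group); n2 <- sum(!in_group); n <- n1 + n2
  z <- numeric(nrow(X))
  for (f in seq_len(nrow(X))) {
    x <- X[f, ]
    r <- rank(x)
    R1 <- sum(r[in_group])
    mu <- n1 * (n + 1) / 2
    tie_tbl <- table(x)
    tie_term <- sum(tie_tbl^3 - tie_tbl)
    sigma2 <- (n1 * n2 / 12) * ((n + 1) - tie_term / (n * (n - 1)))
    z[f] <- if (sigma2 <= 0) 0 else (R1 - mu) / sqrt(sigma2)
  }
  z
}

#' One-vs-rest Wilcoxon rank-sum marker detection
#'
#' For each cell type, each feature is tested group-vs-rest with the
#' tie-corrected normal approximation of the Wilcoxon rank-sum test
#' (`z = (R - mu)/sigma` with `mu = n1 (n1 + n2 + 1)/2` and tie-adjusted
#' `sigma`), two-sided p, Benjamini-Hochberg adjustment across features
#' within the cell type. TE-derived features are those whose id contains
#' `"STRG."`; the significant TE subset uses `p_adj < alpha`.
#'
#' @param matrix A `te_count_matrix` with a `normalized` layer.
#' @param metadata Tibble `barcode`, `cell_type`; at least two cell
#'   types.
#' @param alpha Adjusted-p cutoff for the TE subset, default 0.05.
#' @param layer Layer to test, default `"normalized"`.
#' @return A `te_marker_result`: tibble `cell_type`, `feature_id`, `z`,
#'   `p_value`, `p_adj`, `log2_fc` (of expm1 group means), `is_te_derived`,
#'   `significant` (`p_adj < alpha`), with `alpha` as an attribute.
#' @export
rank_te_markers <- function(matrix, metadata, alpha = 0.05,
                            layer = c("normalized", "counts")) {
  layer <- match.arg(layer)
  m <- if (layer == "normalized") matrix$normalized else matrix$counts
  if (is.null(m)) abort("Normalized layer absent; run normalize_log1p()")
  meta <- metadata[match(matrix$barcodes, metadata$barcode), , drop = FALSE]
  if (anyNA(meta$cell_type)) {
    abort("Every barcode in the matrix needs a cell_type label")
  }
  types <- sort(unique(meta$cell_type))
  if (length(types) < 2) abort("Need at least two cell types")
  X <- as.matrix(m)
  res <- purrr::map(types, function(ct) {
    in_group <- meta$cell_type == ct
    if (sum(in_group) < 1 || sum(!in_group) < 1) {
      warn(paste0("Cell type ", ct, " has an empty contrast; skipped"))
      return(NULL)
    }
    z <- rank_sum_z(X, in_group)
    p <- pmin(1, 2 * pnorm(-abs(z)))
    mean_in <- rowMeans(X[, in_group, drop = FALSE])
    mean_out <- rowMeans(X[, !in_group, drop = FALSE])
    tibble(
      cell_type = ct,
      feature_id = matrix$features$id,
      z = z,
      p_value = p,
      p_adj = p.adjust(p, method = "BH"),
      log2_fc = log2((expm1(mean_in) + 1e-9) / (expm1(mean_out) + 1e-9)),
      is_te_derived = grepl("STRG.", matrix$features$id, fixed = TRUE)
    )
  })
  out <- bind_rows(purrr::compact(res)) %>%
    mutate(significant = .data$p_adj < alpha)
  attr(out, "alpha") <- alpha
  class(out) <- c("te_marker_result", class(out))
  out
}

#' Significant TE-derived markers
#'
#' @param markers A `te_marker_result`.
#' @return The rows with a `"STRG."`-containing feature id and adjusted
#'   p below the result's alpha.
#' @export
significant_te_markers <- function(markers) {
  filter(markers, .data$is_te_derived, .data$significant)
}

#' @rdname rank_te_markers
#' @param x A `te_marker_result`.
#' @param ... Unused.
#' @export
glance.te_marker_result <- function(x, ...) {
  x %>%
    group_by(.data$cell_type) %>%
    summarise(n_tested = n(),
              n_significant = sum(.data$significant),
              n_te_significant = sum(.data$significant & .data$is_te_derived),
              .groups = "drop")
}

#' @rdname rank_te_markers
#' @param object A `te_marker_result`.
#' @export
autoplot.te_marker_result <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$log2_fc,
                               y = -log10(pmax(.data$p_adj, 1e-300)),
                               colour = .data$significant & .data$is_te_derived)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::facet_wrap(~ .data$cell_type) +
    ggplot2::labs(x = "log2 fold change", y = "-log10 adjusted p",
                  colour = "significant TE") +
    ggplot2::theme_minimal()
}
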