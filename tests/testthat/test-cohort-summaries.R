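small_matrix <- function(counts, te_flags = NULL, barcodes = NULL) {
  nf <- nrow(counts)
  if (is.null(te_flags)) te_flags <- rep(FALSE, nf)
  ids <- ifelse(te_flags, paste0("STRG.", seq_len(nf)), paste0("F", seq_len(nf)))
  if (is.null(barcodes)) barcodes <- paste0("BC", seq_len(ncol(counts)))
  te_count_matrix(
    Matrix::Matrix(counts, sparse = TRUE),
    tibble::tibble(id = ids, name = ids, kind = "gene", is_te = te_flags),
    barcodes)
}

test_that("normalization scales to the median total then log1p", {
  counts <- cbind(c(4, 6, 0), c(10, 20, 0))   # totals 10 and 30, median 20
  m <- normalize_log1p(small_matrix(counts))
  expect_equal(as.matrix(m$normalized)[, 1], log1p(c(4, 6, 0) * 2),
               ignore_attr = TRUE)
  expect_equal(as.matrix(m$normalized)[, 2], log1p(c(10, 20, 0) * 2 / 3),
               ignore_attr = TRUE)
  # single cell: scale factor 1 (median = own total)
  m1 <- normalize_log1p(small_matrix(cbind(c(3, 5, 0))))
  expect_equal(as.matrix(m1$normalized)[, 1], log1p(c(3, 5, 0)),
               ignore_attr = TRUE)
  expect_warning(mz <- normalize_log1p(small_matrix(cbind(c(0, 0), c(1, 1)))),
                 "zero total")
  expect_equal(as.matrix(mz$normalized)[, 1], c(0, 0), ignore_attr = TRUE)
})

test_that("per-cell TE fraction counts features or UMIs as requested", {
  counts <- rbind(matrix(1, nrow = 8, ncol = 1), c(3), c(5),
                  matrix(0, nrow = 2, ncol = 1))
  m <- small_matrix(counts, te_flags = c(rep(FALSE, 8), TRUE, TRUE,
                                         FALSE, FALSE))
  fr <- te_fraction_per_cell(m)
  expect_equal(fr$per_cell$fraction, 2 / 10)     # 2 TE of 10 detected
  fu <- te_fraction_per_cell(m, mode = "umis")
  expect_equal(fu$per_cell$fraction, 8 / 16)
  # always within [0,1], empty cells excluded from group means
  set.seed(5)
  counts2 <- matrix(rpois(60, 1), nrow = 6)
  counts2[, 1] <- 0
  m2 <- small_matrix(counts2, te_flags = c(TRUE, rep(FALSE, 5)))
  meta <- tibble::tibble(barcode = m2$barcodes,
                         tissue = rep(c("a", "b"), 5))
  fr2 <- te_fraction_per_cell(m2, meta)
  expect_true(all(fr2$per_cell$fraction >= 0 & fr2$per_cell$fraction <= 1))
  expect_equal(fr2$n_empty_cells, 1)
  expect_equal(sum(fr2$group_means$n_cells), 9)
  # per-cell loop oracle
  want <- vapply(seq_len(10), function(j) {
    nz <- counts2[, j] > 0
    if (!any(nz)) 0 else sum(nz & c(TRUE, rep(FALSE, 5))) / sum(nz)
  }, numeric(1))
  expect_equal(fr2$per_cell$fraction, want)
})

test_that("tissue TE sets threshold summed expression and partition exactly", {
  counts <- rbind(c(60, 95, 20, 30),    # STRG.1
                  c(60, 60, 60, 60),    # STRG.2
                  c(5, 5, 120, 100),    # STRG.3
                  c(9, 9, 9, 9))        # F4 (not TE)
  m <- small_matrix(counts, te_flags = c(TRUE, TRUE, TRUE, FALSE))
  m$normalized <- m$counts   # use raw values as the normalized layer
  meta <- tibble::tibble(barcode = m$barcodes,
                         tissue = c("A", "A", "B", "B"))
  out <- tissue_te_sets(m, meta, threshold = 100)
  expect_setequal(out$sets$A, c("STRG.1", "STRG.2"))
  expect_setequal(out$sets$B, c("STRG.2", "STRG.3"))
  expect_equal(out$intersections$size[out$intersections$tissues == "A&B"], 1L)
  # exact partition: exclusive sizes sum to the union
  expect_equal(sum(out$intersections$size),
               length(unique(unlist(out$sets))))
  # threshold 0 admits every expressed TE everywhere
  out0 <- tissue_te_sets(m, meta, threshold = 0)
  expect_setequal(out0$sets$A, c("STRG.1", "STRG.2", "STRG.3"))
})

test_that("tissue set intersections match a brute-force power-set oracle", {
  set.seed(13)
  counts <- matrix(rpois(20 * 12, 3), nrow = 20)
  m <- small_matrix(counts, te_flags = rep(c(TRUE, FALSE), 10))
  m$normalized <- m$counts
  meta <- tibble::tibble(barcode = m$barcodes,
                         tissue = rep(c("x", "y", "z"), each = 4))
  out <- tissue_te_sets(m, meta, threshold = 12)
  sets <- out$sets
  universe <- unique(unlist(sets))
  combos <- table(vapply(universe, function(f) {
    paste(names(sets)[vapply(sets, function(s) f %in% s, logical(1))],
          collapse = "&")
  }, character(1)))
  got <- setNames(out$intersections$size, out$intersections$tissues)
  expect_setequal(names(got), names(combos))
  expect_equal(unname(got[names(combos)]), unname(as.integer(combos)))
})

test_that("class composition tallies superfamilies and catches unmapped features", {
  sets <- list(g1 = c("t1", "t2", "t3", "t4", "t5"), g2 = character(0))
  map <- c(t1 = "LINE", t2 = "LINE", t3 = "LINE", t4 = "LINE", t5 = "SINE")
  cc <- class_composition_per_group(sets, map)
  expect_equal(cc$proportion[cc$group == "g1" & cc$superfamily == "LINE"], 0.8)
  expect_equal(sum(cc$proportion[cc$group == "g1"]), 1)
  expect_true(all(cc$empty[cc$group == "g2"]))
  expect_true(all(cc$n[cc$group == "g2"] == 0))
  expect_error(class_composition_per_group(list(g = "unknown"), map),
               "unknown")
})

test_that("rank-sum z and p agree with the stats::wilcox.test oracle", {
  set.seed(17)
  sim <- simulate_expression_matrix(n_cells = c(A = 15, B = 25),
                                    n_nonte = 10, n_te = 3,
                                    te_background_mean = 2, seed = 17)
  m <- normalize_log1p(sim$matrix)
  mk <- rank_te_markers(m, sim$metadata)
  X <- as.matrix(m$normalized)
  in_a <- sim$metadata$cell_type == "A"
  for (f in seq_len(nrow(X))) {
    ref_p <- stats::wilcox.test(X[f, in_a], X[f, !in_a], exact = FALSE,
                                correct = FALSE)$p.value
    got_p <- mk$p_value[mk$cell_type == "A" &
                          mk$feature_id == m$features$id[f]]
    expect_equal(got_p, ref_p, tolerance = 1e-12)
  }
})

test_that("BH adjustment is monotone and bounded below by raw p", {
  sim <- simulate_expression_matrix(
    n_cells = c(A = 20, B = 30),
    planted = tibble::tibble(cell_type = "A", feature = "STRG.1_AluY",
                             mean = 15),
    te_background_mean = 0, seed = 2)
  m <- normalize_log1p(sim$matrix)
  mk <- rank_te_markers(m, sim$metadata)
  for (ct in unique(mk$cell_type)) {
    sub <- dplyr::arrange(mk[mk$cell_type == ct, ], p_value)
    expect_true(all(sub$p_adj >= sub$p_value - 1e-15))
    expect_true(all(diff(sub$p_adj) >= -1e-15))
    expect_true(all(sub$p_adj >= 0 & sub$p_adj <= 1))
  }
  te_sub <- significant_te_markers(mk)
  expect_true(all(grepl("STRG.", te_sub$feature_id, fixed = TRUE)))
  expect_true("STRG.1_AluY" %in% te_sub$feature_id[te_sub$cell_type == "A"])
  # no STRG features -> empty TE subset
  noTE <- simulate_expression_matrix(n_cells = c(A = 10, B = 10), n_te = 0,
                                     seed = 3)
  mk2 <- rank_te_markers(normalize_log1p(noTE$matrix), noTE$metadata)
  expect_equal(nrow(significant_te_markers(mk2)), 0L)
  expect_error(rank_te_markers(m, dplyr::mutate(sim$metadata,
                                                cell_type = "one")),
               "two cell types")
})

test_that("label permutations keep significant counts near the calibration bound", {
  sim <- simulate_expression_matrix(n_cells = c(A = 30, B = 30),
                                    n_nonte = 12, n_te = 4,
                                    te_background_mean = 5, seed = 19)
  m <- normalize_log1p(sim$matrix)
  set.seed(19)
  n_sig <- vapply(1:20, function(i) {
    meta <- sim$metadata
    meta$cell_type <- sample(meta$cell_type)
    sum(rank_te_markers(m, meta)$significant)
  }, numeric(1))
  alpha <- 0.05
  expect_lte(mean(n_sig), alpha * 16 * 2 * 1.5)
})
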