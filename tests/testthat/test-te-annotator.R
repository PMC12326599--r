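toy_repeats <- function(rows) {
  # rows: list of c(subfamily, superfamily, start, end)
  tibble::tibble(
    chrom = "chr1",
    start = vapply(rows, function(r) as.integer(r[[3]]), integer(1)),
    end = vapply(rows, function(r) as.integer(r[[4]]), integer(1)),
    strand = "+",
    subfamily = vapply(rows, `[[`, character(1), 1),
    family = "fam",
    superfamily = vapply(rows, `[[`, character(1), 2),
    element_id = paste0("e", seq_along(rows)),
    genic_context = "unset")
}

toy_tx <- function(starts, ends, id = "T1", strand = "+") {
  tibble::tibble(transcript_id = id, gene_id = id, chrom = "chr1",
                 start = as.integer(starts), end = as.integer(ends),
                 strand = strand)
}

test_that("te_composition measures exon-wise overlap against a per-base oracle", {
  reps <- toy_repeats(list(list("AluY", "SINE", 0, 60),
                           list("L1PA3", "LINE", 50, 100)))
  comp <- te_composition(toy_tx(0, 100), reps)
  expect_equal(comp$subfamily, c("AluY", "L1PA3"))
  expect_equal(comp$overlap_bp, c(60L, 50L))
  expect_equal(comp$overlap_pct, c(60, 50))
  # per-base oracle on the 100 bp toy
  base_cov <- function(s, e) sum(seq(1, 100) > s & seq(1, 100) <= e)
  expect_equal(comp$overlap_bp[1], base_cov(0, 60))
  expect_equal(comp$overlap_bp[2], base_cov(50, 100))
})

test_that("intronic repeats contribute nothing and same-subfamily copies merge", {
  reps <- toy_repeats(list(list("AluY", "SINE", 50, 100)))
  comp <- te_composition(toy_tx(c(0, 100), c(50, 150)), reps)
  expect_equal(nrow(comp), 0L)
  # two AluY copies 30 + 20 bp -> one entry with 50 bp
  reps2 <- toy_repeats(list(list("AluY", "SINE", 0, 30),
                            list("AluY", "SINE", 60, 80)))
  comp2 <- te_composition(toy_tx(0, 100), reps2)
  expect_equal(nrow(comp2), 1L)
  expect_equal(comp2$overlap_bp, 50L)
  # overlapping copies of one subfamily never double count shared bases
  reps3 <- toy_repeats(list(list("AluY", "SINE", 0, 30),
                            list("AluY", "SINE", 20, 50)))
  expect_equal(te_composition(toy_tx(0, 100), reps3)$overlap_bp, 50L)
})

test_that("display names follow composition order with sanitization and tie rules", {
  comp <- tibble::tibble(subfamily = c("AluY", "L1PA3"),
                         superfamily = c("SINE", "LINE"),
                         overlap_bp = c(60L, 50L), overlap_pct = c(60, 50))
  expect_equal(name_transcript("STRG.1", comp), "STRG.1_AluY_L1PA3")
  herv <- tibble::tibble(subfamily = "HERVH-int", superfamily = "LTR",
                         overlap_bp = 90L, overlap_pct = 90)
  expect_equal(name_transcript("STRG.2", herv), "STRG.2_HERVH-int")
  weird <- tibble::tibble(subfamily = "SVA_D", superfamily = "Retroposon",
                          overlap_bp = 10L, overlap_pct = 10)
  expect_equal(name_transcript("STRG.3", weird), "STRG.3_SVA-D")
  expect_error(name_transcript("STRG.4", comp[0, ]), "empty")
  # equal percentages: alphabetical tie-break comes from te_composition
  reps <- toy_repeats(list(list("AluY", "SINE", 0, 50),
                           list("AluSz", "SINE", 50, 100)))
  comp_tie <- te_composition(toy_tx(0, 100), reps)
  expect_equal(comp_tie$subfamily, c("AluSz", "AluY"))
})

test_that("superfamily assignment maximizes summed overlap with fixed tie order", {
  mk <- function(sf, bp) tibble::tibble(subfamily = paste0("s", seq_along(sf)),
                                        superfamily = sf, overlap_bp = bp,
                                        overlap_pct = bp)
  expect_equal(assign_superfamily(mk(c("SINE", "LINE"), c(60L, 50L))), "SINE")
  expect_equal(assign_superfamily(mk("LTR", 90L)), "LTR")
  expect_equal(assign_superfamily(mk(c("LINE", "SINE"), c(50L, 50L))), "LINE")
  expect_equal(assign_superfamily(mk("RC", 10L)), "DNA")
  # summed across subfamilies of one class
  expect_equal(assign_superfamily(mk(c("SINE", "LINE", "LINE"),
                                     c(60L, 40L, 30L))), "LINE")
  expect_error(assign_superfamily(mk(character(0), integer(0))), "empty")
})

test_that("transcript metrics report mature length, span and strand-aware TES", {
  m <- transcript_metrics(toy_tx(c(10, 30), c(20, 40)))
  expect_equal(m$mature_length, 20L)
  expect_equal(m$genomic_span, 30L)
  expect_equal(m$tes_coordinate, 40L)
  m2 <- transcript_metrics(toy_tx(c(10, 30), c(20, 40), strand = "-"))
  expect_equal(m2$tes_coordinate, 11L)   # 1-based first-exon start
  # mature length equals a per-base exon rasterization
  ref <- cached_ref()
  tx <- ref$assembled[ref$assembled$transcript_id ==
                        ref$assembled$transcript_id[1], ]
  cov <- rep(FALSE, max(tx$end))
  for (i in seq_len(nrow(tx))) cov[seq(tx$start[i] + 1, tx$end[i])] <- TRUE
  expect_equal(transcript_metrics(tx)$mature_length, sum(cov))
})

test_that("guide annotation adds one single-exon model per repeat and round trips", {
  ref <- cached_ref()
  guide <- build_guide_annotation(ref$genes, ref$repeats, ref$sizes)
  expect_equal(nrow(guide), nrow(ref$genes) + nrow(ref$repeats))
  expect_setequal(unique(guide$source_kind), c("nonTE_gene", "TE_derived"))
  path <- withr::local_tempfile(fileext = ".gtf")
  write_gtf(guide, path)
  back <- read_gtf(path)
  expect_equal(nrow(back), nrow(guide))
  expect_equal(back$start, guide$start)
  bad <- ref$repeats[1, ]
  bad$chrom <- "chrUn_random"
  expect_error(build_guide_annotation(ref$genes, bad, ref$sizes), "absent")
})

test_that("annotation summary counts genes, isoforms and superfamilies", {
  anno <- tibble::tibble(
    gene_id = c("STRG.1", "STRG.2", "STRG.3", "STRG.3", "STRG.3"),
    transcript_id = paste0("t", 1:5),
    superfamily = c("SINE", "SINE", "LINE", "LINE", "LTR"))
  s <- summarize_annotation(anno)
  expect_equal(s$n_genes, 3L)
  expect_equal(s$isoform_histogram,
               tibble::tibble(n_isoforms = c(1L, 3L), n_genes = c(2L, 1L)))
  expect_equal(sum(s$isoform_histogram$n_genes), s$n_genes)
  expect_equal(sum(s$superfamilies$proportion), 1, tolerance = 1e-9)
  expect_equal(s$superfamilies$n[s$superfamilies$superfamily == "SINE"], 2L)
  # permutation invariance
  s2 <- summarize_annotation(anno[sample(5), ])
  expect_equal(s2$superfamilies, s$superfamilies)
  expect_equal(s2$isoform_histogram, s$isoform_histogram)
  # all-SINE toy
  s3 <- summarize_annotation(dplyr::mutate(anno, superfamily = "SINE"))
  expect_equal(s3$superfamilies$proportion[s3$superfamilies$superfamily == "SINE"],
               1)
})

test_that("annotate_te_transcripts drops TE-free transcripts and keeps composition totals consistent", {
  ref <- cached_ref()
  masks <- cached_masks()
  mixed <- dplyr::bind_rows(ref$assembled, ref$genes[ref$genes$gene_id == "G4", ])
  anno <- annotate_te_transcripts(mixed, ref$repeats)
  expect_setequal(anno$transcript_id, unique(ref$assembled$transcript_id))
  expect_false("G4.t1" %in% anno$transcript_id)  # clean gene is not TE-derived
  # sum of composition bp >= exonic overlap with the TE_all mask
  for (i in seq_len(min(5, nrow(anno)))) {
    ex <- attr(anno, "exons")
    ex <- ex[ex$transcript_id == anno$transcript_id[i], ]
    mask_bp <- overlap_bp(ex[, c("chrom", "start", "end")], masks$TE_all)
    expect_gte(sum(anno$composition[[i]]$overlap_bp), mask_bp)
  }
  expect_true(all(vapply(anno$composition, nrow, integer(1)) > 0))
})
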