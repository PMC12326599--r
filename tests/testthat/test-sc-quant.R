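sc_exons <- function(tx, gene, start, end, kind, chrom = "chrQ") {
  tibble::tibble(transcript_id = tx, gene_id = gene, chrom = chrom,
                 start = as.integer(start), end = as.integer(end),
                 strand = "+", source_kind = kind)
}

test_that("reconcile_annotations removes exon-overlapping TE transcripts only", {
  gene <- sc_exons("G1.t1", "G1", 150, 250, "nonTE_gene")
  te_hit <- sc_exons("STRG.1.1", "STRG.1", 100, 200, "TE_derived")
  te_intronic <- dplyr::bind_rows(
    sc_exons("STRG.2.1", "STRG.2", 300, 350, "TE_derived"))
  rec <- reconcile_annotations(dplyr::bind_rows(te_hit, te_intronic), gene)
  expect_equal(rec$removed_transcripts, "STRG.1.1")
  expect_setequal(unique(rec$merged$transcript_id), c("G1.t1", "STRG.2.1"))
  # TE transcript inside a gene intron only is retained (exon-level rule)
  gene2 <- dplyr::bind_rows(sc_exons("G2.t1", "G2", c(0, 500), c(100, 600),
                                     "nonTE_gene"))
  te_in_intron <- sc_exons("STRG.3.1", "STRG.3", 200, 300, "TE_derived")
  rec2 <- reconcile_annotations(te_in_intron, gene2)
  expect_equal(rec2$removed_transcripts, character(0))
})

test_that("reconcile_annotations matches a brute-force all-pairs filter and is monotone", {
  set.seed(21)
  mk_tx <- function(i, kind, prefix) {
    s <- sample(0:2000, 1)
    sc_exons(paste0(prefix, i, ".1"), paste0(prefix, i), s,
             s + sample(50:200, 1), kind)
  }
  te <- dplyr::bind_rows(lapply(1:30, mk_tx, kind = "TE_derived",
                                prefix = "STRG."))
  genes <- dplyr::bind_rows(lapply(1:20, mk_tx, kind = "nonTE_gene",
                                   prefix = "G"))
  rec <- reconcile_annotations(te, genes)
  want_removed <- unique(unlist(lapply(seq_len(nrow(te)), function(i) {
    for (j in seq_len(nrow(genes))) {
      if (max(te$start[i], genes$start[j]) < min(te$end[i], genes$end[j])) {
        return(te$transcript_id[i])
      }
    }
    NULL
  })))
  if (is.null(want_removed)) want_removed <- character(0)
  expect_setequal(rec$removed_transcripts, want_removed)
  # adding a gene can only shrink the survivor set
  extra <- sc_exons("G99.t1", "G99", 0, 2300, "nonTE_gene")
  rec_more <- reconcile_annotations(te, dplyr::bind_rows(genes, extra))
  survivors <- function(r) setdiff(unique(te$transcript_id),
                                   r$removed_transcripts)
  expect_true(all(survivors(rec_more) %in% survivors(rec)))
})

test_that("assign_read gives genes priority over TEs and flags ambiguity", {
  merged <- dplyr::bind_rows(
    sc_exons("G1.t1", "G1", 100, 200, "nonTE_gene"),
    sc_exons("G2.t1", "G2", 180, 260, "nonTE_gene"),
    sc_exons("STRG.1.1", "STRG.1", 150, 250, "TE_derived"),
    sc_exons("STRG.2.1", "STRG.2", 400, 500, "TE_derived"),
    sc_exons("STRG.2.2", "STRG.2", c(400, 520), c(500, 560), "TE_derived"))
  reps <- tibble::tibble(chrom = "chrQ", start = 390L, end = 510L,
                         strand = "+", subfamily = "AluY", family = "Alu",
                         superfamily = "SINE", element_id = "AluY|chrQ|390|510",
                         genic_context = "unset")
  idx <- feature_index(merged, reps)
  # TE-only region
  a <- assign_read(toy_blocks(410, 470, "chrQ"), idx)
  expect_equal(a$status, "assigned")
  expect_equal(a$gene_id, "STRG.2")
  expect_true(is.na(a$transcript_id))     # equal overlap of both isoforms
  expect_equal(a$repeat_ids, "AluY|chrQ|390|510")
  # isoform-distinctive block
  a2 <- assign_read(toy_blocks(530, 560, "chrQ"), idx)
  expect_equal(a2$transcript_id, "STRG.2.2")
  # shared TE/gene region goes to the gene
  a3 <- assign_read(toy_blocks(150, 180, "chrQ"), idx)
  expect_equal(a3$gene_id, "G1")
  # two nonTE genes with equal exon overlap: ambiguous
  a4 <- assign_read(toy_blocks(170, 210, "chrQ"), idx)
  expect_equal(a4$status, "ambiguous")
  # nothing there
  a5 <- assign_read(toy_blocks(700, 750, "chrQ"), idx)
  expect_equal(a5$status, "no_feature")
})

test_that("UMI deduplication collapses molecules, not reads", {
  merged <- sc_exons("G1.t1", "G1", 100, 300, "nonTE_gene")
  sizes <- c(chrQ = 1000L)
  mk_read <- function(id, umi, cb = "AAAACCCC") {
    tibble::tibble(read_id = id, chrom = "chrQ", pos = 120L, flag = 0L,
                   mapq = 60L, cigar = "50M",
                   tags = paste0("CB:Z:", cb, "\tUB:Z:", umi))
  }
  sam <- withr::local_tempfile(fileext = ".sam")
  telokit:::write_sam(dplyr::bind_rows(
    mk_read("a1", "TTTT"), mk_read("a2", "TTTT"),   # same molecule
    mk_read("b1", "GGGG"),                           # second molecule
    mk_read("c1", "CCCC", cb = "AAAAGGGG")), sizes, sam)
  q <- quantify_cells(sam, merged)
  m <- as.matrix(q$matrix$counts)
  expect_equal(m["G1", "AAAACCCC"], 2)    # two distinct UMIs
  expect_equal(m["G1.t1", "AAAACCCC"], 2)
  expect_equal(m["G1", "AAAAGGGG"], 1)
  expect_equal(q$stats$assigned, 4)
})

test_that("duplicating every record leaves the matrix unchanged (UMI idempotence)", {
  ref <- cached_ref()
  sim <- simulate_barcoded_reads(
    ref, n_cells = c(TypeA = 4, TypeB = 4),
    planted_markers = tibble::tibble(cell_type = "TypeA", feature = "STRG.1",
                                     mean = 5),
    background_mean_gene = 1, seed = 4, out_sam = NULL)
  sam1 <- withr::local_tempfile(fileext = ".sam")
  sam2 <- withr::local_tempfile(fileext = ".sam")
  telokit:::write_sam(sim$reads, ref$sizes, sam1)
  doubled <- dplyr::bind_rows(sim$reads, dplyr::mutate(
    sim$reads, read_id = paste0(read_id, "_dup")))
  telokit:::write_sam(doubled, ref$sizes, sam2)
  q1 <- quantify_cells(sam1, sim$merged, ref$repeats,
                       barcode_whitelist = sim$metadata$barcode)
  q2 <- quantify_cells(sam2, sim$merged, ref$repeats,
                       barcode_whitelist = sim$metadata$barcode)
  expect_equal(as.matrix(q1$matrix$counts), as.matrix(q2$matrix$counts))
  expect_equal(as.matrix(q1$repeat_matrix$counts),
               as.matrix(q2$repeat_matrix$counts))
})

test_that("record bookkeeping is a partition and whitelisting drops other barcodes", {
  merged <- sc_exons("G1.t1", "G1", 100, 300, "nonTE_gene")
  sizes <- c(chrQ = 1000L)
  reads <- tibble::tibble(
    read_id = c("ok", "lowq", "notag", "other_bc", "nowhere"),
    chrom = "chrQ", pos = c(120L, 120L, 120L, 120L, 700L),
    flag = 0L, mapq = c(60L, 5L, 60L, 60L, 60L), cigar = "50M",
    tags = c("CB:Z:AAAA\tUB:Z:TTTT", "CB:Z:AAAA\tUB:Z:TATA", "",
             "CB:Z:CCCC\tUB:Z:TTTT", "CB:Z:AAAA\tUB:Z:GGGG"))
  sam <- withr::local_tempfile(fileext = ".sam")
  telokit:::write_sam(reads, sizes, sam)
  q <- quantify_cells(sam, merged, barcode_whitelist = "AAAA")
  s <- q$stats
  expect_equal(s$total_records, 5)
  expect_equal(s$filtered + s$no_tag + s$not_whitelisted + s$no_feature +
                 s$ambiguous + s$assigned, s$total_records)
  expect_equal(s$not_whitelisted, 1)
  expect_equal(s$no_tag, 1)
  expect_equal(s$filtered, 1)
  expect_equal(q$matrix$barcodes, "AAAA")
})

test_that("matrix directories round trip exactly and features keep their layers", {
  set.seed(31)
  feats <- tibble::tibble(
    id = c("G1", "G1.t1", "STRG.1", "STRG.1.1", "AluY|chr1|5|10"),
    name = c("G1", "G1.t1", "STRG.1", "STRG.1.1", "AluY"),
    kind = c("gene", "isoform", "gene", "isoform", "repeat_element"),
    is_te = c(FALSE, FALSE, TRUE, TRUE, TRUE))
  m <- Matrix::sparseMatrix(i = c(1, 3, 5), j = c(1, 2, 3), x = c(2, 1, 7),
                            dims = c(5, 3))
  cm <- te_count_matrix(m, feats, c("BC1", "BC2", "BC3"))
  dir <- withr::local_tempdir()
  write_matrix(cm, dir)
  back <- read_matrix(dir)
  expect_equal(as.matrix(back$counts), as.matrix(cm$counts))
  expect_equal(back$features, cm$features)
  expect_equal(back$barcodes, cm$barcodes)
  # a TE-flagged feature never carries a nonTE id and vice versa
  expect_false(any(back$features$is_te & grepl("^G\\d", back$features$id)))
  tl <- tidy(cm)
  expect_equal(sum(tl$value), 10)
  expect_error(te_count_matrix(m, feats[c(1, 1, 2, 3, 4), ], c("a", "b", "c")),
               "unique")
})
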