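# Self-consistent toy fixtures with known truth: a genome with GT..AG
# introns, a RepeatMasker-style TE annotation, a gene annotation, long
# reads engineered one per classification category, and barcoded
# single-cell reads with planted cell-type markers.
#
# Layout: each chromosome is divided into 2 kb tiles. Gene tiles hold a
# two-exon gene (types cycle: a gene whose first exon is 80% covered by
# a TE, a gene with an intronic TE, a fusion gene with an upstream
# intergenic TE in the same tile, and a clean gene). TE tiles hold up to
# three intergenic elements; the first slot of each TE tile is a fixed
# 600 bp element that can host assembled TE-transcript models.

TILE <- 2000L

sim_subfamily_pool <- list(
  LINE = c("L1PA3", "L1HS", "L2a"),
  SINE = c("AluY", "AluSz", "MIRb"),
  LTR = c("HERVH-int", "LTR7", "MLT1B"),
  DNA = c("MER20", "Charlie1a"),
  Retroposon = c("SVA_D", "SVA_B")
)
sim_family_of <- c(LINE = "L1", SINE = "Alu", LTR = "ERV1",
                   DNA = "hAT-Charlie", Retroposon = "SVA")

int2dna <- function(i, width) {
  bases <- c("A", "C", "G", "T")
  out <- character(width)
  for (k in seq_len(width)) {
    out[k] <- bases[(i %% 4) + 1]
    i <- i %/% 4
  }
  paste(rev(out), collapse = "")
}

patch_splice_dinucleotides <- function(seqs, introns) {
  # forward-strand patches so every intron is canonical GT..AG in
  # transcript orientation
  for (i in seq_len(nrow(introns))) {
    chr <- introns$chrom[i]
    s <- introns$istart[i]; e <- introns$iend[i]
    if (introns$strand[i] == "-") {
      substr(seqs[[chr]], s + 1, s + 2) <- "CT"
      substr(seqs[[chr]], e - 1, e) <- "AC"
    } else {
      substr(seqs[[chr]], s + 1, s + 2) <- "GT"
      substr(seqs[[chr]], e - 1, e) <- "AG"
    }
  }
  seqs
}

#' Simulate a toy reference: genome, repeats, genes, assembled models
#'
#' Generates a deterministic (seeded) reference triplet — FASTA genome,
#' RepeatMasker-style TE table, gene annotation — plus a set of
#' "assembled" TE-transcript models (STRG genes over dedicated
#' intergenic elements) and a truth table for every placement. All gene
#' and TE-transcript introns carry canonical GT..AG dinucleotides in
#' transcript orientation.
#'
#' @param seed RNG seed; identical seeds give byte-identical outputs.
#' @param n_chroms,chrom_len Genome shape (default 2 x 100 kb).
#' @param n_genes Total genes (split across chromosomes).
#' @param n_te Total TE copies to place (gene-linked placements count).
#' @param te_class_mix Named class proportions (must sum to 1).
#' @param n_strg Number of assembled STRG gene models.
#' @param out_dir If non-NULL, writes `genome.fa`, `rmsk.tsv` (ucsc_table
#'   dialect, including two non-TE decoy rows per chromosome),
#'   `genes.gtf`, `assembled.gtf` and `truth_repeats.tsv` there.
#' @return List: `genome` (DNAStringSet), `sizes`, `genes` (exon
#'   tibble), `repeats` (TE-only tibble), `assembled` (exon tibble of
#'   STRG models), `truth` (list with `te_roles`, `gene_types`, `seed`),
#'   `files`.
#' @export
simulate_reference <- function(seed = 1, n_chroms = 2, chrom_len = 100000,
                               n_genes = 20, n_te = 200,
                               te_class_mix = c(LINE = 0.3, SINE = 0.3,
                                                LTR = 0.2, DNA = 0.1,
                                                Retroposon = 0.1),
                               n_strg = 12, out_dir = NULL) {
  stopifnot(abs(sum(te_class_mix) - 1) < 1e-8)
  set.seed(seed)
  chroms <- paste0("chrS", seq_len(n_chroms))
  sizes <- setNames(rep(as.integer(chrom_len), n_chroms), chroms)
  n_tiles <- chrom_len %/% TILE
  draw_te_identity <- function() {
    cls <- sample(names(te_class_mix), 1, prob = te_class_mix)
    list(class = cls, subfamily = sample(sim_subfamily_pool[[cls]], 1))
  }

  gene_rows <- list(); te_rows <- list(); gene_quota <- n_genes
  te_quota <- n_te
  gene_types_cycle <- c("exonic_te", "intronic_te", "fusion", "clean")
  gi <- 0L
  for (ci in seq_along(chroms)) {
    chr <- chroms[ci]
    for (ti in seq_len(n_tiles)) {
      t0 <- (ti - 1L) * TILE
      is_gene_tile <- ti %% 2 == 1
      if (is_gene_tile && gene_quota > 0) {
        gi <- gi + 1L; gene_quota <- gene_quota - 1L
        type <- gene_types_cycle[(gi - 1L) %% 4L + 1L]
        strand <- if (gi %% 2 == 0) "-" else "+"
        gid <- paste0("G", gi)
        if (type == "fusion") {
          ex <- tibble(start = t0 + c(800L, 1500L), end = t0 + c(1100L, 1800L))
          if (te_quota > 0) {
            id <- draw_te_identity()
            te_rows[[length(te_rows) + 1]] <- tibble(
              chrom = chr, start = t0 + 100L, end = t0 + 300L,
              strand = "+", subfamily = id$subfamily, class = id$class,
              role = "fusion_te", linked_gene = gid)
            te_quota <- te_quota - 1L
          }
        } else {
          ex <- tibble(start = t0 + c(200L, 900L), end = t0 + c(500L, 1200L))
          if (type == "exonic_te" && te_quota > 0) {
            id <- draw_te_identity()
            te_rows[[length(te_rows) + 1]] <- tibble(
              chrom = chr, start = t0 + 230L, end = t0 + 470L,
              strand = "+", subfamily = id$subfamily, class = id$class,
              role = "exonic", linked_gene = gid)
            te_quota <- te_quota - 1L
          } else if (type == "intronic_te" && te_quota > 0) {
            id <- draw_te_identity()
            te_rows[[length(te_rows) + 1]] <- tibble(
              chrom = chr, start = t0 + 550L, end = t0 + 750L,
              strand = "+", subfamily = id$subfamily, class = id$class,
              role = "intronic", linked_gene = gid)
            te_quota <- te_quota - 1L
          }
        }
        gene_rows[[length(gene_rows) + 1]] <- tibble(
          transcript_id = paste0(gid, ".t1"), gene_id = gid, chrom = chr,
          start = ex$start, end = ex$end, strand = strand,
          source_kind = "nonTE_gene", gene_type = type)
      } else if (te_quota > 0) {
        offs <- c(100L, 700L, 1300L)
        lens <- c(600L, sample(150:400, 2, replace = TRUE))
        for (k in seq_len(3)) {
          if (te_quota == 0) break
          id <- draw_te_identity()
          te_rows[[length(te_rows) + 1]] <- tibble(
            chrom = chr, start = t0 + offs[k], end = t0 + offs[k] + lens[k],
            strand = sample(c("+", "-"), 1), subfamily = id$subfamily,
            class = id$class, role = if (k == 1) "slot" else "free",
            linked_gene = NA_character_)
          te_quota <- te_quota - 1L
        }
      }
    }
  }
  if (gene_quota > 0 || te_quota > 0) {
    abort(paste0("Infeasible placement: ", gene_quota, " gene(s) and ",
                 te_quota, " TE(s) did not fit; enlarge the genome"))
  }
  genes <- bind_rows(gene_rows)
  te_truth <- bind_rows(te_rows) %>%
    mutate(element_id = paste(.data$subfamily, .data$chrom, .data$start,
                              .data$end, sep = "|"),
           genic_context_truth = if_else(.data$role %in% c("exonic", "intronic"),
                                         "intragenic", "intergenic"))
  repeats <- tibble(
    chrom = te_truth$chrom, start = te_truth$start, end = te_truth$end,
    strand = te_truth$strand, subfamily = te_truth$subfamily,
    family = unname(sim_family_of[te_truth$class]),
    superfamily = te_truth$class, element_id = te_truth$element_id,
    genic_context = "unset")

  # assembled STRG transcript models over 'slot' elements
  slots <- filter(te_truth, .data$role == "slot")
  if (missing(n_strg)) n_strg <- min(n_strg, nrow(slots))
  if (n_strg > nrow(slots)) {
    abort(paste0("n_strg = ", n_strg, " exceeds available slot elements (",
                 nrow(slots), ")"))
  }
  iso_cycle <- c(1L, 1L, 1L, 2L, 1L, 1L, 1L, 1L, 1L, 3L)
  iso_exons <- list(`1` = c(400L, 500L), `2` = c(520L, 590L),
                    `3` = c(300L, 350L))
  asm_rows <- list()
  for (k in seq_len(n_strg)) {
    sl <- slots[k, ]
    ts <- sl$start
    strand <- if (k %% 2 == 0) "-" else "+"
    n_iso <- iso_cycle[(k - 1L) %% length(iso_cycle) + 1L]
    gid <- paste0("STRG.", k)
    for (j in seq_len(n_iso)) {
      de <- iso_exons[[as.character(j)]]
      asm_rows[[length(asm_rows) + 1]] <- tibble(
        transcript_id = paste0(gid, ".", j), gene_id = gid,
        chrom = sl$chrom, start = ts + c(50L, de[1]),
        end = ts + c(250L, de[2]), strand = strand,
        source_kind = "TE_derived", host_element = sl$element_id)
    }
  }
  assembled <- bind_rows(asm_rows)

  # genome sequence + splice-site patches for every intron
  seqs <- lapply(chroms, function(chr) {
    paste(sample(c("A", "C", "G", "T"), chrom_len, replace = TRUE),
          collapse = "")
  })
  names(seqs) <- chroms
  all_exons <- bind_rows(select(genes, "transcript_id", "chrom", "start",
                                "end", "strand"),
                         select(assembled, "transcript_id", "chrom", "start",
                                "end", "strand"))
  introns <- all_exons %>%
    group_by(.data$transcript_id) %>%
    arrange(.data$start, .by_group = TRUE) %>%
    summarise(chrom = first(.data$chrom), strand = first(.data$strand),
              istart = list(head(.data$end, -1)),
              iend = list(tail(.data$start, -1)), .groups = "drop") %>%
    tidyr::unnest(c("istart", "iend"))
  seqs <- patch_splice_dinucleotides(seqs, introns)
  genome <- Biostrings::DNAStringSet(unlist(seqs))

  files <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    fa <- file.path(out_dir, "genome.fa")
    Biostrings::writeXStringSet(genome, fa)
    rmsk <- file.path(out_dir, "rmsk.tsv")
    decoys <- tibble(chrom = chroms,
                     start = sizes - 400L, end = sizes - 300L,
                     strand = "+", subfamily = "(TTAGGG)n",
                     family = "Simple_repeat", superfamily = "Simple_repeat")
    rmsk_tbl <- bind_rows(
      select(repeats, "chrom", "start", "end", "strand", "subfamily",
             "superfamily", "family"),
      select(decoys, "chrom", "start", "end", "strand", "subfamily",
             "superfamily", "family")) %>%
      rename(genoName = "chrom", genoStart = "start", genoEnd = "end",
             repName = "subfamily", repClass = "superfamily",
             repFamily = "family")
    readr::write_tsv(rmsk_tbl, rmsk)
    genes_gtf <- file.path(out_dir, "genes.gtf")
    write_gtf(select(genes, -"gene_type"), genes_gtf)
    asm_gtf <- file.path(out_dir, "assembled.gtf")
    write_gtf(select(assembled, -"host_element"), asm_gtf)
    truth_tsv <- file.path(out_dir, "truth_repeats.tsv")
    readr::write_tsv(te_truth, truth_tsv)
    files <- list(genome = fa, rmsk = rmsk, genes = genes_gtf,
                  assembled = asm_gtf, truth = truth_tsv)
  }
  list(genome = genome, sizes = sizes,
       genes = select(genes, -"gene_type"),
       repeats = repeats, assembled = select(assembled, -"host_element"),
       truth = list(te_roles = te_truth,
                    gene_types = distinct(genes, .data$gene_id,
                                          .data$gene_type),
                    seed = seed),
       files = files)
}

cigar_query_len <- function(cigar) {
  m <- stringr::str_match_all(cigar, "(\\d+)([MIDNSHP=X])")[[1]]
  sum(as.integer(m[, 2])[m[, 3] %in% c("M", "I", "S", "=", "X")])
}

write_sam <- function(reads, sizes, path) {
  header <- c("@HD\tVN:1.6\tSO:coordinate",
              paste0("@SQ\tSN:", names(sizes), "\tLN:", unname(sizes)))
  mapped <- reads[!is.na(reads$chrom), , drop = FALSE]
  mapped <- mapped[order(match(mapped$chrom, names(sizes)), mapped$pos), ,
                   drop = FALSE]
  unmapped <- reads[is.na(reads$chrom), , drop = FALSE]
  fmt <- function(r) {
    n <- nrow(r)
    if (n == 0) return(character(0))
    qlen <- vapply(r$cigar, function(cg) {
      if (cg == "*") 1L else as.integer(cigar_query_len(cg))
    }, integer(1), USE.NAMES = FALSE)
    seqs <- vapply(qlen, function(L) paste(rep("A", L), collapse = ""),
                   character(1))
    tags <- if ("tags" %in% names(r)) {
      ifelse(is.na(r$tags) | r$tags == "", "", paste0("\t", r$tags))
    } else ""
    paste0(r$read_id, "\t", r$flag, "\t",
           ifelse(is.na(r$chrom), "*", r$chrom), "\t",
           ifelse(is.na(r$chrom), 0L, r$pos + 1L), "\t", r$mapq, "\t",
           r$cigar, "\t*\t0\t0\t", seqs, "\t*", tags)
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(header, fmt(mapped), fmt(unmapped)), con)
  invisible(path)
}

#' Simulate long reads with known classification truth
#'
#' Constructs reads that satisfy exactly one category definition each:
#' category 1 inside intergenic elements (CIGARs cycle through plain
#' matches, deletions, insertions and soft clips), category 2 over
#' exon-resident elements with intragenic-TE fraction strictly above
#' 0.8, category 3 spanning an intergenic element and a gene exon
#' through an `N` junction, and category 4 decoys (fraction exactly 0.80
#' at the strict boundary, low-fraction reads, and intronic-TE-only
#' reads). Optional filter decoys (low MAPQ, hard clip, secondary,
#' unmapped) and TE-free exon reads carry truth labels `discarded` and
#' `not_te`.
#'
#' @param ref A reference from [simulate_reference()].
#' @param per_category Named or positional counts for categories 1-4.
#' @param include_decoys Add the filter/non-TE decoys? Default TRUE.
#' @param seed RNG seed.
#' @param out_sam If non-NULL, a coordinate-sorted SAM is written here.
#' @return List: `reads` (tibble incl. `truth_category`), `sam`.
#' @export
simulate_long_reads <- function(ref, per_category = c(40, 40, 40, 40),
                                include_decoys = TRUE, seed = 1,
                                out_sam = NULL) {
  set.seed(seed + 1000L)
  stopifnot(length(per_category) == 4)
  roles <- ref$truth$te_roles
  types <- ref$truth$gene_types
  gene_spans <- transcript_spans(ref$genes)
  inter_te <- filter(roles, .data$role %in% c("slot", "free"))
  exonic_te <- filter(roles, .data$role == "exonic")
  intronic_te <- filter(roles, .data$role == "intronic")
  fusion_te <- filter(roles, .data$role == "fusion_te")
  need <- c(nrow(inter_te), nrow(exonic_te), nrow(fusion_te),
            nrow(exonic_te) + nrow(intronic_te))
  impossible <- which(per_category > 0 & need == 0)
  if (length(impossible) > 0) {
    abort(paste0("Category ", impossible[1],
                 " reads are impossible under this reference"))
  }
  rows <- list()
  add <- function(id, chrom, pos, cigar, truth, mapq = 60L, flag = 0L) {
    rows[[length(rows) + 1]] <<- tibble(
      read_id = id, chrom = chrom, pos = as.integer(pos), flag = flag,
      mapq = mapq, cigar = cigar, truth_category = truth)
  }
  # -- category 1: inside an intergenic element -------------------------
  for (i in seq_len(per_category[1])) {
    te <- inter_te[(i - 1L) %% nrow(inter_te) + 1L, ]
    len <- sample(80:min(150L, te$end - te$start), 1)
    pos <- te$start + sample(0:(te$end - te$start - len), 1)
    a <- len %/% 2L
    cigar <- switch((i - 1L) %% 4L + 1L,
      paste0(len, "M"),
      paste0(a, "M2D", len - a - 2L, "M"),
      paste0(a, "M2I", len - a, "M"),
      paste0("5S", len, "M"))
    add(paste0("r1_", i), te$chrom, pos, cigar, "1_intergenic")
  }
  # -- category 2: exon + intragenic TE, fraction > 0.8 -----------------
  for (i in seq_len(per_category[2])) {
    te <- exonic_te[(i - 1L) %% nrow(exonic_te) + 1L, ]
    pad <- 1L + (i - 1L) %% 59L              # 240/(240+pad) > 0.8 for pad < 60
    add(paste0("r2_", i), te$chrom, te$start - pad,
        paste0(te$end - te$start + pad, "M"), "2_intragenic")
  }
  # -- category 3: intergenic TE .. N .. gene exon ----------------------
  for (i in seq_len(per_category[3])) {
    te <- fusion_te[(i - 1L) %% nrow(fusion_te) + 1L, ]
    span <- gene_spans[gene_spans$gene_id == te$linked_gene, ]
    exon1_s <- span$start                    # fusion exon1 begins the span
    b1s <- te$start + 50L; b1e <- b1s + 100L
    b2s <- exon1_s + 50L + 10L * ((i - 1L) %% 10L); b2e <- b2s + 100L
    add(paste0("r3_", i), te$chrom, b1s,
        paste0("100M", b2s - b1e, "N100M"), "3_fusion")
  }
  # -- category 4: boundary / low-fraction / intronic decoys ------------
  for (i in seq_len(per_category[4])) {
    flavor <- (i - 1L) %% 3L + 1L
    if (flavor == 3L && nrow(intronic_te) == 0) flavor <- 1L
    if (flavor %in% c(1L, 2L)) {
      te <- exonic_te[(i - 1L) %% nrow(exonic_te) + 1L, ]
      w <- te$end - te$start                 # 240
      pad <- if (flavor == 1L) w %/% 4L else w %/% 2L  # 0.80 exact / 0.667
      add(paste0("r4_", i), te$chrom, te$start - pad,
          paste0(w + pad, "M"), "4_other")
    } else {
      te <- intronic_te[(i - 1L) %% nrow(intronic_te) + 1L, ]
      len <- sample(80:140, 1)
      pos <- te$start + sample(0:(te$end - te$start - len), 1)
      add(paste0("r4_", i), te$chrom, pos, paste0(len, "M"), "4_other")
    }
  }
  if (include_decoys) {
    te <- inter_te[1, ]
    add("d_lowmapq", te$chrom, te$start + 5L, "90M", "discarded", mapq = 10L)
    add("d_hardclip", te$chrom, te$start + 5L, "5H90M", "discarded")
    add("d_secondary", te$chrom, te$start + 5L, "90M", "discarded",
        flag = 256L)
    add("d_unmapped", NA_character_, 0L, "*", "discarded", mapq = 0L,
        flag = 4L)
    clean <- filter(types, .data$gene_type %in% c("clean", "intronic_te"))
    if (nrow(clean) > 0) {
      span <- gene_spans[gene_spans$gene_id == clean$gene_id[1], ]
      # exon2 of a non-fusion gene starts span+700 and holds no TE
      add("d_notte", span$chrom, span$start + 720L, "100M", "not_te")
    }
  }
  reads <- bind_rows(rows)
  sam <- NULL
  if (!is.null(out_sam)) {
    write_sam(reads, ref$sizes, out_sam)
    sam <- out_sam
  }
  list(reads = reads, sam = sam)
}

# feature table shared by quantify_cells() and the simulators
sc_feature_table <- function(merged_exons) {
  spans <- transcript_spans(merged_exons)
  bind_rows(
    spans %>% distinct(.data$gene_id, .keep_all = TRUE) %>%
      mutate(id = .data$gene_id, name = .data$gene_id, kind = "gene",
             is_te = .data$source_kind == "TE_derived") %>%
      select("id", "name", "kind", "is_te"),
    spans %>%
      mutate(id = .data$transcript_id, name = .data$transcript_id,
             kind = "isoform", is_te = .data$source_kind == "TE_derived") %>%
      select("id", "name", "kind", "is_te")
  )
}

#' Simulate barcoded single-cell reads with planted markers
#'
#' Molecules are drawn Poisson per (cell, gene); each molecule picks one
#' isoform, lands in that isoform's distinctive exon, gets a unique UMI,
#' and is emitted as 1-3 duplicate reads sharing its CB/UB tags. The
#' truth matrix records molecules (not reads) over the same gene +
#' isoform feature universe that [quantify_cells()] reports, so exact
#' recovery can be asserted.
#'
#' @param ref Reference from [simulate_reference()].
#' @param n_cells Named integer vector: cells per cell type.
#' @param planted_markers Tibble `cell_type`, `feature` (a gene id),
#'   `mean`: Poisson means overriding the background for that type.
#' @param background_mean_gene,background_mean_te Background Poisson
#'   means for nonTE genes and STRG genes.
#' @param dup_range Inclusive range of duplicate reads per molecule.
#' @param tissues Tissue labels cycled over cells (for the metadata).
#' @param seed RNG seed.
#' @param out_sam If non-NULL, the barcoded SAM is written here.
#' @return List: `reads`, `sam`, `truth` (a `te_count_matrix`),
#'   `metadata` (tibble `barcode`, `cell_type`, `tissue`), `merged`
#'   (the reconciled annotation used).
#' @export
simulate_barcoded_reads <- function(ref, n_cells = c(TypeA = 30, TypeB = 120),
                                    planted_markers =
                                      tibble(cell_type = "TypeA",
                                             feature = "STRG.1", mean = 20),
                                    background_mean_gene = 2,
                                    background_mean_te = 0.5,
                                    dup_range = c(1, 3),
                                    tissues = c("liver", "lung"),
                                    seed = 1, out_sam = NULL) {
  set.seed(seed + 2000L)
  stopifnot(!is.null(names(n_cells)))
  rec <- reconcile_annotations(ref$assembled, ref$genes)
  merged <- rec$merged
  spans <- transcript_spans(merged)
  feats <- sc_feature_table(merged)
  missing <- setdiff(planted_markers$feature, feats$id)
  if (length(missing) > 0) {
    abort(paste0("Planted feature absent from annotation: ",
                 paste(missing, collapse = ", ")))
  }
  genes_tbl <- distinct(spans, .data$gene_id, .keep_all = TRUE)
  # distinctive exon of each isoform: nonTE genes use exon2; STRG
  # isoforms use their second (or only) exon
  iso_exon <- merged %>%
    group_by(.data$transcript_id) %>%
    arrange(.data$start, .by_group = TRUE) %>%
    slice(n()) %>%
    ungroup() %>%
    select("transcript_id", "gene_id", "chrom", "start", "end",
           "source_kind")
  barcodes <- vapply(seq_len(sum(n_cells)), int2dna, character(1),
                     width = 12)
  metadata <- tibble(
    barcode = barcodes,
    cell_type = rep(names(n_cells), n_cells),
    tissue = rep_len(tissues, sum(n_cells))
  )
  mol_counter <- 0L
  reads <- list(); truth_triples <- list()
  for (ci in seq_len(nrow(metadata))) {
    bc <- metadata$barcode[ci]; ct <- metadata$cell_type[ci]
    for (g in genes_tbl$gene_id) {
      is_te <- genes_tbl$source_kind[genes_tbl$gene_id == g] == "TE_derived"
      planted <- planted_markers[planted_markers$cell_type == ct &
                                   planted_markers$feature == g, ]
      lam <- if (nrow(planted) > 0) planted$mean[1]
             else if (is_te) background_mean_te else background_mean_gene
      k <- rpois(1, lam)
      if (k == 0) next
      isoforms <- iso_exon[iso_exon$gene_id == g, , drop = FALSE]
      for (mol in seq_len(k)) {
        mol_counter <- mol_counter + 1L
        iso <- isoforms[sample(nrow(isoforms), 1), , drop = FALSE]
        umi <- int2dna(mol_counter, 10)
        width <- iso$end - iso$start
        len <- min(60L, width - 10L)
        pos <- iso$start + sample(0:(width - len), 1)
        n_dup <- sample(dup_range[1]:dup_range[2], 1)
        for (d in seq_len(n_dup)) {
          reads[[length(reads) + 1]] <- tibble(
            read_id = paste0("m", mol_counter, "_", d), chrom = iso$chrom,
            pos = as.integer(pos), flag = 0L, mapq = 60L,
            cigar = paste0(len, "M"),
            tags = paste0("CB:Z:", bc, "\tUB:Z:", umi))
        }
        truth_triples[[length(truth_triples) + 1]] <- tibble(
          barcode = bc, feature = c(g, iso$transcript_id))
      }
    }
  }
  empty_reads <- tibble(read_id = character(), chrom = character(),
                        pos = integer(), flag = integer(), mapq = integer(),
                        cigar = character(), tags = character())
  reads <- bind_rows(empty_reads, reads)
  truth_tr <- bind_rows(tibble(barcode = character(), feature = character()),
                        truth_triples)
  truth_cnt <- count(truth_tr, .data$barcode, .data$feature)
  truth_m <- Matrix::sparseMatrix(
    i = match(truth_cnt$feature, feats$id),
    j = match(truth_cnt$barcode, barcodes),
    x = truth_cnt$n, dims = c(nrow(feats), length(barcodes)))
  truth <- te_count_matrix(truth_m, feats, barcodes)
  sam <- NULL
  if (!is.null(out_sam)) {
    write_sam(reads, ref$sizes, out_sam)
    sam <- out_sam
  }
  list(reads = reads, sam = sam, truth = truth, metadata = metadata,
       merged = merged)
}

#' Simulate an expression matrix directly (no reads)
#'
#' A light generator for statistics tests: Poisson counts per (cell,
#' feature) with optional planted cell-type markers, returned as a
#' `te_count_matrix` plus metadata. TE features carry `STRG.`-style
#' ids.
#'
#' @param n_cells Named integer vector, cells per cell type.
#' @param n_nonte,n_te Numbers of nonTE (`ENSGxxxx`) and TE
#'   (`STRG.k_AluY`) features.
#' @param background_mean,te_background_mean Poisson background means.
#' @param planted Tibble `cell_type`, `feature`, `mean` (overrides).
#' @param seed RNG seed.
#' @return List: `matrix` (`te_count_matrix`), `metadata`.
#' @export
simulate_expression_matrix <- function(n_cells = c(TypeA = 30, TypeB = 120),
                                       n_nonte = 15, n_te = 5,
                                       background_mean = 5,
                                       te_background_mean = 0.5,
                                       planted = NULL, seed = 1) {
  set.seed(seed + 3000L)
  te_ids <- if (n_te > 0) paste0("STRG.", seq_len(n_te), "_AluY") else character(0)
  feats <- tibble(
    id = c(sprintf("ENSG%06d", seq_len(n_nonte)), te_ids),
    name = NA_character_,
    kind = "gene",
    is_te = c(rep(FALSE, n_nonte), rep(TRUE, n_te))
  )
  feats$name <- feats$id
  barcodes <- vapply(seq_len(sum(n_cells)), int2dna, character(1), width = 10)
  metadata <- tibble(barcode = barcodes,
                     cell_type = rep(names(n_cells), n_cells))
  lam <- matrix(rep(ifelse(feats$is_te, te_background_mean, background_mean),
                    length(barcodes)),
                nrow = nrow(feats))
  if (!is.null(planted)) {
    for (i in seq_len(nrow(planted))) {
      fi <- match(planted$feature[i], feats$id)
      cj <- which(metadata$cell_type == planted$cell_type[i])
      if (is.na(fi)) abort(paste0("Unknown planted feature: ",
                                  planted$feature[i]))
      lam[fi, cj] <- planted$mean[i]
    }
  }
  counts <- matrix(rpois(length(lam), lam), nrow = nrow(lam))
  m <- te_count_matrix(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                   "CsparseMatrix"),
                       feats, barcodes)
  list(matrix = m, metadata = metadata)
}
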