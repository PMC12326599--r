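# Shared fixtures and independent oracles for the test suite. The
# reference is cached per seed so expensive pieces are built once per
# test run.

.fixture_cache <- new.env(parent = emptyenv())

cached_ref <- function(seed = 1) {
  key <- paste0("ref", seed)
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, simulate_reference(seed = seed), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

cached_masks <- function(seed = 1) {
  key <- paste0("masks", seed)
  if (!exists(key, envir = .fixture_cache)) {
    ref <- cached_ref(seed)
    assign(key, build_te_masks(ref$repeats, ref$genes, ref$sizes),
           envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# Hand-built four-mask fixture on a single 400 bp chromosome:
#   exon  (0,50) (100,110) (300,340)
#   intra (50,100) (110,200)
#   inter (210,270) (350,380)
toy_masks <- function() {
  sizes <- c(chrT = 400L)
  iv <- function(...) {
    m <- matrix(c(...), ncol = 2, byrow = TRUE)
    tibble::tibble(chrom = "chrT", start = m[, 1], end = m[, 2])
  }
  inter <- iv(210, 270, 350, 380)
  intra <- iv(50, 100, 110, 200)
  list(
    TE_all = build_genome_mask(dplyr::bind_rows(inter, intra), sizes, "TE_all"),
    TE_intergenic = build_genome_mask(inter, sizes, "TE_intergenic"),
    TE_intragenic = build_genome_mask(intra, sizes, "TE_intragenic"),
    EXON = build_genome_mask(iv(0, 50, 100, 110, 300, 340), sizes, "EXON")
  )
}

toy_blocks <- function(start, end, chrom = "chrT") {
  tibble::tibble(chrom = chrom, start = as.integer(start),
                 end = as.integer(end))
}

# independent per-base union length (sweep over every base)
naive_union_length <- function(intervals, sizes) {
  total <- 0L
  for (chr in names(sizes)) {
    covered <- rep(FALSE, sizes[[chr]])
    sub <- intervals[intervals$chrom == chr, , drop = FALSE]
    for (i in seq_len(nrow(sub))) {
      for (b in seq(sub$start[i] + 1L, sub$end[i])) covered[b] <- TRUE
    }
    total <- total + sum(covered)
  }
  total
}

# independent CIGAR walker (regmatches-based, distinct from the package's)
oracle_blocks <- function(pos, cigar) {
  toks <- regmatches(cigar, gregexpr("[0-9]+[A-Z=]", cigar))[[1]]
  lens <- as.integer(sub("[A-Z=]$", "", toks))
  ops <- sub("^[0-9]+", "", toks)
  out <- NULL
  s <- pos; e <- pos
  for (i in seq_along(ops)) {
    if (ops[i] %in% c("M", "=", "X", "D")) e <- e + lens[i]
    if (ops[i] == "N") {
      if (e > s) out <- rbind(out, c(s, e))
      s <- e + lens[i]; e <- s
    }
  }
  if (e > s) out <- rbind(out, c(s, e))
  out
}

# brute-force per-base read classifier built from the reference truth
# (rasterizes annotations; independent of the mask machinery)
oracle_classifier <- function(ref) {
  lab <- lapply(names(ref$sizes), function(chr) {
    n <- ref$sizes[[chr]]
    v <- list(inter = rep(FALSE, n), intra = rep(FALSE, n),
              exon = rep(FALSE, n))
    roles <- ref$truth$te_roles
    for (i in which(roles$chrom == chr)) {
      idx <- seq(roles$start[i] + 1L, roles$end[i])
      if (roles$genic_context_truth[i] == "intergenic") {
        v$inter[idx] <- TRUE
      } else {
        v$intra[idx] <- TRUE
      }
    }
    for (i in which(ref$genes$chrom == chr)) {
      v$exon[seq(ref$genes$start[i] + 1L, ref$genes$end[i])] <- TRUE
    }
    v
  })
  names(lab) <- names(ref$sizes)
  function(chrom, pos, cigar, te_frac_min = 0.8) {
    bl <- oracle_blocks(pos, cigar)
    v <- lab[[chrom]]
    idx <- unlist(lapply(seq_len(nrow(bl)), function(i) {
      seq(bl[i, 1] + 1L, bl[i, 2])
    }))
    aligned <- length(idx)
    inter <- sum(v$inter[idx]); intra <- sum(v$intra[idx])
    exon <- sum(v$exon[idx])
    if (inter + intra == 0) return("not_te")
    if (exon == 0 && inter > 0 && intra == 0) return("1_intergenic")
    if (exon > 0 && inter > 0) return("3_fusion")
    if (exon > 0 && intra / aligned > te_frac_min) return("2_intragenic")
    "4_other"
  }
}

dir_md5 <- function(dir) {
  files <- sort(list.files(dir, recursive = TRUE))
  vapply(files, function(f) unname(tools::md5sum(file.path(dir, f))),
         character(1))
}
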