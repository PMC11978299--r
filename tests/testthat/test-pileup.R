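test_that("pileup counts hand-placed reads exactly", {
  ref <- Biostrings::DNAStringSet(c(ctgX = "AAAACGTACGTACGTAAAA"))
  # 10 reads over the same interval, 3 of them carrying C->T at offset 4
  seqs <- c(rep("CGTACGTACGT", 7), rep("TGTACGTACGT", 3))
  recs <- data.frame(chrom = "ctgX", pos0 = 4L, seq = seqs,
                     stringsAsFactors = FALSE)
  sam <- write_manual_sam(recs, ref, tempfile(fileext = ".sam"))
  pu <- build_pileup(sam, ref)
  at4 <- pu[pu$pos == 4L, ]
  expect_equal(at4$C, 7L)
  expect_equal(at4$T, 3L)
  expect_equal(at4$depth, 10L)
  expect_equal(at4$ref_base, "C")
  at5 <- pu[pu$pos == 5L, ]
  expect_equal(at5$G, 10L)
  expect_equal(at5$depth, 10L)
  # zero-depth positions are omitted
  expect_false(any(pu$pos < 4L | pu$pos > 14L))
})

test_that("duplicate and secondary alignments are excluded from the pileup", {
  ref <- Biostrings::DNAStringSet(c(ctgX = "AAAACGTACGTACGTAAAA"))
  recs <- data.frame(chrom = "ctgX", pos0 = 4L,
                     seq = rep("CGTACGTACGT", 4),
                     flag = c(0L, 1024L, 256L, 2048L),
                     stringsAsFactors = FALSE)
  sam <- write_manual_sam(recs, ref, tempfile(fileext = ".sam"))
  pu <- build_pileup(sam, ref)
  expect_equal(pu$depth[pu$pos == 4L], 1L)
})

test_that("contig mismatches against the reference are fatal", {
  ref <- Biostrings::DNAStringSet(c(ctgX = "AAAACGTACGTACGTAAAA"))
  other <- Biostrings::DNAStringSet(c(ctgY = "AAAACGTACGTACGTAAAA"))
  recs <- data.frame(chrom = "ctgX", pos0 = 4L, seq = "CGTACGTACGT",
                     stringsAsFactors = FALSE)
  sam <- write_manual_sam(recs, ref, tempfile(fileext = ".sam"))
  expect_error(build_pileup(sam, other), "ctgX")
  short <- Biostrings::DNAStringSet(c(ctgX = "AAAACGTACG"))
  expect_error(build_pileup(sam, short), "length mismatch")
})

test_that("pileup of a simulated run equals a brute-force per-read tally", {
  w <- tiny_world(2, c(400L, 500L), seed = 91)
  truth <- plant_m5c_sites(w$genes, w$reference, 4, rate_range = c(0.3, 0.3),
                           seed = 2)
  spec <- condition_spec("DRAM", 1, coverage_mean = 25, rate_multiplier = 1,
                         error_rate = 0.005, seed = 6)
  sam <- simulate_reads(w$genes, w$reference, truth, spec,
                        out_dir = tempfile())
  pu <- build_pileup(sam[1], w$reference, min_base_quality = 0,
                     min_mapping_quality = 0)
  oracle <- naive_pileup_tally(sam[1])
  expect_equal(nrow(pu), nrow(oracle))
  for (col in c("A", "C", "G", "T", "depth")) {
    expect_equal(pu[[col]], oracle[[col]], label = col)
  }
  expect_equal(pu$pos, oracle$pos)
})

test_that("candidates read conversion classes through the gene strand", {
  genes <- dramseq:::new_gene_model("ctgP", 0L, 200L, "gP", "+", 50L, 150L,
                                    list(200L), list(0L))
  pu <- data.frame(chrom = "ctgP", pos = 100L, ref_base = "C",
                   A = 0L, C = 90L, G = 0L, T = 10L, N = 0L, depth = 100L,
                   stringsAsFactors = FALSE)
  cand <- extract_candidates(pu, genes, "C2U")
  expect_equal(nrow(cand), 1L)
  expect_equal(cand$ratio, 0.10)
  expect_equal(cand$strand, "+")

  genes_m <- dramseq:::new_gene_model("ctgM", 0L, 200L, "gM", "-", 50L, 150L,
                                      list(200L), list(0L))
  pu_m <- data.frame(chrom = "ctgM", pos = 100L, ref_base = "G",
                     A = 20L, C = 0L, G = 80L, T = 0L, N = 0L, depth = 100L,
                     stringsAsFactors = FALSE)
  cand_m <- extract_candidates(pu_m, genes_m, "C2U")
  expect_equal(cand_m$ratio, 0.20)
  expect_equal(cand_m$strand, "-")

  # N bases inflate depth but never the edited count
  pu_n <- pu
  pu_n$N <- 10L; pu_n$depth <- 110L
  cand_n <- extract_candidates(pu_n, genes, "C2U")
  expect_equal(cand_n$edited, 10L)
  expect_equal(cand_n$coverage, 110L)
})

test_that("positions outside genes are evaluated on both strands", {
  genes <- dramseq:::new_gene_model("ctgP", 500L, 700L, "gP", "+", 550L, 650L,
                                    list(200L), list(0L))
  pu <- data.frame(chrom = "ctgP", pos = c(10L, 20L),
                   ref_base = c("C", "G"),
                   A = c(0L, 5L), C = c(45L, 0L), G = c(0L, 45L),
                   T = c(5L, 0L), N = c(0L, 0L), depth = c(50L, 50L),
                   stringsAsFactors = FALSE)
  cand <- extract_candidates(pu, genes, "C2U")
  expect_equal(nrow(cand), 2L)
  expect_equal(cand$strand[cand$pos == 10L], "+")  # ref C, C->T on +
  expect_equal(cand$strand[cand$pos == 20L], "-")  # ref G, G->A reads - C2U
  expect_true(all(is.na(cand$gene_id)))
})

test_that("overlapping genes on both strands flag ambiguous candidates", {
  genes <- dramseq:::new_gene_model(c("ctgP", "ctgP"), c(0L, 0L),
                                    c(200L, 200L), c("gA", "gB"),
                                    c("+", "-"), c(50L, 50L), c(150L, 150L),
                                    list(200L, 200L), list(0L, 0L))
  pu <- data.frame(chrom = "ctgP", pos = 100L, ref_base = "C",
                   A = 0L, C = 90L, G = 0L, T = 10L, N = 0L, depth = 100L,
                   stringsAsFactors = FALSE)
  cand <- extract_candidates(pu, genes, "C2U")
  # ref C only supports the + orientation of C2U, flagged ambiguous
  expect_equal(nrow(cand), 1L)
  expect_true(all(cand$ambiguous))
})

test_that("candidate extraction matches a raw-read oracle on an ABE run", {
  w <- tiny_world(2, c(400L, 450L), seed = 101)
  truth <- plant_m5c_sites(w$genes, w$reference, 4, editor = "ABE",
                           rate_range = c(0.4, 0.4), seed = 3)
  spec <- condition_spec("DRAM", 1, coverage_mean = 30, rate_multiplier = 1,
                         error_rate = 0, seed = 8)
  sam <- simulate_reads(w$genes, w$reference, truth, spec,
                        out_dir = tempfile())
  pu <- build_pileup(sam[1], w$reference, min_base_quality = 0)
  cand <- extract_candidates(pu, w$genes, "A2G")
  tally <- naive_pileup_tally(sam[1])
  # oracle: for each gene position, edited count is the alt-base tally in
  # reference space given the gene strand
  ora <- list()
  for (gi in seq_len(nrow(w$genes))) {
    g <- w$genes[gi, ]
    sub <- tally[tally$chrom == g$chrom & tally$pos >= g$start &
                   tally$pos < g$end, ]
    refc <- strsplit(as.character(w$reference[[g$chrom]]), "")[[1]]
    want_ref <- if (g$strand == "+") "A" else "T"
    alt <- if (g$strand == "+") "G" else "C"
    sub <- sub[refc[sub$pos + 1L] == want_ref & sub[[alt]] > 0, ]
    if (nrow(sub)) {
      ora[[gi]] <- data.frame(chrom = sub$chrom, pos = sub$pos,
                              edited = sub[[alt]], coverage = sub$depth)
    }
  }
  ora <- do.call(rbind, ora)
  ora <- ora[order(ora$chrom, ora$pos), ]
  genic <- cand[!is.na(cand$gene_id), ]
  expect_equal(genic$pos, ora$pos)
  expect_equal(genic$edited, ora$edited)
  expect_equal(genic$coverage, ora$coverage)
})

test_that("strand involution maps candidates onto themselves", {
  w <- generate_transcriptome(2, c(450L, 450L), seed = 111)
  truth <- plant_m5c_sites(w$genes, w$reference, 3, rate_range = c(0.3, 0.3),
                           seed = 4)
  spec <- condition_spec("DRAM", 1, coverage_mean = 40, rate_multiplier = 1,
                         error_rate = 0, seed = 5)
  sam <- simulate_reads(w$genes, w$reference, truth, spec,
                        out_dir = tempfile())
  pu <- build_pileup(sam[1], w$reference)
  cand <- extract_candidates(pu, w$genes, "C2U")
  # complement the whole coordinate system and re-extract
  fw <- flip_world(w)
  fpu <- pu
  L <- Biostrings::width(w$reference)[match(pu$chrom, names(w$reference))]
  fpu$pos <- L - 1L - pu$pos
  fpu$ref_base <- dramseq:::complement_base(pu$ref_base)
  fpu[, c("A", "C", "G", "T")] <- pu[, c("T", "G", "C", "A")]
  fcand <- extract_candidates(fpu, fw$genes, "C2U")
  # map complemented-space positions back and compare the candidate sets
  fL <- Biostrings::width(w$reference)[match(fcand$chrom,
                                             names(w$reference))]
  fcand$pos <- fL - 1L - fcand$pos
  fcand$strand <- ifelse(fcand$strand == "+", "-", "+")
  cols <- c("chrom", "pos", "strand", "coverage", "edited", "ratio")
  a <- cand[order(cand$chrom, cand$pos, cand$strand), cols]
  b <- fcand[order(fcand$chrom, fcand$pos, fcand$strand), cols]
  rownames(a) <- rownames(b) <- NULL
  expect_equal(a, b)
})

test_that("emitted candidate ratios always lie in (0, 1]", {
  w <- tiny_world(2, c(400L, 500L), seed = 121)
  truth <- plant_m5c_sites(w$genes, w$reference, 5, rate_range = c(0.2, 0.8),
                           seed = 6)
  spec <- condition_spec("DRAM", 1, coverage_mean = 20, rate_multiplier = 1,
                         error_rate = 0.01, seed = 7)
  sam <- simulate_reads(w$genes, w$reference, truth, spec,
                        out_dir = tempfile())
  cand <- extract_candidates(build_pileup(sam[1], w$reference), w$genes,
                             "C2U")
  expect_true(all(cand$ratio > 0 & cand$ratio <= 1))
  expect_true(all(cand$edited <= cand$coverage))
})
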