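test_that("transcriptome segments follow the requested fractions", {
  w <- generate_transcriptome(1, c(300L, 300L), c(0.2, 0.5, 0.3), seed = 1)
  expect_equal(nrow(w$genes), 1L)
  seg <- dramseq:::gene_segments(w$genes[1, ])
  expect_equal(unname(seg[c("utr5", "cds", "utr3")]), c(60L, 150L, 90L))
  expect_equal(unname(seg["cds"]) %% 3L, 0L)
})

test_that("generation is deterministic for a fixed seed", {
  w1 <- generate_transcriptome(5, c(400L, 600L), seed = 7)
  w2 <- generate_transcriptome(5, c(400L, 600L), seed = 7)
  f1 <- tempfile(fileext = ".fa"); f2 <- tempfile(fileext = ".fa")
  Biostrings::writeXStringSet(w1$reference, f1)
  Biostrings::writeXStringSet(w2$reference, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(w1$genes$thick_start, w2$genes$thick_start)
  w3 <- generate_transcriptome(5, c(400L, 600L), seed = 8)
  expect_false(identical(as.character(w1$reference),
                         as.character(w3$reference)))
})

test_that("invalid fractions are rejected and both strands are represented", {
  expect_error(generate_transcriptome(2, c(300L, 300L), c(0.5, 0.5, 0.5)),
               "sum to 1")
  w <- generate_transcriptome(6, c(300L, 500L), seed = 3)
  expect_setequal(unique(w$genes$strand), c("+", "-"))
})

test_that("BED12 output is consistent with the FASTA by an independent parser", {
  skip_if_not_installed("rtracklayer")
  w <- generate_transcriptome(50, c(300L, 800L), seed = 3)
  bed <- tempfile(fileext = ".bed")
  write_gene_model(w$genes, bed)
  gr <- rtracklayer::import(bed, format = "BED")
  expect_equal(length(gr), 50L)
  blocks <- rtracklayer::blocks(gr)
  for (i in seq_along(gr)) {
    chrom <- as.character(GenomicRanges::seqnames(gr)[i])
    expect_true(chrom %in% names(w$reference))
    # blocks fall inside the contig and their total length matches the
    # transcript extent recorded in the gene model
    expect_lte(max(GenomicRanges::end(blocks[[i]])),
               Biostrings::width(w$reference)[match(chrom,
                                                    names(w$reference))])
    expect_equal(sum(GenomicRanges::width(blocks[[i]])),
                 w$genes$end[i] - w$genes$start[i])
  }
  # round trip through the package reader
  rt <- read_gene_model(bed)
  expect_equal(rt$start, w$genes$start)
  expect_equal(rt$thick_end, w$genes$thick_end)
})

test_that("planted sites honour degenerate weights and fixed rates", {
  w <- tiny_world(seed = 21)
  t_cds <- plant_m5c_sites(w$genes, w$reference, 10,
                           region_weights = c(CDS = 1), seed = 2)
  expect_equal(nrow(t_cds), 10L)
  expect_true(all(t_cds$region == "CDS"))
  t_fix <- plant_m5c_sites(w$genes, w$reference, 8,
                           rate_range = c(0.147, 0.147), seed = 2)
  expect_true(all(t_fix$edit_rate == 0.147))
  # every planted position is a sense-strand C
  for (i in seq_len(nrow(t_fix))) {
    g <- w$genes[w$genes$name == t_fix$transcript_id[i], ]
    txs <- dramseq:::transcript_seq(w$reference, g)
    expect_identical(substring(txs, t_fix$position[i] + 1L,
                               t_fix$position[i] + 1L), "C")
  }
  expect_false(any(duplicated(paste(t_fix$transcript_id, t_fix$position))))
})

test_that("planted region distribution converges to the requested weights", {
  w <- generate_transcriptome(20, c(900L, 1500L), seed = 5)
  weights <- c(CDS = 0.6, UTR3 = 0.3, UTR5 = 0.1)
  truth <- plant_m5c_sites(w$genes, w$reference, 200,
                           region_weights = weights, seed = 5)
  counts <- table(factor(truth$region, levels = names(weights)))
  for (r in names(weights)) {
    bounds <- qbinom(c(0.005, 0.995), 200, weights[r])
    expect_gte(counts[[r]], bounds[1])
    expect_lte(counts[[r]], bounds[2])
  }
})

test_that("a null condition yields mismatch-free alignments", {
  w <- tiny_world(2, c(400L, 500L), seed = 31)
  truth <- plant_m5c_sites(w$genes, w$reference, 4, rate_range = c(0.5, 0.5),
                           seed = 1)
  spec <- condition_spec("DRAM_MUT", replicate_count = 1, coverage_mean = 20,
                         rate_multiplier = 0, background_rate = 0,
                         error_rate = 0, seed = 4)
  sam <- simulate_reads(w$genes, w$reference, truth, spec,
                        out_dir = tempfile())
  lines <- readLines(sam[1])
  body <- lines[!startsWith(lines, "@")]
  expect_true(all(grepl("\tNM:i:0\t", body)))
})

test_that("per-read editing matches its binomial law at a planted site", {
  w <- generate_transcriptome(1, c(600L, 600L), seed = 41)
  truth <- plant_m5c_sites(w$genes, w$reference, 1,
                           region_weights = c(CDS = 1),
                           rate_range = c(0.5, 0.5), seed = 2)
  spec <- condition_spec("DRAM", replicate_count = 1, coverage_mean = 2000,
                         rate_multiplier = 1, error_rate = 0, seed = 9)
  sam <- simulate_reads(w$genes, w$reference, truth, spec,
                        out_dir = tempfile())
  pu <- build_pileup(sam[1], w$reference)
  cand <- extract_candidates(pu, w$genes, "C2U")
  near <- cand[abs(cand$pos - truth$gpos[1]) <= truth$window_halfwidth[1] &
                 cand$strand == truth$strand[1], ]
  expect_gt(nrow(near), 0)
  n <- sum(near$coverage)
  frac <- sum(near$edited) / n
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / n))
})

test_that("knockout attenuation preserves a >=1.5-fold DRAM/KO margin", {
  w <- tiny_world(2, c(700L, 900L), seed = 51)
  truth <- plant_m5c_sites(w$genes, w$reference, 6, rate_range = c(0.3, 0.3),
                           seed = 3)
  dram <- condition_spec("DRAM", 1, coverage_mean = 150, rate_multiplier = 1,
                         error_rate = 0, seed = 7)
  ko <- condition_spec("KNOCKOUT", 1, coverage_mean = 150,
                       rate_multiplier = 0.1, error_rate = 0, seed = 7)
  get_ratio <- function(spec) {
    sam <- simulate_reads(w$genes, w$reference, truth, spec,
                          out_dir = tempfile())
    pu <- build_pileup(sam[1], w$reference)
    cand <- extract_candidates(pu, w$genes, "C2U", keep_zero = TRUE)
    hit <- logical(nrow(cand))
    for (i in seq_len(nrow(truth))) {
      hit <- hit | (cand$chrom == truth$chrom[i] &
                      abs(cand$pos - truth$gpos[i]) <= 20 &
                      cand$strand == truth$strand[i])
    }
    sum(cand$edited[hit]) / sum(cand$coverage[hit])
  }
  expect_gte(get_ratio(dram) / get_ratio(ko), 1.5)
})

test_that("read count and interior depth track the requested coverage", {
  w <- generate_transcriptome(1, c(1500L, 1500L), seed = 61)
  truth <- plant_m5c_sites(w$genes, w$reference, 1, seed = 1)
  spec <- condition_spec("DRAM", 1, coverage_mean = 40, rate_multiplier = 0,
                         error_rate = 0, seed = 3)
  sam <- simulate_reads(w$genes, w$reference, truth, spec, read_length = 100L,
                        out_dir = tempfile())
  body <- readLines(sam[1])
  body <- body[!startsWith(body, "@")]
  expect_equal(length(body), round(40 * 1500 / 100))
  pu <- build_pileup(sam[1], w$reference, min_base_quality = 0)
  g <- w$genes[1, ]
  interior <- pu[pu$pos >= g$start + 150 & pu$pos < g$end - 150, ]
  expect_lt(abs(mean(interior$depth) - 40) / 40, 0.15)
})

test_that("short transcripts are skipped with a warning", {
  w <- generate_transcriptome(1, c(300L, 300L), seed = 71)
  truth <- plant_m5c_sites(w$genes, w$reference, 1, seed = 1)
  spec <- condition_spec("DRAM", 1, coverage_mean = 10, seed = 2)
  expect_warning(
    simulate_reads(w$genes, w$reference, truth, spec, read_length = 400L,
                   out_dir = tempfile()),
    "shorter than read length")
})

test_that("strand flipping leaves transcript-space edit counts unchanged", {
  w <- generate_transcriptome(2, c(500L, 500L), seed = 81)
  truth <- plant_m5c_sites(w$genes, w$reference, 4, rate_range = c(0.4, 0.4),
                           seed = 5)
  fw <- flip_world(w)
  # planted truth carries transcript coordinates; genomic ones are recomputed
  ftruth <- truth
  for (i in seq_len(nrow(ftruth))) {
    g <- fw$genes[fw$genes$name == ftruth$transcript_id[i], ]
    ftruth$strand[i] <- g$strand
    ftruth$gpos[i] <- dramseq:::tx_to_genomic(g, ftruth$position[i])
  }
  spec <- condition_spec("DRAM", 1, coverage_mean = 60, rate_multiplier = 1,
                         error_rate = 0, seed = 13)
  tx_counts <- function(world, tr) {
    sam <- simulate_reads(world$genes, world$reference, tr,
                          out_dir = tempfile(), spec = spec)
    pu <- build_pileup(sam[1], world$reference)
    cand <- extract_candidates(pu, world$genes, "C2U")
    cand <- cand[!is.na(cand$gene_id), ]
    tpos <- integer(nrow(cand))
    for (i in seq_len(nrow(cand))) {
      g <- world$genes[world$genes$name == cand$gene_id[i], ]
      tpos[i] <- dramseq:::genomic_to_tx(g, cand$pos[i])
    }
    res <- data.frame(gene = cand$gene_id, tpos = tpos, edited = cand$edited)
    res[order(res$gene, res$tpos), ]
  }
  a <- tx_counts(w, truth)
  b <- tx_counts(fw, ftruth)
  rownames(a) <- rownames(b) <- NULL
  expect_equal(a, b)
})

test_that("bisulfite amplicon simulation obeys its limits and its law", {
  amp <- paste0("ATGGCAT", "C", "GGATTACCGA")  # site at offset 7
  r0 <- simulate_bisulfite_amplicon(amp, 7L, m5c_fraction = 0,
                                    n_reads = 200, seed = 2)
  b0 <- as.character(Biostrings::subseq(r0, 8L, 8L))
  expect_true(all(b0 == "T"))
  r1 <- simulate_bisulfite_amplicon(amp, 7L, m5c_fraction = 1,
                                    n_reads = 200,
                                    conversion_efficiency = 0.5, seed = 2)
  b1 <- as.character(Biostrings::subseq(r1, 8L, 8L))
  expect_true(all(b1 == "C"))
  n <- 10000L
  rr <- simulate_bisulfite_amplicon(amp, 7L, m5c_fraction = 0.755,
                                    n_reads = n, seed = 3)
  frac <- mean(as.character(Biostrings::subseq(rr, 8L, 8L)) == "C")
  expect_lt(abs(frac - 0.755), 3 * sqrt(0.755 * 0.245 / n))
  expect_equal(length(rr), n)
  # deterministic per seed
  rr2 <- simulate_bisulfite_amplicon(amp, 7L, m5c_fraction = 0.755,
                                     n_reads = 50, seed = 9)
  rr3 <- simulate_bisulfite_amplicon(amp, 7L, m5c_fraction = 0.755,
                                     n_reads = 50, seed = 9)
  expect_identical(as.character(rr2), as.character(rr3))
})

test_that("simulated Sanger traces are normalised and split as requested", {
  tr0 <- simulate_sanger_trace(0, "GATCA", 3L)
  expect_true(all(abs(rowSums(tr0[, c("A", "C", "G", "T")]) - 1) < 1e-12))
  expect_true(all(apply(tr0[, c("A", "C", "G", "T")], 1, max) == 1))
  tr <- simulate_sanger_trace(0.136, "GATCA", 3L)
  expect_equal(tr$C[4], 0.864)
  expect_equal(tr$T[4], 0.136)
  expect_true(all(abs(rowSums(tr[, c("A", "C", "G", "T")]) - 1) < 1e-12))
  expect_error(simulate_sanger_trace(0.2, "GGTGG", 1L), "A or a C")
})
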