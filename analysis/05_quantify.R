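#!/usr/bin/env Rscript
# Site-level quantification outside the transcriptome-wide caller:
# bisulfite-amplicon methylation fractions at the two validated target
# sites, Sanger-trace edit rates for both editors, and replicate
# correlations of per-mRNA mutation counts.

suppressPackageStartupMessages(library(dramseq))

sim <- "results/analysis/sim"
out <- "results/analysis/quant"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
seed <- 20260923L

reference <- Biostrings::readDNAStringSet(file.path(sim, "reference.fa"))
names(reference) <- sub(" .*", "", names(reference))
truth <- read_truth(file.path(sim, "truth_cbe.tsv"))

# bisulfite amplicons at the two validated methylation fractions, taking the
# first two planted sites as the amplified targets
bs_truth <- truth[1:2, ]
bs_truth$m5c_fraction <- c(0.755, 0.2725)
bs_rows <- list()
for (i in 1:2) {
  tr <- bs_truth[i, ]
  contig <- as.character(reference[[tr$chrom]])
  lo <- max(1L, tr$gpos + 1L - 60L)
  hi <- min(nchar(contig), tr$gpos + 1L + 60L)
  amp <- substring(contig, lo, hi)
  site_pos <- tr$gpos + 1L - lo            # 0-based within the amplicon
  if (tr$strand == "-") {
    amp <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(amp)))
    site_pos <- (hi - lo) - site_pos
  }
  reads <- simulate_bisulfite_amplicon(amp, site_pos, tr$m5c_fraction,
                                       n_reads = 10000L,
                                       conversion_efficiency = 1,
                                       seed = seed + i)
  q <- bisulfite_fraction(reads, amp, site_pos)
  q$site_id <- tr$site_id
  q$true_fraction <- 100 * tr$m5c_fraction
  bs_rows[[i]] <- q
  message(sprintf(
    "%s: planted m5C fraction %.2f%%, recovered %.2f%% (%d reads, QC %s)",
    tr$site_id, 100 * tr$m5c_fraction, q$fraction, q$n_reads,
    ifelse(q$qc_pass, "pass", "fail")))
}
utils::write.table(do.call(rbind, bs_rows),
                   file.path(out, "bisulfite_fractions.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)

# Sanger-trace quantification at the validated site-level edit rates
sanger <- data.frame(editor = c("ABE", "CBE"), conversion = c("A2G", "C2U"),
                     edit_rate = c(0.147, 0.136))
flank <- "GGTACTAGG"  # A at offset 3 used for ABE, C at offset 4 for CBE
sanger$position <- c(3L, 4L)
sanger$measured_pct <- NA_real_
for (i in 1:2) {
  trc <- simulate_sanger_trace(sanger$edit_rate[i], flank,
                               sanger$position[i])
  sanger$measured_pct[i] <- sanger_edit_rate(trc, sanger$position[i],
                                             sanger$conversion[i])
  message(sprintf("%s Sanger trace: %.1f%% %s editing recovered",
                  sanger$editor[i], sanger$measured_pct[i],
                  sanger$conversion[i]))
}
utils::write.table(sanger, file.path(out, "sanger_rates.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)

# replicate correlation over all DRAM replicate pairs (CBE arm)
genes <- read_gene_model(file.path(sim, "genes.bed"))
sams <- list.files(file.path(sim, "cbe"), pattern = "^dram_rep.*\\.sam$",
                   full.names = TRUE)
counts <- lapply(sams, function(s)
  per_gene_edit_counts(extract_candidates(build_pileup(s, reference),
                                          genes, "C2U")))
pairs <- utils::combn(length(counts), 2)
cors <- apply(pairs, 2, function(p)
  replicate_correlation(counts[[p[1]]], counts[[p[2]]]))
cor_tab <- data.frame(rep_a = pairs[1, ], rep_b = pairs[2, ],
                      pearson_r = cors)
utils::write.table(cor_tab, file.path(out, "replicate_correlation.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
message(sprintf("replicate per-mRNA mutation-count correlations: %s",
                paste(sprintf("%.3f", cors), collapse = ", ")))
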