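#!/usr/bin/env Rscript
# Build the synthetic study: a 50-transcript transcriptome, 100 planted m5C
# sites, and condition-specific alignments for the CBE arm of the assay
# (DRAM x3, reader-mutant x1, deaminase-only x2, knockout x3), plus a
# scaled-down ABE arm used for the cross-editor gene merge.

suppressPackageStartupMessages(library(dramseq))

out <- "results/analysis/sim"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
seed <- 20260923L

world <- generate_transcriptome(50, c(800L, 2000L), seed = seed)
Biostrings::writeXStringSet(world$reference, file.path(out, "reference.fa"))
write_gene_model(world$genes, file.path(out, "genes.bed"))

truth_cbe <- plant_m5c_sites(world$genes, world$reference, 100,
                             rate_range = c(0.3, 0.3), editor = "CBE",
                             seed = seed + 1L)
write_truth(truth_cbe, file.path(out, "truth_cbe.tsv"))
truth_abe <- plant_m5c_sites(world$genes, world$reference, 40,
                             rate_range = c(0.3, 0.3), editor = "ABE",
                             seed = seed + 2L)
write_truth(truth_abe, file.path(out, "truth_abe.tsv"))

specs <- default_condition_specs(seed = seed, coverage_mean = 100,
                                 error_rate = 0.001)
for (cond in names(specs)) {
  sams <- simulate_reads(world$genes, world$reference, truth_cbe,
                         specs[[cond]], out_dir = file.path(out, "cbe"))
  message(sprintf("CBE %-14s -> %d replicate SAM file(s)", cond,
                  length(sams)))
}
abe_specs <- default_condition_specs(seed = seed + 50L, coverage_mean = 100,
                                     error_rate = 0.001)
for (cond in c("DRAM", "KNOCKOUT")) {
  sams <- simulate_reads(world$genes, world$reference, truth_abe,
                         abe_specs[[cond]], out_dir = file.path(out, "abe"))
  message(sprintf("ABE %-14s -> %d replicate SAM file(s)", cond,
                  length(sams)))
}
message("planted ", nrow(truth_cbe), " CBE and ", nrow(truth_abe),
        " ABE m5C sites; inputs under ", out)
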