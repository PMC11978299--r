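#!/usr/bin/env Rscript
# Gene-structure context of the called sites: region assignment, metagene
# density over scaled 5'UTR/CDS/3'UTR coordinates, and signed distances
# from the planted m5C sites (standing in for a BS-seq reference list) to
# the nearest called edit.

suppressPackageStartupMessages(library(dramseq))

sim <- "results/analysis/sim"
calls <- "results/analysis/calls"
out <- "results/analysis/annotation"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

genes <- read_gene_model(file.path(sim, "genes.bed"))
truth <- read_truth(file.path(sim, "truth_cbe.tsv"))
sites <- read_candidates(file.path(calls, "cbe_sites.tsv"))

regions <- assign_region(sites, genes)
utils::write.table(regions, file.path(out, "regions.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)
tab <- table(regions$region)
message("region distribution of called sites:")
for (r in names(tab)) message(sprintf("  %-10s %5d (%.1f%%)", r, tab[[r]],
                                      100 * tab[[r]] / sum(tab)))

prof <- metagene_profile(regions, n_bins = 90L)
utils::write.table(prof, file.path(out, "metagene.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)
seg <- findInterval(prof$bin_mid, c(0, 1, 2, 3))
mass <- tapply(prof$density, seg, sum)
message(sprintf(
  "metagene mass: 5'UTR %.2f, CDS %.2f, 3'UTR %.2f (sums to %.3f)",
  mass[["1"]], mass[["2"]], mass[["3"]], sum(prof$density)))

ref_sites <- data.frame(chrom = truth$chrom, pos = truth$gpos,
                        strand = truth$strand)
for (win in c(3000L, 80L)) {
  rec <- distance_to_reference(sites, ref_sites, window = win)
  hist <- distance_histogram(rec, window = win)
  utils::write.table(rec, file.path(out, sprintf("distances_%d.tsv", win)),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(hist, file.path(out, sprintf("distance_hist_%d.tsv",
                                                  win)),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  message(sprintf(
    "window %4d nt: %d/%d reference sites matched; %.1f%% of nearest edits within +/-20 nt",
    win, nrow(rec), nrow(ref_sites),
    100 * mean(abs(rec$signed_distance) <= 20)))
}
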