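#!/usr/bin/env Rscript
# Pileup, candidate extraction and the comparative filter cascade:
# replicated DRAM sites filtered against pooled knockout ratios, minus
# anything seen in the deaminase-only control, then the high-confidence
# tier and the cross-editor gene merge.

suppressPackageStartupMessages(library(dramseq))

sim <- "results/analysis/sim"
out <- "results/analysis/calls"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

reference <- Biostrings::readDNAStringSet(file.path(sim, "reference.fa"))
names(reference) <- sub(" .*", "", names(reference))
genes <- read_gene_model(file.path(sim, "genes.bed"))

arm_candidates <- function(arm, conv) {
  sams <- list.files(file.path(sim, arm), pattern = "\\.sam$",
                     full.names = TRUE)
  lapply(stats::setNames(sams, basename(sams)), function(s) {
    cond <- sub("_rep.*", "", basename(s))
    extract_candidates(build_pileup(s, reference), genes, conv,
                       keep_zero = (cond == "knockout"))
  })
}

call_arm <- function(arm, conv) {
  cands <- arm_candidates(arm, conv)
  dram <- cands[grepl("^dram_rep", names(cands))]
  ko <- pool_candidates(cands[grepl("^knockout", names(cands))])
  deam <- cands[grepl("^deaminase", names(cands))]
  sites <- call_replicated_sites(unname(dram), ko, filter_params())
  n_rep <- nrow(sites)
  if (length(deam)) sites <- subtract_background(sites, pool_candidates(deam))
  hc <- high_confidence_tier(sites, high_confidence_params())
  message(sprintf(
    "%s arm: %d replicated sites, %d after background subtraction, %d high-confidence",
    toupper(arm), n_rep, nrow(sites), nrow(hc)))
  # replicate agreement on per-mRNA mutation counts (first two replicates)
  r <- replicate_correlation(per_gene_edit_counts(dram[[1]]),
                             per_gene_edit_counts(dram[[2]]))
  message(sprintf("%s arm: Pearson r between replicate per-mRNA mutation counts = %.3f",
                  toupper(arm), r))
  write_candidates(sites, file.path(out, paste0(arm, "_sites.tsv")))
  write_candidates(hc, file.path(out, paste0(arm, "_sites_hc.tsv")))
  write_sites_bed(sites, file.path(out, paste0(arm, "_sites.bed")))
  sites
}

cbe_sites <- call_arm("cbe", "C2U")
abe_sites <- call_arm("abe", "A2G")

merged <- merge_editor_genes(abe_sites, cbe_sites, genes)
utils::write.table(merged, file.path(out, "merged_genes.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)
message(sprintf("merged gene table: %d genes (%d supported by both editors)",
                nrow(merged), sum(merged$editors == "ABE+CBE")))
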