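#!/usr/bin/env Rscript
# Sequence context of the called sites: +/-20 nt gene-strand flanks and the
# position frequency matrix with per-column information content (the data
# behind a sequence logo).

suppressPackageStartupMessages(library(dramseq))

sim <- "results/analysis/sim"
calls <- "results/analysis/calls"
out <- "results/analysis/motif"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

reference <- Biostrings::readDNAStringSet(file.path(sim, "reference.fa"))
names(reference) <- sub(" .*", "", names(reference))

for (arm in c("cbe", "abe")) {
  sites <- read_candidates(file.path(calls, paste0(arm, "_sites.tsv")))
  fl <- extract_flanks(sites, reference, k = 20L)
  seqs <- Biostrings::DNAStringSet(fl)
  names(seqs) <- sprintf("%s_site%04d", arm, seq_along(fl))
  Biostrings::writeXStringSet(seqs, file.path(out, paste0(arm, "_flanks.fa")))
  pfm <- build_pfm(fl)
  write_pfm(pfm, file.path(out, paste0(arm, "_pfm.tsv")))
  centre <- pfm[pfm$offset == 0L, ]
  message(sprintf(
    "%s arm: %d flanks; centre base %s at frequency %.2f, IC %.2f bits",
    toupper(arm), length(fl), if (arm == "cbe") "C" else "A",
    if (arm == "cbe") centre$C else centre$A, centre$ic))
}
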