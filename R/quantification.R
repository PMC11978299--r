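#' Edit rate from a Sanger base-proportion trace
#'
#' Reads the deamination-product proportion at the queried position from a
#' per-position base-proportion table, enforcing the expected conversion
#' pair: C-to-U traces split between C and T, A-to-G traces between A and G.
#' When `conversion` is omitted the pair whose proportions account for the
#' column is used.
#'
#' @param trace `data.frame` with columns `pos`, `A`, `C`, `G`, `T`
#'   ([simulate_sanger_trace()] emits this shape).
#' @param position 0-based position to quantify.
#' @param conversion `"C2U"`, `"A2G"`, or `NULL` to infer.
#' @return the edit rate as a percentage.
#' @export
sanger_edit_rate <- function(trace, position, conversion = NULL) {
  row <- trace[trace$pos == position, , drop = FALSE]
  if (nrow(row) != 1L) stop("position not present in trace", call. = FALSE)
  pairs <- list(C2U = c("C", "T"), A2G = c("A", "G"))
  if (is.null(conversion)) {
    sums <- vapply(pairs, function(p) row[[p[1]]] + row[[p[2]]], 0)
    conversion <- names(pairs)[which.max(sums)]
  }
  conversion <- match.arg(conversion, names(pairs))
  p <- pairs[[conversion]]
  tot <- row[[p[1]]] + row[[p[2]]]
  if (tot <= 0) stop(sprintf("no %s/%s signal at position %d", p[1], p[2],
                             position), call. = FALSE)
  100 * row[[p[2]]] / tot
}

#' Methylation fraction from bisulfite amplicon reads
#'
#' Quantifies the methylated fraction at one cytosine of an amplicon from
#' bisulfite-converted deep-sequencing reads: retained C counts as
#' methylated, converted T as unmethylated; any other base (sequencing
#' error) is excluded from the denominator. The QC flag requires more than
#' 1000 reads.
#'
#' @param reads a [Biostrings::DNAStringSet] or path to a FASTQ/FASTA file;
#'   reads must span the amplicon (exact positional anchoring, as emitted by
#'   [simulate_bisulfite_amplicon()]).
#' @param amplicon_reference amplicon sequence (character or DNAString).
#' @param site_position 0-based position of the interrogated C.
#' @param min_reads_qc read count that must be exceeded for `qc_pass`.
#' @return a one-row `data.frame`: `site_position`, `n_reads`, `retained_c`,
#'   `converted_t`, `fraction` (percent), `qc_pass`.
#' @export
bisulfite_fraction <- function(reads, amplicon_reference, site_position,
                               min_reads_qc = 1000L) {
  if (is.character(reads) && length(reads) == 1L && file.exists(reads)) {
    fmt <- if (grepl("\\.(fq|fastq)(\\.gz)?$", reads)) "fastq" else "fasta"
    reads <- Biostrings::readDNAStringSet(reads, format = fmt)
  }
  amp <- as.character(amplicon_reference)
  if (base_at(amp, site_position + 1L) != "C") {
    stop("site_position must index a C in the amplicon reference",
         call. = FALSE)
  }
  if (!all(Biostrings::width(reads) == nchar(amp))) {
    stop("reads must span the full amplicon", call. = FALSE)
  }
  bases <- as.character(Biostrings::subseq(reads, site_position + 1L,
                                           site_position + 1L))
  retained <- sum(bases == "C")
  converted <- sum(bases == "T")
  denom <- retained + converted
  data.frame(site_position = site_position, n_reads = length(reads),
             retained_c = retained, converted_t = converted,
             fraction = if (denom > 0) 100 * retained / denom else NA_real_,
             qc_pass = length(reads) > min_reads_qc)
}

#' Pearson correlation of per-gene mutation counts between replicates
#'
#' Vectors are aligned on the union of gene names, with genes absent from
#' one replicate counted as 0. Returns `NA` with a warning when either
#' aligned vector is constant.
#'
#' @param counts_a,counts_b named numeric vectors of per-gene mutation
#'   counts.
#' @return the Pearson correlation coefficient.
#' @export
replicate_correlation <- function(counts_a, counts_b) {
  if (is.null(names(counts_a)) || is.null(names(counts_b))) {
    stopifnot(length(counts_a) == length(counts_b))
    a <- as.numeric(counts_a)
    b <- as.numeric(counts_b)
  } else {
    genes <- union(names(counts_a), names(counts_b))
    a <- as.numeric(counts_a[genes]); a[is.na(a)] <- 0
    b <- as.numeric(counts_b[genes]); b[is.na(b)] <- 0
  }
  if (stats::var(a) == 0 || stats::var(b) == 0) {
    warning("correlation undefined for a constant count vector")
    return(NA_real_)
  }
  stats::cor(a, b)
}

#' Per-gene edited-read counts from a candidate table
#'
#' Convenience summary feeding [replicate_correlation()]: sums edited reads
#' of one conversion class per gene.
#'
#' @param candidates candidate `data.frame` ([extract_candidates()]).
#' @return named integer vector of per-gene edited-read counts.
#' @export
per_gene_edit_counts <- function(candidates) {
  cand <- candidates[!is.na(candidates$gene_id), , drop = FALSE]
  if (!nrow(cand)) return(stats::setNames(integer(0), character(0)))
  tapply(cand$edited, cand$gene_id, sum)
}
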