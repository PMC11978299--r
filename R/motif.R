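#' Extract gene-strand flanking sequences around called sites
#'
#' Returns the `2k + 1` nt sequence centred on each edited base, taken on
#' the gene strand (minus-strand sites yield reverse-complemented genomic
#' sequence), so the centre base is always the editable base of the
#' conversion (C for C-to-U, A for A-to-G). Sites closer than `k` to a
#' contig end are padded with `N` and flagged.
#'
#' @param called_sites called-site `data.frame` (`chrom`, `pos`, `strand`).
#' @param reference contig sequences.
#' @param k flank half-width, nt (default 20).
#' @return a character vector of flanks with attribute `padded` (logical).
#' @export
extract_flanks <- function(called_sites, reference, k = 20L) {
  n <- nrow(called_sites)
  out <- character(n)
  padded <- logical(n)
  widths <- stats::setNames(Biostrings::width(reference), names(reference))
  for (i in seq_len(n)) {
    chrom <- called_sites$chrom[i]
    pos <- called_sites$pos[i]
    L <- widths[[chrom]]
    lo <- pos - k
    hi <- pos + k
    clip_lo <- max(0L, lo)
    clip_hi <- min(L - 1L, hi)
    core <- substring(as.character(reference[[chrom]]), clip_lo + 1L,
                      clip_hi + 1L)
    seqi <- paste0(strrep("N", clip_lo - lo), core, strrep("N", hi - clip_hi))
    padded[i] <- clip_lo > lo || hi > clip_hi
    if (called_sites$strand[i] == "-") {
      seqi <- revcomp(chartr("N", "N", seqi))
    }
    out[i] <- seqi
  }
  attr(out, "padded") <- padded
  out
}

#' Position frequency matrix and information content of flank sequences
#'
#' Computes per-column base frequencies over A/C/G/U (T is reported as U,
#' the transcript alphabet) with `N`-padded cells excluded from the column
#' denominator, and the information content per column as
#' `2 - H` bits, where `H` is the Shannon entropy against a uniform
#' background.
#'
#' @param flanks character vector of equal-length sequences
#'   ([extract_flanks()]).
#' @return a `data.frame` with `offset` (centre = 0), `A`, `C`, `G`, `U`,
#'   `ic`; attribute `n_sequences` records the input size.
#' @export
build_pfm <- function(flanks) {
  stopifnot(length(flanks) >= 1L)
  w <- unique(nchar(flanks))
  if (length(w) != 1L) stop("flank sequences must share one length",
                            call. = FALSE)
  mat <- Biostrings::consensusMatrix(Biostrings::DNAStringSet(flanks))
  need <- c(DNA_BASES, "N")
  counts <- matrix(0L, length(need), w, dimnames = list(need, NULL))
  have <- intersect(rownames(mat), need)
  counts[have, ] <- mat[have, , drop = FALSE]
  denom <- colSums(counts[DNA_BASES, , drop = FALSE])
  freq <- sweep(counts[DNA_BASES, , drop = FALSE], 2L, pmax(denom, 1L), "/")
  h <- apply(freq, 2L, function(p) {
    p <- p[p > 0]
    -sum(p * log2(p))
  })
  ic <- ifelse(denom > 0, 2 - h, NA_real_)
  k <- (w - 1L) %/% 2L
  out <- data.frame(offset = seq_len(w) - k - 1L,
                    A = freq["A", ], C = freq["C", ], G = freq["G", ],
                    U = freq["T", ], ic = ic)
  rownames(out) <- NULL
  attr(out, "n_sequences") <- length(flanks)
  out
}

#' Write a position frequency matrix as TSV
#'
#' @param pfm output of [build_pfm()].
#' @param path TSV path.
#' @return `path`, invisibly.
#' @export
write_pfm <- function(pfm, path) {
  utils::write.table(pfm, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
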