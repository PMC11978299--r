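#' Gene models
#'
#' A gene model is a plain `data.frame` with one row per transcript and the
#' twelve BED12 fields (0-based, half-open genomic coordinates), where
#' `block_sizes` and `block_starts` are integer list-columns. The thick
#' interval delimits the CDS; the untranslated regions are inferred from it
#' and the transcript strand. Transcript-space coordinates run 5' to 3' on
#' the sense strand, 0-based.
#'
#' @name gene_model
NULL

new_gene_model <- function(chrom, start, end, name, strand,
                           thick_start, thick_end,
                           block_sizes, block_starts) {
  stopifnot(length(chrom) == length(start), all(strand %in% c("+", "-")))
  df <- data.frame(
    chrom = chrom, start = as.integer(start), end = as.integer(end),
    name = name, score = 0L, strand = strand,
    thick_start = as.integer(thick_start), thick_end = as.integer(thick_end),
    item_rgb = "0", block_count = lengths(block_sizes),
    stringsAsFactors = FALSE
  )
  df$block_sizes <- lapply(block_sizes, as.integer)
  df$block_starts <- lapply(block_starts, as.integer)
  class(df) <- c("gene_model", "data.frame")
  df
}

#' Write a gene model to BED12
#'
#' @param genes a gene model `data.frame` (see [gene_model]).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gene_model <- function(genes, path) {
  fmt_list <- function(l) vapply(l, function(x) paste(x, collapse = ","), "")
  out <- data.frame(
    genes$chrom, genes$start, genes$end, genes$name, genes$score,
    genes$strand, genes$thick_start, genes$thick_end, genes$item_rgb,
    genes$block_count, fmt_list(genes$block_sizes), fmt_list(genes$block_starts)
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED12 gene model
#'
#' @param path BED12 file, 0-based half-open.
#' @return a gene model `data.frame`.
#' @export
read_gene_model <- function(path) {
  raw <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE,
                           col.names = c("chrom", "start", "end", "name",
                                         "score", "strand", "thick_start",
                                         "thick_end", "item_rgb",
                                         "block_count", "block_sizes",
                                         "block_starts"))
  split_ints <- function(x) lapply(strsplit(as.character(x), ","), as.integer)
  new_gene_model(raw$chrom, raw$start, raw$end, raw$name, raw$strand,
                 raw$thick_start, raw$thick_end,
                 split_ints(raw$block_sizes), split_ints(raw$block_starts))
}

# Genomic block intervals of one gene-model row: matrix [start, end) per exon.
gene_blocks <- function(gene) {
  bs <- gene$block_starts[[1]] + gene$start
  cbind(start = bs, end = bs + gene$block_sizes[[1]])
}

tx_length <- function(gene) sum(gene$block_sizes[[1]])

# Map genomic positions (0-based) to transcript coordinates (0-based, 5'->3'
# on the sense strand). Non-exonic positions map to NA.
genomic_to_tx <- function(gene, gpos) {
  blocks <- gene_blocks(gene)
  off <- c(0L, cumsum(blocks[, "end"] - blocks[, "start"]))
  L <- tx_length(gene)
  plus <- rep(NA_integer_, length(gpos))
  for (j in seq_len(nrow(blocks))) {
    inb <- !is.na(gpos) & gpos >= blocks[j, "start"] & gpos < blocks[j, "end"]
    plus[inb] <- off[j] + gpos[inb] - blocks[j, "start"]
  }
  if (gene$strand == "+") plus else ifelse(is.na(plus), NA_integer_, L - 1L - plus)
}

# Inverse of genomic_to_tx; tpos must lie in [0, tx_length).
tx_to_genomic <- function(gene, tpos) {
  L <- tx_length(gene)
  stopifnot(all(tpos >= 0 & tpos < L))
  plus <- if (gene$strand == "+") tpos else L - 1L - tpos
  blocks <- gene_blocks(gene)
  off <- c(0L, cumsum(blocks[, "end"] - blocks[, "start"]))
  out <- integer(length(plus))
  for (j in seq_len(nrow(blocks))) {
    inb <- plus >= off[j] & plus < off[j + 1L]
    out[inb] <- blocks[j, "start"] + plus[inb] - off[j]
  }
  out
}

# Transcript-space segment lengths (5'UTR, CDS, 3'UTR) of one gene-model row.
gene_segments <- function(gene) {
  blocks <- gene_blocks(gene)
  cds_len <- sum(pmax(0L, pmin(blocks[, "end"], gene$thick_end) -
                        pmax(blocks[, "start"], gene$thick_start)))
  L <- tx_length(gene)
  if (cds_len == 0L) {
    return(c(utr5 = 0L, cds = 0L, utr3 = 0L, tx = L))
  }
  first_cds_g <- if (gene$strand == "+") gene$thick_start else gene$thick_end - 1L
  utr5 <- genomic_to_tx(gene, first_cds_g)
  c(utr5 = as.integer(utr5), cds = as.integer(cds_len),
    utr3 = as.integer(L - utr5 - cds_len), tx = L)
}

# Region label of transcript-space positions for one gene: UTR5/CDS/UTR3.
tx_region <- function(gene, tpos) {
  seg <- gene_segments(gene)
  ifelse(tpos < seg["utr5"], "UTR5",
         ifelse(tpos < seg["utr5"] + seg["cds"], "CDS", "UTR3"))
}

# Sense-strand transcript sequence of one gene as a character scalar.
transcript_seq <- function(reference, gene) {
  blocks <- gene_blocks(gene)
  contig <- as.character(reference[[gene$chrom]])
  pieces <- substring(contig, blocks[, "start"] + 1L, blocks[, "end"])
  s <- paste(pieces, collapse = "")
  if (gene$strand == "-") revcomp(s) else s
}
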