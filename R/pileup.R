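#' Build a per-position nucleotide pileup from alignments
#'
#' Tallies read bases per reference position after excluding secondary,
#' supplementary and duplicate-flagged alignments and applying base- and
#' mapping-quality floors. SAM input is converted, coordinate-sorted and
#' indexed internally; BAM input is sorted/indexed into a temporary copy when
#' needed. Positions with zero retained depth are omitted.
#'
#' @param alignments path to a SAM or BAM file.
#' @param reference contig sequences ([Biostrings::DNAStringSet]) matching
#'   the alignment header.
#' @param min_base_quality minimum Phred base quality (default 20).
#' @param min_mapping_quality minimum mapping quality (default 20).
#' @return a `data.frame` with columns `chrom`, `pos` (0-based), `ref_base`,
#'   `A`, `C`, `G`, `T`, `N`, `depth`, where `depth = A+C+G+T+N`.
#' @export
build_pileup <- function(alignments, reference,
                         min_base_quality = 20L, min_mapping_quality = 20L) {
  bam <- as_sorted_bam(alignments)
  hdr <- Rsamtools::scanBamHeader(bam)[[1]]$targets
  missing <- setdiff(names(hdr), names(reference))
  if (length(missing)) {
    stop(sprintf("alignment contig(s) absent from reference: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  bad_len <- names(hdr)[hdr != Biostrings::width(reference)[match(names(hdr),
                                                       names(reference))]]
  if (length(bad_len)) {
    stop(sprintf("contig length mismatch vs reference: %s",
                 paste(bad_len, collapse = ", ")), call. = FALSE)
  }
  sbp <- Rsamtools::ScanBamParam(
    flag = Rsamtools::scanBamFlag(isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE,
                                  isDuplicate = FALSE,
                                  isUnmappedQuery = FALSE))
  pp <- Rsamtools::PileupParam(max_depth = 1000000L,
                               min_base_quality = as.integer(min_base_quality),
                               min_mapq = as.integer(min_mapping_quality),
                               min_nucleotide_depth = 1L,
                               distinguish_strands = FALSE,
                               distinguish_nucleotides = TRUE,
                               include_deletions = FALSE,
                               include_insertions = FALSE)
  p <- Rsamtools::pileup(bam, scanBamParam = sbp, pileupParam = pp)
  if (nrow(p) == 0L) {
    return(data.frame(chrom = character(0), pos = integer(0),
                      ref_base = character(0), A = integer(0), C = integer(0),
                      G = integer(0), T = integer(0), N = integer(0),
                      depth = integer(0), stringsAsFactors = FALSE))
  }
  chrom <- as.character(p$seqnames)
  key <- paste0(chrom, ":", p$pos)
  uk <- !duplicated(key)
  out_chrom <- chrom[uk]
  out_pos1 <- p$pos[uk]
  m <- matrix(0L, sum(uk), 5L, dimnames = list(NULL, c(DNA_BASES, "N")))
  i <- match(key, key[uk])
  j <- match(as.character(p$nucleotide), colnames(m))
  keep <- !is.na(j)
  m[cbind(i[keep], j[keep])] <- p$count[keep]
  ref_base <- character(length(out_pos1))
  for (ctg in unique(out_chrom)) {
    sel <- out_chrom == ctg
    ref_base[sel] <- base_at(as.character(reference[[ctg]]), out_pos1[sel])
  }
  out <- data.frame(chrom = out_chrom, pos = out_pos1 - 1L,
                    ref_base = ref_base, A = m[, "A"], C = m[, "C"],
                    G = m[, "G"], T = m[, "T"], N = m[, "N"],
                    depth = as.integer(rowSums(m)), stringsAsFactors = FALSE)
  out <- out[order(match(out$chrom, names(reference)), out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Coerce a SAM/BAM path into a coordinate-sorted, indexed BAM path.
as_sorted_bam <- function(alignments) {
  stopifnot(file.exists(alignments))
  if (grepl("\\.sam$", alignments, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- Rsamtools::asBam(alignments, destination = dest, overwrite = TRUE,
                            indexDestination = TRUE)
    return(bam)
  }
  bai <- paste0(alignments, ".bai")
  if (file.exists(bai)) return(alignments)
  sorted <- Rsamtools::sortBam(alignments, tempfile())
  Rsamtools::indexBam(sorted)
  sorted
}

#' Extract candidate editing events from a pileup
#'
#' Interprets base counts as deamination candidates of one conversion class
#' relative to the gene strand: C-to-U on a plus-strand gene reads as C/T
#' counts in reference space, on a minus-strand gene as G/A counts (and
#' correspondingly A-to-G as A/G or T/C). Positions covered by genes on both
#' strands yield one candidate per strand, flagged ambiguous; positions
#' outside any gene are evaluated on both strands (gene-less candidates).
#'
#' @param pileup output of [build_pileup()].
#' @param genes gene model.
#' @param conversion `"C2U"` or `"A2G"`.
#' @param keep_zero keep positions whose edited-read count is zero (needed
#'   for knockout controls, where covered-but-unedited evidence matters);
#'   default drops them.
#' @return a `data.frame` with columns `chrom`, `pos` (0-based), `strand`
#'   (gene strand evaluated), `conversion`, `ref_base`, `coverage`,
#'   `edited`, `ratio`, `gene_id`, `ambiguous`.
#' @export
extract_candidates <- function(pileup, genes, conversion = c("C2U", "A2G"),
                               keep_zero = FALSE) {
  conversion <- match.arg(conversion)
  if (nrow(pileup) == 0L) return(empty_candidates())
  # per-strand reference base and edited ("alt") base in reference space
  ref_plus <- if (conversion == "C2U") "C" else "A"
  alt_plus <- if (conversion == "C2U") "T" else "G"
  ref_minus <- complement_base(ref_plus)
  alt_minus <- complement_base(alt_plus)

  pu_gr <- GenomicRanges::GRanges(pileup$chrom,
                                  IRanges::IRanges(pileup$pos + 1L,
                                                   width = 1L))
  gene_gr <- GenomicRanges::GRanges(genes$chrom,
                                    IRanges::IRanges(genes$start + 1L,
                                                     genes$end))
  hits <- GenomicRanges::findOverlaps(pu_gr, gene_gr, ignore.strand = TRUE)
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)

  rows <- data.frame(pu = qh, strand = genes$strand[sh],
                     gene_id = genes$name[sh], stringsAsFactors = FALSE)
  # ambiguity: the same pileup position hit by genes on both strands
  both <- tapply(rows$strand, rows$pu, function(s) length(unique(s)) > 1L)
  rows$ambiguous <- unname(both[as.character(rows$pu)])
  # intergenic positions: evaluate both strands, no gene
  inter <- setdiff(seq_len(nrow(pileup)), unique(qh))
  if (length(inter)) {
    rows <- rbind(rows,
                  data.frame(pu = rep(inter, 2L),
                             strand = rep(c("+", "-"), each = length(inter)),
                             gene_id = NA_character_, ambiguous = FALSE,
                             stringsAsFactors = FALSE))
  }

  rb <- pileup$ref_base[rows$pu]
  want_ref <- ifelse(rows$strand == "+", ref_plus, ref_minus)
  keep <- rb == want_ref
  rows <- rows[keep, , drop = FALSE]
  if (nrow(rows) == 0L) return(empty_candidates())
  alt <- ifelse(rows$strand == "+", alt_plus, alt_minus)
  counts <- as.matrix(pileup[rows$pu, DNA_BASES])
  edited <- counts[cbind(seq_len(nrow(rows)), match(alt, DNA_BASES))]
  coverage <- pileup$depth[rows$pu]
  out <- data.frame(chrom = pileup$chrom[rows$pu], pos = pileup$pos[rows$pu],
                    strand = rows$strand, conversion = conversion,
                    ref_base = pileup$ref_base[rows$pu],
                    coverage = coverage, edited = as.integer(edited),
                    ratio = edited / coverage, gene_id = rows$gene_id,
                    ambiguous = rows$ambiguous, stringsAsFactors = FALSE)
  if (!keep_zero) out <- out[out$edited > 0L, , drop = FALSE]
  out <- out[order(out$chrom, out$pos, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_candidates <- function() {
  data.frame(chrom = character(0), pos = integer(0), strand = character(0),
             conversion = character(0), ref_base = character(0),
             coverage = integer(0), edited = integer(0), ratio = numeric(0),
             gene_id = character(0), ambiguous = logical(0),
             stringsAsFactors = FALSE)
}

#' Write / read a candidate table as TSV
#'
#' @param candidates candidate `data.frame` from [extract_candidates()].
#' @param path TSV path.
#' @return `path` (write) or the candidate `data.frame` (read).
#' @export
write_candidates <- function(candidates, path) {
  utils::write.table(candidates, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_candidates
#' @export
read_candidates <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    na.strings = "NA")
}
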