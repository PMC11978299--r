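#' Assign called sites to transcript regions
#'
#' Labels each site as 5'UTR, CDS, 3'UTR, intron or intergenic, and computes
#' the metagene coordinate for exonic mRNA sites: position rescaled within
#' its segment to `[0,1)` (5'UTR), `[1,2)` (CDS) or `[2,3)` (3'UTR). When a
#' site falls in several isoforms the label follows the precedence
#' CDS > 5'UTR > 3'UTR > intron, ties broken by the longest transcript.
#' Sites carrying a `strand` column are only matched to genes on that
#' strand.
#'
#' @param sites `data.frame` with `chrom`, `pos` (0-based) and optionally
#'   `strand`.
#' @param genes gene model.
#' @return the input with `region`, `metagene_coordinate` and
#'   `region_gene_id` columns appended.
#' @export
assign_region <- function(sites, genes) {
  n <- nrow(sites)
  region <- rep("intergenic", n)
  coord <- rep(NA_real_, n)
  gene_id <- rep(NA_character_, n)
  if (n == 0L) {
    sites$region <- character(0)
    sites$metagene_coordinate <- numeric(0)
    sites$region_gene_id <- character(0)
    return(sites)
  }
  prec <- c(CDS = 1L, UTR5 = 2L, UTR3 = 3L, intron = 4L)
  has_strand <- "strand" %in% names(sites)
  site_gr <- GenomicRanges::GRanges(sites$chrom,
                                    IRanges::IRanges(sites$pos + 1L, width = 1L))
  gene_gr <- GenomicRanges::GRanges(genes$chrom,
                                    IRanges::IRanges(genes$start + 1L,
                                                     genes$end))
  hits <- GenomicRanges::findOverlaps(site_gr, gene_gr, ignore.strand = TRUE)
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  for (i in unique(qh)) {
    gidx <- sh[qh == i]
    if (has_strand && !is.na(sites$strand[i])) {
      gidx <- gidx[genes$strand[gidx] == sites$strand[i]]
    }
    if (!length(gidx)) next
    best <- NULL
    for (g in gidx) {
      gene <- genes[g, ]
      tpos <- genomic_to_tx(gene, sites$pos[i])
      if (is.na(tpos)) {
        lab <- "intron"; mg <- NA_real_
      } else {
        seg <- gene_segments(gene)
        if (tpos < seg["utr5"]) {
          lab <- "UTR5"; mg <- tpos / seg["utr5"]
        } else if (tpos < seg["utr5"] + seg["cds"]) {
          lab <- "CDS"; mg <- 1 + (tpos - seg["utr5"]) / seg["cds"]
        } else {
          lab <- "UTR3"; mg <- 2 + (tpos - seg["utr5"] - seg["cds"]) / seg["utr3"]
        }
      }
      cand <- list(lab = lab, mg = unname(mg), gene = gene$name,
                   len = tx_length(gene))
      if (is.null(best) ||
          prec[cand$lab] < prec[best$lab] ||
          (prec[cand$lab] == prec[best$lab] && cand$len > best$len)) {
        best <- cand
      }
    }
    region[i] <- best$lab
    coord[i] <- best$mg
    gene_id[i] <- best$gene
  }
  sites$region <- region
  sites$metagene_coordinate <- coord
  sites$region_gene_id <- gene_id
  sites
}

#' Metagene density profile over scaled transcript coordinates
#'
#' Bins the metagene coordinates of exonic sites over `[0, 3)` (5'UTR, CDS,
#' 3'UTR each spanning one unit) and normalises to bin proportions summing
#' to 1.
#'
#' @param region_calls output of [assign_region()].
#' @param n_bins number of bins over `[0, 3)` (default 90, i.e. 30 per
#'   segment).
#' @return a `data.frame` with `bin_start`, `bin_end`, `bin_mid`, `count`,
#'   `density`; the attribute `n_sites` records how many exonic sites
#'   contributed (0 flags an empty profile).
#' @export
metagene_profile <- function(region_calls, n_bins = 90L) {
  stopifnot(n_bins >= 3L)
  mg <- region_calls$metagene_coordinate
  mg <- mg[!is.na(mg)]
  breaks <- seq(0, 3, length.out = n_bins + 1L)
  counts <- if (length(mg)) {
    as.integer(table(cut(mg, breaks, right = FALSE,
                         include.lowest = FALSE,
                         labels = seq_len(n_bins))))
  } else rep(0L, n_bins)
  density <- if (sum(counts)) counts / sum(counts) else rep(0, n_bins)
  out <- data.frame(bin_start = breaks[-(n_bins + 1L)], bin_end = breaks[-1L],
                    bin_mid = (breaks[-(n_bins + 1L)] + breaks[-1L]) / 2,
                    count = counts, density = density)
  attr(out, "n_sites") <- length(mg)
  out
}

#' Signed distances from reference m5C sites to the nearest called edit
#'
#' For every reference site (distance 0), finds the nearest called edit on
#' the same reference and gene strand within `window` nt and reports the
#' signed distance along the gene strand (negative = upstream of the m5C
#' site in transcript orientation). Reference sites with no edit inside the
#' window contribute no record; equidistant up/downstream edits resolve to
#' the downstream (positive) record.
#'
#' @param called_sites called-site `data.frame` (`chrom`, `pos`, `strand`).
#' @param reference_m5c `data.frame` with `chrom`, `pos` (0-based), `strand`
#'   -- e.g. read from a BED6 of bisulfite-sequencing calls via
#'   [read_sites_bed()].
#' @param window maximum absolute distance, nt (3000 for the broad view, 80
#'   for the fine view).
#' @return a `data.frame` of records: `chrom`, `ref_pos`, `strand`,
#'   `edit_pos`, `signed_distance`.
#' @export
distance_to_reference <- function(called_sites, reference_m5c, window = 3000L) {
  out <- vector("list", nrow(reference_m5c))
  for (i in seq_len(nrow(reference_m5c))) {
    ref <- reference_m5c[i, ]
    ed <- called_sites[called_sites$chrom == ref$chrom &
                         called_sites$strand == ref$strand, , drop = FALSE]
    if (!nrow(ed)) next
    d_gen <- ed$pos - ref$pos
    signed <- if (ref$strand == "+") d_gen else -d_gen
    signed <- signed[abs(signed) <= window]
    if (!length(signed)) next
    best <- min(abs(signed))
    pick <- if (best %in% signed) best else -best  # downstream wins ties
    out[[i]] <- data.frame(chrom = ref$chrom, ref_pos = ref$pos,
                           strand = ref$strand,
                           edit_pos = if (ref$strand == "+") ref$pos + pick
                                      else ref$pos - pick,
                           signed_distance = pick, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(chrom = character(0), ref_pos = integer(0),
                      strand = character(0), edit_pos = integer(0),
                      signed_distance = integer(0), stringsAsFactors = FALSE)
  }
  rownames(res) <- NULL
  res
}

#' Histogram of signed distances
#'
#' Bin width is 1 nt for windows up to 80 nt and 50 nt otherwise, matching
#' the fine and broad distance views.
#'
#' @param records output of [distance_to_reference()].
#' @param window the window used to compute the records.
#' @return a `data.frame` with `bin_start`, `bin_end`, `count`.
#' @export
distance_histogram <- function(records, window = 3000L) {
  bw <- if (window <= 80L) 1L else 50L
  breaks <- seq(-window, window + bw, by = bw) - 0.5
  counts <- as.integer(table(cut(records$signed_distance, breaks,
                                 right = FALSE)))
  data.frame(bin_start = utils::head(breaks, -1L) + 0.5,
             bin_end = utils::head(breaks, -1L) + 0.5 + bw - 1L,
             count = counts)
}

#' Read a BED6 site list
#'
#' @param path BED6 path (0-based half-open).
#' @return a `data.frame` with `chrom`, `pos`, `name`, `score`, `strand`.
#' @export
read_sites_bed <- function(path) {
  raw <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  data.frame(chrom = raw[[1]], pos = as.integer(raw[[2]]), name = raw[[4]],
             score = raw[[5]], strand = raw[[6]], stringsAsFactors = FALSE)
}
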