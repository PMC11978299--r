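#' Generate a synthetic single-exon transcriptome
#'
#' Builds `n_transcripts` random transcripts, each embedded in its own contig
#' with intergenic flanks on both sides. Every transcript has contiguous
#' 5'UTR, CDS and 3'UTR segments; the CDS length is a multiple of 3 and both
#' genomic strands are represented. Deterministic for a fixed seed.
#'
#' @param n_transcripts number of transcripts (one per contig).
#' @param length_range integer interval of transcript lengths, nt (min 150).
#' @param utr_cds_fractions fractions of transcript length allotted to
#'   (5'UTR, CDS, 3'UTR); must sum to 1.
#' @param seed RNG seed.
#' @param flank_length intergenic flank placed on each side of the transcript.
#' @return a list with `reference` (a [Biostrings::DNAStringSet] of contigs)
#'   and `genes` (a gene model `data.frame`, see [gene_model]).
#' @export
generate_transcriptome <- function(n_transcripts,
                                   length_range = c(800L, 2000L),
                                   utr_cds_fractions = c(0.2, 0.5, 0.3),
                                   seed = 1L,
                                   flank_length = 100L) {
  stopifnot(n_transcripts >= 1, length(utr_cds_fractions) == 3)
  if (abs(sum(utr_cds_fractions) - 1) > 1e-8) {
    stop("utr_cds_fractions must sum to 1", call. = FALSE)
  }
  if (min(length_range) < 150L) stop("transcript lengths must be >= 150 nt",
                                     call. = FALSE)
  with_seed(seed, {
    lens <- if (length_range[1] == length_range[2]) {
      rep(length_range[1], n_transcripts)
    } else {
      sample(seq(length_range[1], length_range[2]), n_transcripts,
             replace = TRUE)
    }
    # both strands represented whenever n >= 2
    strands <- rep_len(c("+", "-"), n_transcripts)
    strands <- sample(strands)
    seqs <- character(n_transcripts)
    chrom <- sprintf("ctg%03d", seq_len(n_transcripts))
    name <- sprintf("tx%03d", seq_len(n_transcripts))
    start <- rep(as.integer(flank_length), n_transcripts)
    end <- start + lens
    thick_start <- integer(n_transcripts)
    thick_end <- integer(n_transcripts)
    for (i in seq_len(n_transcripts)) {
      L <- lens[i]
      cds <- max(3L, (round(L * utr_cds_fractions[2]) %/% 3L) * 3L)
      utr5 <- max(1L, round(L * utr_cds_fractions[1]))
      if (utr5 + cds > L - 1L) utr5 <- L - cds - 1L
      utr3 <- L - utr5 - cds
      stopifnot(utr5 >= 1L, utr3 >= 1L)
      seqs[i] <- random_dna(L + 2L * flank_length)
      # CDS genomic extent depends on strand: 5'UTR sits at the genomic end
      # that is 5' in transcript orientation
      if (strands[i] == "+") {
        thick_start[i] <- start[i] + utr5
        thick_end[i] <- thick_start[i] + cds
      } else {
        thick_end[i] <- end[i] - utr5
        thick_start[i] <- thick_end[i] - cds
      }
    }
    reference <- Biostrings::DNAStringSet(seqs)
    names(reference) <- chrom
    genes <- new_gene_model(chrom, start, end, name, strands,
                            thick_start, thick_end,
                            block_sizes = as.list(lens),
                            block_starts = as.list(rep(0L, n_transcripts)))
    list(reference = reference, genes = genes)
  })
}

#' Plant m5C sites on synthetic transcripts
#'
#' Chooses cytosines on the transcript sense strand, distributed across
#' 5'UTR/CDS/3'UTR according to `region_weights`, and assigns each site a
#' per-read editing rate and a bisulfite-mode methylation fraction. The
#' editing window of the fusion protein extends `window_halfwidth` nt on
#' either side of the site.
#'
#' @param genes gene model.
#' @param reference contig sequences ([Biostrings::DNAStringSet]).
#' @param n_sites number of sites to plant.
#' @param region_weights named weights over `c("UTR5","CDS","UTR3")`.
#' @param rate_range interval from which per-site edit rates are drawn
#'   uniformly; the default brackets the site-level rates measured for the
#'   validated RPSA and AP5Z1 targets (13.6--14.7%).
#' @param editor `"ABE"` (edits A within the window) or `"CBE"` (edits C).
#' @param window_halfwidth editing-window half width, nt.
#' @param m5c_fraction_range interval for per-site methylation fractions
#'   used by the bisulfite amplicon simulator.
#' @param seed RNG seed.
#' @return a `data.frame` of planted truth: `site_id`, `transcript_id`,
#'   `position` (0-based transcript offset), `chrom`, `gpos` (0-based genomic
#'   position), `strand`, `region`, `editor`, `edit_rate`,
#'   `window_halfwidth`, `m5c_fraction`.
#' @export
plant_m5c_sites <- function(genes, reference, n_sites,
                            region_weights = c(CDS = 0.6, UTR3 = 0.3, UTR5 = 0.1),
                            rate_range = c(0.136, 0.147),
                            editor = "CBE",
                            window_halfwidth = 20L,
                            m5c_fraction_range = c(0.2, 0.9),
                            seed = 1L) {
  stopifnot(editor %in% c("ABE", "CBE"), window_halfwidth >= 0)
  stop_if_not_prob(rate_range, "rate_range")
  regions <- names(region_weights)
  stopifnot(all(regions %in% c("UTR5", "CDS", "UTR3")), all(region_weights >= 0))
  with_seed(seed, {
    # eligible C positions (transcript space) per gene and region
    elig <- list()
    for (i in seq_len(nrow(genes))) {
      gene <- genes[i, ]
      txs <- transcript_seq(reference, gene)
      cpos <- as.integer(gregexpr("C", txs, fixed = TRUE)[[1]]) - 1L
      cpos <- cpos[cpos >= 0L]
      reg <- tx_region(gene, cpos)
      for (r in regions) {
        p <- cpos[reg == r]
        if (length(p)) elig[[paste0(i, ":", r)]] <- list(gene_i = i, region = r,
                                                         pos = p)
      }
    }
    for (r in regions) {
      if (region_weights[r] > 0 && !any(vapply(elig, function(e) e$region == r,
                                               logical(1)))) {
        warning(sprintf("no transcript offers a C in region %s; skipped", r))
      }
    }
    site_region <- sample(regions, n_sites, replace = TRUE,
                          prob = region_weights)
    out <- vector("list", n_sites)
    used <- character(0)
    for (k in seq_len(n_sites)) {
      pool <- Filter(function(e) e$region == site_region[k], elig)
      if (!length(pool)) next
      for (attempt in seq_len(50L)) {
        e <- pool[[sample.int(length(pool), 1L)]]
        pos <- e$pos[sample.int(length(e$pos), 1L)]
        key <- paste0(e$gene_i, ":", pos)
        if (!key %in% used) break
      }
      if (key %in% used) next
      used <- c(used, key)
      gene <- genes[e$gene_i, ]
      out[[k]] <- data.frame(
        site_id = NA_character_, transcript_id = gene$name,
        position = pos, chrom = gene$chrom,
        gpos = tx_to_genomic(gene, pos), strand = gene$strand,
        region = e$region, editor = editor,
        edit_rate = stats::runif(1, rate_range[1], rate_range[2]),
        window_halfwidth = as.integer(window_halfwidth),
        m5c_fraction = stats::runif(1, m5c_fraction_range[1],
                                    m5c_fraction_range[2]),
        stringsAsFactors = FALSE
      )
    }
    truth <- do.call(rbind, out)
    if (is.null(truth)) stop("no eligible sites could be planted", call. = FALSE)
    truth$site_id <- sprintf("site%04d", seq_len(nrow(truth)))
    rownames(truth) <- NULL
    truth
  })
}

#' Describe a simulated experimental condition
#'
#' Encodes one transfection condition of the assay: the DRAM fusion itself,
#' the reader-mutant fusion (residual binding only), the free deaminase
#' (diffuse background, 3'UTR-biased), the methyltransferase knockout
#' (attenuated editing) and untreated wild type.
#'
#' @param condition one of `"DRAM"`, `"DRAM_MUT"`, `"DEAMINASE_ONLY"`,
#'   `"KNOCKOUT"`, `"WILDTYPE"`.
#' @param replicate_count number of replicates (replicate `r` uses seed
#'   `seed + r`).
#' @param coverage_mean target mean read depth per transcript position.
#' @param rate_multiplier scalar applied to every planted site's edit rate.
#' @param background_rate per-read probability that an editable base outside
#'   any editing window is deaminated (off-target activity).
#' @param background_region_bias multiplicative weight applied to
#'   `background_rate` within 3'UTRs.
#' @param error_rate per-base sequencing error probability.
#' @param seed base RNG seed for this condition.
#' @return a `condition_spec` list.
#' @export
condition_spec <- function(condition = c("DRAM", "DRAM_MUT", "DEAMINASE_ONLY",
                                         "KNOCKOUT", "WILDTYPE"),
                           replicate_count = 2L,
                           coverage_mean = 100,
                           rate_multiplier = 1,
                           background_rate = 0,
                           background_region_bias = 1,
                           error_rate = 0,
                           seed = 1L) {
  condition <- match.arg(condition)
  stopifnot(replicate_count >= 1, coverage_mean > 0, rate_multiplier >= 0,
            background_region_bias >= 0)
  stop_if_not_prob(background_rate, "background_rate")
  stop_if_not_prob(error_rate, "error_rate")
  structure(list(condition = condition,
                 replicate_count = as.integer(replicate_count),
                 coverage_mean = coverage_mean,
                 rate_multiplier = rate_multiplier,
                 background_rate = background_rate,
                 background_region_bias = background_region_bias,
                 error_rate = error_rate,
                 seed = as.integer(seed)),
            class = "condition_spec")
}

#' Default condition set matching the study design
#'
#' Three DRAM replicates, one reader-mutant replicate, two deaminase-only
#' replicates and three knockout replicates. The mutant retains 2% of the
#' on-target rate (residual binding); the knockout retains 10%; the free
#' deaminase edits diffusely with a 3:1 bias toward 3'UTRs.
#'
#' @param seed base seed; each condition derives its own offset seed.
#' @param coverage_mean mean depth shared by all conditions.
#' @param error_rate shared sequencing error rate.
#' @param knockout_multiplier residual editing in knockout cells.
#' @param background_rate off-target per-read deamination probability in the
#'   deaminase-only condition.
#' @return named list of [condition_spec()] objects.
#' @export
default_condition_specs <- function(seed = 1L, coverage_mean = 100,
                                    error_rate = 0.001,
                                    knockout_multiplier = 0.1,
                                    background_rate = 0.005) {
  list(
    DRAM = condition_spec("DRAM", replicate_count = 3L,
                          coverage_mean = coverage_mean,
                          rate_multiplier = 1, error_rate = error_rate,
                          seed = seed),
    DRAM_MUT = condition_spec("DRAM_MUT", replicate_count = 1L,
                              coverage_mean = coverage_mean,
                              rate_multiplier = 0.02, error_rate = error_rate,
                              seed = seed + 100L),
    DEAMINASE_ONLY = condition_spec("DEAMINASE_ONLY", replicate_count = 2L,
                                    coverage_mean = coverage_mean,
                                    rate_multiplier = 0,
                                    background_rate = background_rate,
                                    background_region_bias = 3,
                                    error_rate = error_rate,
                                    seed = seed + 200L),
    KNOCKOUT = condition_spec("KNOCKOUT", replicate_count = 3L,
                              coverage_mean = coverage_mean,
                              rate_multiplier = knockout_multiplier,
                              error_rate = error_rate, seed = seed + 300L)
  )
}

# Editable base for an editor, on the transcript sense strand.
editable_base <- function(editor) if (editor == "ABE") "A" else "C"
edited_to <- function(editor) if (editor == "ABE") "G" else "T"

#' Simulate strand-specific aligned reads for one condition
#'
#' Reads are sense-strand transcript fragments of fixed length placed
#' uniformly along each transcript. Each editable base (A for ABE, C for CBE)
#' within `window_halfwidth` nt of a planted site is deaminated per read with
#' probability `edit_rate * rate_multiplier`; off-target background edits and
#' flat-profile sequencing errors are applied afterwards. Alignments are
#' written as coordinate-sorted SAM with `@SQ` headers and MD/NM tags; reads
#' from minus-strand genes are stored reverse-complemented (flag 16), so a
#' transcript-level C-to-U appears as G-to-A in reference coordinates.
#'
#' @param genes gene model.
#' @param reference contig sequences.
#' @param truth planted sites from [plant_m5c_sites()] (may be zero rows).
#' @param spec a [condition_spec()].
#' @param read_length read length, nt; transcripts shorter than this are
#'   skipped with a warning.
#' @param out_dir directory receiving one SAM per replicate.
#' @return character vector of SAM paths (one per replicate).
#' @export
simulate_reads <- function(genes, reference, truth, spec,
                           read_length = 100L, out_dir = tempdir()) {
  stopifnot(inherits(spec, "condition_spec"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  editor <- if (nrow(truth)) truth$editor[1] else "CBE"
  base_from <- editable_base(editor)
  base_to <- edited_to(editor)
  paths <- character(spec$replicate_count)
  for (r in seq_len(spec$replicate_count)) {
    paths[r] <- file.path(out_dir, sprintf("%s_rep%d.sam",
                                           tolower(spec$condition), r))
    with_seed(spec$seed + r, {
      recs <- vector("list", nrow(genes))
      for (i in seq_len(nrow(genes))) {
        gene <- genes[i, ]
        recs[[i]] <- simulate_gene_reads(gene, reference, truth, spec,
                                         read_length, base_from, base_to)
      }
      recs <- do.call(rbind, recs)
      write_sam(recs, reference, paths[r])
    })
  }
  paths
}

# Simulate all reads of one transcript for one replicate; returns a
# data.frame of SAM fields (rname, pos0, flag, seq) or NULL.
simulate_gene_reads <- function(gene, reference, truth, spec, read_length,
                                base_from, base_to) {
  L <- tx_length(gene)
  if (read_length > L) {
    warning(sprintf("transcript %s (%d nt) shorter than read length; skipped",
                    gene$name, L))
    return(NULL)
  }
  n_reads <- as.integer(round(spec$coverage_mean * L / read_length))
  if (n_reads == 0L) return(NULL)
  txs <- transcript_seq(reference, gene)
  txc <- strsplit(txs, "", fixed = TRUE)[[1]]
  starts <- sample.int(L - read_length + 1L, n_reads, replace = TRUE) - 1L
  reads <- substring(txs, starts + 1L, starts + read_length)

  # (read, transcript-position) pairs to mutate, accumulated then applied
  mut_read <- integer(0); mut_pos <- integer(0); mut_base <- character(0)

  ord <- order(starts)
  s_sorted <- starts[ord]

  editable_tx <- which(txc == base_from) - 1L
  gtruth <- truth[truth$transcript_id == gene$name, , drop = FALSE]
  in_window <- logical(length(txc))
  if (nrow(gtruth) && spec$rate_multiplier > 0) {
    for (k in seq_len(nrow(gtruth))) {
      lo <- max(0L, gtruth$position[k] - gtruth$window_halfwidth[k])
      hi <- min(L - 1L, gtruth$position[k] + gtruth$window_halfwidth[k])
      in_window[(lo + 1L):(hi + 1L)] <- TRUE
    }
    for (k in seq_len(nrow(gtruth))) {
      lo <- max(0L, gtruth$position[k] - gtruth$window_halfwidth[k])
      hi <- min(L - 1L, gtruth$position[k] + gtruth$window_halfwidth[k])
      epos <- editable_tx[editable_tx >= lo & editable_tx <= hi]
      p <- min(1, gtruth$edit_rate[k] * spec$rate_multiplier)
      for (e in epos) {
        # reads covering transcript position e: start in [e-RL+1, e]
        lo_i <- findInterval(e - read_length, s_sorted) + 1L
        hi_i <- findInterval(e, s_sorted)
        if (hi_i < lo_i) next
        idx <- ord[lo_i:hi_i]
        hit <- idx[stats::runif(length(idx)) < p]
        if (length(hit)) {
          mut_read <- c(mut_read, hit)
          mut_pos <- c(mut_pos, rep(e, length(hit)))
          mut_base <- c(mut_base, rep(base_to, length(hit)))
        }
      }
    }
  }

  if (spec$background_rate > 0) {
    reg <- tx_region(gene, editable_tx)
    pbg <- pmin(1, spec$background_rate *
                  ifelse(reg == "UTR3", spec$background_region_bias, 1))
    for (j in seq_along(editable_tx)) {
      e <- editable_tx[j]
      if (in_window[e + 1L]) next  # windows handled above
      lo_i <- findInterval(e - read_length, s_sorted) + 1L
      hi_i <- findInterval(e, s_sorted)
      if (hi_i < lo_i) next
      idx <- ord[lo_i:hi_i]
      hit <- idx[stats::runif(length(idx)) < pbg[j]]
      if (length(hit)) {
        mut_read <- c(mut_read, hit)
        mut_pos <- c(mut_pos, rep(e, length(hit)))
        mut_base <- c(mut_base, rep(base_to, length(hit)))
      }
    }
  }

  if (spec$error_rate > 0) {
    n_err <- stats::rbinom(n_reads, read_length, spec$error_rate)
    err_reads <- rep(seq_len(n_reads), n_err)
    if (length(err_reads)) {
      err_off <- unlist(lapply(n_err[n_err > 0], function(k)
        sample.int(read_length, k)))
      err_tx <- starts[err_reads] + err_off - 1L
      cur <- txc[err_tx + 1L]
      alt <- vapply(cur, function(b) sample(setdiff(DNA_BASES, b), 1L), "")
      mut_read <- c(mut_read, err_reads)
      mut_pos <- c(mut_pos, err_tx)
      mut_base <- c(mut_base, unname(alt))
    }
  }

  if (length(mut_read)) {
    touched <- unique(mut_read)
    pieces <- strsplit(reads[touched], "", fixed = TRUE)
    names(pieces) <- as.character(touched)
    for (m in seq_along(mut_read)) {
      off <- mut_pos[m] - starts[mut_read[m]] + 1L
      pieces[[as.character(mut_read[m])]][off] <- mut_base[m]
    }
    reads[touched] <- vapply(pieces, paste, "", collapse = "")
  }

  # place on the genome: minus-strand genes carry reverse-complemented reads
  if (gene$strand == "+") {
    pos0 <- gene$start + starts
    seq_out <- reads
    flag <- 0L
  } else {
    pos0 <- gene$end - starts - read_length
    seq_out <- revcomp(reads)
    flag <- 16L
  }
  data.frame(rname = gene$chrom, pos0 = pos0, flag = flag, seq = seq_out,
             stringsAsFactors = FALSE)
}

# Write alignment records as coordinate-sorted SAM with MD/NM tags.
write_sam <- function(recs, reference, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:coordinate", con)
  writeLines(sprintf("@SQ\tSN:%s\tLN:%d", names(reference),
                     Biostrings::width(reference)), con)
  writeLines(sprintf("@PG\tID:dramseq\tPN:dramseq\tVN:%s",
                     as.character(utils::packageVersion("dramseq"))), con)
  if (is.null(recs) || nrow(recs) == 0L) return(invisible(path))
  recs <- recs[order(match(recs$rname, names(reference)), recs$pos0), ,
               drop = FALSE]
  rl <- nchar(recs$seq)
  refstr <- vapply(names(reference), function(n) as.character(reference[[n]]), "")
  ref_sub <- substring(refstr[recs$rname], recs$pos0 + 1L, recs$pos0 + rl)
  md <- character(nrow(recs))
  nm <- integer(nrow(recs))
  same <- recs$seq == ref_sub
  md[same] <- as.character(rl[same])
  for (i in which(!same)) {
    a <- strsplit(recs$seq[i], "", fixed = TRUE)[[1]]
    b <- strsplit(ref_sub[i], "", fixed = TRUE)[[1]]
    mm <- which(a != b)
    nm[i] <- length(mm)
    runs <- diff(c(0L, mm)) - 1L
    md[i] <- paste0(paste0(runs, b[mm], collapse = ""), rl[i] - mm[length(mm)])
  }
  qname <- sprintf("r%07d", seq_len(nrow(recs)))
  lines <- paste(qname, recs$flag, recs$rname, recs$pos0 + 1L, 60L,
                 paste0(rl, "M"), "*", 0L, 0L, recs$seq,
                 strrep("I", rl), paste0("NM:i:", nm), paste0("MD:Z:", md),
                 sep = "\t")
  writeLines(lines, con)
  invisible(path)
}

#' Simulate bisulfite-converted amplicon reads
#'
#' Emulates amplicon deep sequencing after chemical deamination: every
#' unmethylated cytosine converts to thymine with probability
#' `conversion_efficiency`, while the target site retains its C in a fraction
#' `m5c_fraction` of molecules (the methylated fraction protected from
#' conversion).
#'
#' @param amplicon amplicon reference sequence (character or DNAString).
#' @param site_position 0-based position of the interrogated cytosine.
#' @param m5c_fraction methylated fraction at the site, in `[0, 1]`.
#' @param n_reads number of reads to emit.
#' @param conversion_efficiency probability that an unmethylated C converts.
#' @param seed RNG seed.
#' @param out_fastq optional path; if given, reads are also written as FASTQ.
#' @return a [Biostrings::DNAStringSet] of `n_reads` reads.
#' @export
simulate_bisulfite_amplicon <- function(amplicon, site_position, m5c_fraction,
                                        n_reads, conversion_efficiency = 1,
                                        seed = 1L, out_fastq = NULL) {
  stopifnot(n_reads >= 1)
  stop_if_not_prob(m5c_fraction, "m5c_fraction")
  stop_if_not_prob(conversion_efficiency, "conversion_efficiency")
  amp <- as.character(amplicon)
  ampc <- strsplit(amp, "", fixed = TRUE)[[1]]
  if (ampc[site_position + 1L] != "C") {
    stop("site_position must index a C in the amplicon", call. = FALSE)
  }
  cpos <- which(ampc == "C")
  with_seed(seed, {
    reads <- matrix(rep(ampc, n_reads), nrow = n_reads, byrow = TRUE)
    methylated <- stats::runif(n_reads) < m5c_fraction
    for (p in cpos) {
      conv <- stats::runif(n_reads) < conversion_efficiency
      if (p == site_position + 1L) conv <- conv & !methylated
      reads[conv, p] <- "T"
    }
    out <- Biostrings::DNAStringSet(apply(reads, 1, paste, collapse = ""))
    names(out) <- sprintf("amp%06d", seq_len(n_reads))
    if (!is.null(out_fastq)) {
      Biostrings::writeXStringSet(out, out_fastq, format = "fastq",
                                  qualities = Biostrings::BStringSet(
                                    rep(strrep("I", nchar(amp)), n_reads)))
    }
    out
  })
}

#' Simulate a Sanger-style base-proportion trace
#'
#' Stand-in for a chromatogram: a table of per-position base proportions in
#' which every position shows its template base at proportion 1, except the
#' edited position, which splits between the template base and its
#' deamination product (C to T, or A to G) according to `edit_rate`.
#'
#' @param edit_rate fraction of molecules edited at `position`.
#' @param flank template sequence covered by the trace.
#' @param position 0-based offset of the edited base within `flank`; must be
#'   an A or a C.
#' @return a `data.frame` with columns `pos`, `A`, `C`, `G`, `T`; each row
#'   sums to 1.
#' @export
simulate_sanger_trace <- function(edit_rate, flank, position) {
  stop_if_not_prob(edit_rate, "edit_rate")
  fc <- strsplit(as.character(flank), "", fixed = TRUE)[[1]]
  stopifnot(position >= 0, position < length(fc))
  tab <- matrix(0, nrow = length(fc), ncol = 4,
                dimnames = list(NULL, DNA_BASES))
  tab[cbind(seq_along(fc), match(fc, DNA_BASES))] <- 1
  b <- fc[position + 1L]
  if (edit_rate > 0) {
    if (!b %in% c("A", "C")) {
      stop("edited position must be an A or a C", call. = FALSE)
    }
    prod <- if (b == "A") "G" else "T"
    tab[position + 1L, b] <- 1 - edit_rate
    tab[position + 1L, prod] <- edit_rate
  }
  data.frame(pos = seq_along(fc) - 1L, tab)
}

#' Write / read the planted-site truth table
#'
#' @param truth truth `data.frame` from [plant_m5c_sites()].
#' @param path TSV path.
#' @return `path` (write) or the truth `data.frame` (read).
#' @export
write_truth <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
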