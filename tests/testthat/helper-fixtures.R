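# Shared fixtures and independent oracles, built in code at test time.

tiny_world <- function(n = 3, len = c(800L, 1200L), seed = 11L) {
  generate_transcriptome(n, len, seed = seed)
}

# Hand-write a SAM file from explicit read records (chrom, pos0, seq, flag).
write_manual_sam <- function(records, reference, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:coordinate", con)
  writeLines(sprintf("@SQ\tSN:%s\tLN:%d", names(reference),
                     Biostrings::width(reference)), con)
  records <- records[order(match(records$chrom, names(reference)),
                           records$pos0), , drop = FALSE]
  flag <- if ("flag" %in% names(records)) records$flag else 0L
  rl <- nchar(records$seq)
  writeLines(paste(sprintf("m%04d", seq_len(nrow(records))), flag,
                   records$chrom, records$pos0 + 1L, 60L, paste0(rl, "M"),
                   "*", 0L, 0L, records$seq, strrep("I", rl), sep = "\t"),
             con)
  path
}

# Brute-force per-read pileup oracle: walk every SAM read base by base.
naive_pileup_tally <- function(sam_path) {
  lines <- readLines(sam_path)
  lines <- lines[!startsWith(lines, "@")]
  env <- new.env()
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    flag <- as.integer(f[2])
    if (bitwAnd(flag, 0x400L) > 0L || bitwAnd(flag, 0x100L) > 0L ||
        bitwAnd(flag, 0x800L) > 0L) next
    chrom <- f[3]; pos0 <- as.integer(f[4]) - 1L
    bases <- strsplit(f[10], "", fixed = TRUE)[[1]]
    for (i in seq_along(bases)) {
      key <- paste0(chrom, ":", pos0 + i - 1L)
      cur <- if (!is.null(env[[key]])) env[[key]] else
        c(A = 0L, C = 0L, G = 0L, T = 0L, N = 0L)
      cur[bases[i]] <- cur[bases[i]] + 1L
      env[[key]] <- cur
    }
  }
  keys <- ls(env)
  parts <- strsplit(keys, ":", fixed = TRUE)
  df <- data.frame(chrom = vapply(parts, `[`, "", 1L),
                   pos = as.integer(vapply(parts, `[`, "", 2L)),
                   t(vapply(keys, function(k) env[[k]], integer(5))),
                   stringsAsFactors = FALSE)
  df$depth <- df$A + df$C + df$G + df$T + df$N
  df[order(df$chrom, df$pos), , drop = FALSE]
}

# Reverse-complement a whole synthetic world: flip contigs and gene strands.
flip_world <- function(world) {
  ref <- Biostrings::reverseComplement(world$reference)
  names(ref) <- names(world$reference)
  genes <- world$genes
  for (i in seq_len(nrow(genes))) {
    L <- Biostrings::width(ref)[match(genes$chrom[i], names(ref))]
    s <- genes$start[i]; e <- genes$end[i]
    ts <- genes$thick_start[i]; te <- genes$thick_end[i]
    genes$start[i] <- L - e
    genes$end[i] <- L - s
    genes$thick_start[i] <- L - te
    genes$thick_end[i] <- L - ts
    genes$strand[i] <- if (genes$strand[i] == "+") "-" else "+"
    genes$block_starts[[i]] <- rev((e - s) -
      (genes$block_starts[[i]] + genes$block_sizes[[i]]))
    genes$block_sizes[[i]] <- rev(genes$block_sizes[[i]])
  }
  list(reference = ref, genes = genes)
}

# Build a candidate data.frame row in one call.
cand_row <- function(chrom = "ctg001", pos = 100L, strand = "+",
                     conversion = "C2U", coverage = 100L, edited = 30L,
                     gene_id = "tx001") {
  data.frame(chrom = chrom, pos = as.integer(pos), strand = strand,
             conversion = conversion,
             ref_base = if (conversion == "C2U") "C" else "A",
             coverage = as.integer(coverage), edited = as.integer(edited),
             ratio = edited / coverage, gene_id = gene_id, ambiguous = FALSE,
             stringsAsFactors = FALSE)
}

# Random candidate tables keyed on shared positions, for cascade oracles.
random_candidate_table <- function(n_keys, n_reps, seed) {
  set.seed(seed)
  pos <- sort(sample.int(50000L, n_keys))
  chrom <- sample(c("ctgA", "ctgB"), n_keys, replace = TRUE)
  strand <- sample(c("+", "-"), n_keys, replace = TRUE)
  reps <- lapply(seq_len(n_reps), function(r) {
    coverage <- sample(1:200, n_keys, replace = TRUE)
    edited <- rbinom(n_keys, coverage, runif(n_keys, 0, 0.6))
    keep <- edited > 0
    data.frame(chrom = chrom, pos = pos, strand = strand, conversion = "C2U",
               ref_base = "C", coverage = coverage, edited = edited,
               ratio = edited / coverage, gene_id = NA_character_,
               ambiguous = FALSE, stringsAsFactors = FALSE)[keep, ]
  })
  ko_cov <- sample(0:150, n_keys, replace = TRUE)
  ko_ed <- rbinom(n_keys, ko_cov, 0.05)
  knockout <- data.frame(chrom = chrom, pos = pos, strand = strand,
                         conversion = "C2U", ref_base = "C",
                         coverage = ko_cov, edited = ko_ed,
                         ratio = ifelse(ko_cov > 0, ko_ed / ko_cov, NA),
                         gene_id = NA_character_, ambiguous = FALSE,
                         stringsAsFactors = FALSE)[ko_cov > 0, ]
  list(reps = reps, knockout = knockout, chrom = chrom, pos = pos,
       strand = strand)
}
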