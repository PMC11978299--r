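#' Pool candidate tables across replicates
#'
#' Sums coverage and edited-read counts per (reference, position, strand,
#' conversion) across replicate candidate tables and recomputes the ratio.
#' Used to collapse control conditions (knockout, deaminase-only) into one
#' comparison table.
#'
#' @param replicates list of candidate `data.frame`s.
#' @return a pooled candidate `data.frame`.
#' @export
pool_candidates <- function(replicates) {
  all <- do.call(rbind, replicates)
  if (is.null(all) || nrow(all) == 0L) return(empty_candidates())
  key <- site_key(all)
  first <- all[!duplicated(key), , drop = FALSE]
  fkey <- site_key(first)
  cov <- tapply(all$coverage, key, sum)[fkey]
  ed <- tapply(all$edited, key, sum)[fkey]
  first$coverage <- as.integer(cov)
  first$edited <- as.integer(ed)
  first$ratio <- first$edited / first$coverage
  first <- first[order(first$chrom, first$pos, first$strand), , drop = FALSE]
  rownames(first) <- NULL
  first
}

#' Default pipeline configuration
#'
#' Returns the configuration list consumed by [run_pipeline()], populated
#' with the study-design defaults: 50 transcripts, 100 planted sites, three
#' DRAM and three knockout replicates at 100x coverage, knockout editing
#' attenuated to 10%, sequencing error 1e-3.
#'
#' @param outdir output directory.
#' @param seed global seed; every stage derives its seed from it.
#' @param editor `"CBE"` or `"ABE"`.
#' @param include_deaminase simulate the deaminase-only condition and apply
#'   background subtraction.
#' @return a named list.
#' @export
pipeline_config <- function(outdir = tempfile("dram_run_"), seed = 1L,
                            editor = "CBE", include_deaminase = FALSE) {
  list(
    outdir = outdir, seed = as.integer(seed), editor = editor,
    include_deaminase = include_deaminase,
    n_transcripts = 50L, length_range = c(800L, 2000L),
    utr_cds_fractions = c(0.2, 0.5, 0.3),
    n_sites = 100L,
    region_weights = c(CDS = 0.6, UTR3 = 0.3, UTR5 = 0.1),
    rate_range = c(0.3, 0.3), window_halfwidth = 20L,
    read_length = 100L, coverage_mean = 100, error_rate = 0.001,
    knockout_multiplier = 0.1, background_rate = 0.005,
    filter = filter_params(), high_confidence = high_confidence_params()
  )
}

#' Run the full synthetic DRAM-seq workflow
#'
#' Generates the synthetic transcriptome and planted m5C truth, simulates
#' condition-specific alignments, builds pileups, extracts candidates,
#' applies the replicated comparative filter cascade (with background
#' subtraction when a deaminase-only condition is present and the fold
#' filter disabled with a message when no knockout is), derives the
#' high-confidence tier, and computes region, metagene, distance and motif
#' summaries plus replicate correlations. All tables are written as TSV
#' under `config$outdir` together with a JSON run manifest recording the
#' package version, a configuration hash, seeds and per-stage row counts.
#'
#' @param config configuration list from [pipeline_config()] (or a
#'   compatible list).
#' @return invisibly, a list with the in-memory results: `truth`, `genes`,
#'   `sites`, `hc_sites`, `regions`, `metagene`, `distances`, `pfm`,
#'   `replicate_r`, `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  conv <- if (config$editor == "ABE") "A2G" else "C2U"

  world <- generate_transcriptome(config$n_transcripts, config$length_range,
                                  config$utr_cds_fractions, seed = config$seed)
  truth <- plant_m5c_sites(world$genes, world$reference, config$n_sites,
                           region_weights = config$region_weights,
                           rate_range = config$rate_range,
                           editor = config$editor,
                           window_halfwidth = config$window_halfwidth,
                           seed = config$seed + 1L)
  specs <- default_condition_specs(seed = config$seed,
                                   coverage_mean = config$coverage_mean,
                                   error_rate = config$error_rate,
                                   knockout_multiplier =
                                     config$knockout_multiplier,
                                   background_rate = config$background_rate)
  wanted <- c("DRAM", "KNOCKOUT", if (config$include_deaminase)
    "DEAMINASE_ONLY")
  sam_dir <- file.path(config$outdir, "alignments")
  cand <- list()
  for (cond in wanted) {
    sams <- simulate_reads(world$genes, world$reference, truth, specs[[cond]],
                           read_length = config$read_length,
                           out_dir = sam_dir)
    cand[[cond]] <- lapply(sams, function(s) {
      pu <- build_pileup(s, world$reference)
      extract_candidates(pu, world$genes, conv,
                         keep_zero = (cond == "KNOCKOUT"))
    })
  }

  knockout <- if ("KNOCKOUT" %in% names(cand)) {
    pool_candidates(cand$KNOCKOUT)
  } else {
    message("no knockout condition supplied; fold filter disabled")
    NULL
  }
  sites <- call_replicated_sites(cand$DRAM, knockout, config$filter)
  if (config$include_deaminase) {
    sites <- subtract_background(sites, pool_candidates(cand$DEAMINASE_ONLY))
  }
  hc <- high_confidence_tier(sites, config$high_confidence)

  regions <- assign_region(sites, world$genes)
  mg <- metagene_profile(regions)
  ref_sites <- data.frame(chrom = truth$chrom, pos = truth$gpos,
                          name = truth$site_id, score = 0L,
                          strand = truth$strand, stringsAsFactors = FALSE)
  dist <- distance_to_reference(sites, ref_sites, window = 3000L)
  pfm <- if (nrow(sites)) build_pfm(extract_flanks(sites, world$reference,
                                                   config$window_halfwidth))
         else NULL
  rep_r <- if (length(cand$DRAM) >= 2L) {
    replicate_correlation(per_gene_edit_counts(cand$DRAM[[1]]),
                          per_gene_edit_counts(cand$DRAM[[2]]))
  } else NA_real_

  # persist tables
  write_gene_model(world$genes, file.path(config$outdir, "genes.bed"))
  Biostrings::writeXStringSet(world$reference,
                              file.path(config$outdir, "reference.fa"))
  write_truth(truth, file.path(config$outdir, "truth.tsv"))
  write_candidates(sites, file.path(config$outdir, "called_sites.tsv"))
  write_candidates(hc, file.path(config$outdir, "high_confidence_sites.tsv"))
  if (nrow(sites)) write_sites_bed(sites, file.path(config$outdir,
                                                    "called_sites.bed"))
  utils::write.table(regions, file.path(config$outdir, "regions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(mg, file.path(config$outdir, "metagene.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(dist, file.path(config$outdir, "distances.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(pfm)) write_pfm(pfm, file.path(config$outdir, "pfm.tsv"))

  manifest <- list(
    tool = "dramseq",
    version = as.character(utils::packageVersion("dramseq")),
    seed = config$seed,
    config_hash = config_hash(config),
    stages = list(transcripts = nrow(world$genes), planted_sites = nrow(truth),
                  dram_replicates = length(cand$DRAM),
                  called_sites = nrow(sites), high_confidence = nrow(hc),
                  distance_records = nrow(dist)),
    replicate_pearson_r = rep_r
  )
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(truth = truth, genes = world$genes,
                 reference = world$reference, sites = sites, hc_sites = hc,
                 regions = regions, metagene = mg, distances = dist,
                 pfm = pfm, replicate_r = rep_r, manifest = manifest))
}

# Stable md5 over the deparsed configuration.
config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(deparse(config[order(names(config))]), tmp)
  unname(tools::md5sum(tmp))
}
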