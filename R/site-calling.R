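#' Filter parameter sets for the comparative calling cascade
#'
#' The default tier requires at least 10 reads of coverage, an edit ratio of
#' 5--95%, a ratio at least 1.5-fold above the matched methyltransferase
#' knockout, and at least two edited reads at the site. The high-confidence
#' tier tightens these to a 10--60% ratio, a 2-fold knockout margin and at
#' least four edited reads.
#'
#' @param min_coverage minimum read coverage at the site.
#' @param ratio_min,ratio_max inclusive edit-ratio bounds.
#' @param fold_vs_knockout required ratio fold-change over the knockout.
#' @param min_edited_reads minimum edited-read count.
#' @param min_replicates replicates a site must pass in (cascade level).
#' @param knockout_pseudocount pseudocount used for a knockout position that
#'   is covered but carries zero edited reads.
#' @return a `filter_params` list.
#' @export
filter_params <- function(min_coverage = 10L, ratio_min = 0.05,
                          ratio_max = 0.95, fold_vs_knockout = 1.5,
                          min_edited_reads = 2L, min_replicates = 2L,
                          knockout_pseudocount = 1L) {
  stopifnot(ratio_min >= 0, ratio_min < ratio_max, ratio_max <= 1,
            fold_vs_knockout >= 1, min_edited_reads >= 1, min_replicates >= 1)
  structure(list(min_coverage = min_coverage, ratio_min = ratio_min,
                 ratio_max = ratio_max, fold_vs_knockout = fold_vs_knockout,
                 min_edited_reads = min_edited_reads,
                 min_replicates = min_replicates,
                 knockout_pseudocount = knockout_pseudocount),
            class = "filter_params")
}

#' @rdname filter_params
#' @export
high_confidence_params <- function(min_coverage = 10L, ratio_min = 0.10,
                                   ratio_max = 0.60, fold_vs_knockout = 2.0,
                                   min_edited_reads = 4L,
                                   min_replicates = 2L,
                                   knockout_pseudocount = 1L) {
  filter_params(min_coverage, ratio_min, ratio_max, fold_vs_knockout,
                min_edited_reads, min_replicates, knockout_pseudocount)
}

candidate_key <- function(x) paste(x$chrom, x$pos, x$conversion, sep = "|")
site_key <- function(x) paste(x$chrom, x$pos, x$strand, x$conversion, sep = "|")

# Knockout edit ratio per candidate row: NA when the knockout sample does not
# cover the position (the fold test then passes); pseudocounted when covered
# with zero edited reads.
knockout_ratio_for <- function(candidates, knockout, params) {
  if (is.null(knockout) || nrow(knockout) == 0L) {
    return(rep(NA_real_, nrow(candidates)))
  }
  idx <- match(candidate_key(candidates), candidate_key(knockout))
  ke <- knockout$edited[idx]
  kc <- knockout$coverage[idx]
  pc <- params$knockout_pseudocount
  ifelse(is.na(idx), NA_real_,
         ifelse(ke == 0L, pc / (kc + pc), ke / kc))
}

#' Apply the per-site filter predicates
#'
#' Evaluates the tier predicates on each candidate against its matched
#' knockout counterpart (matched on reference, position and conversion).
#' `filter_site()` is the single-candidate form returning the pass flag and
#' the first failing predicate.
#'
#' @param candidates candidate `data.frame` ([extract_candidates()]).
#' @param knockout knockout-condition candidates extracted with
#'   `keep_zero = TRUE`, or `NULL` when no knockout sample exists (the fold
#'   test then passes everywhere).
#' @param params a [filter_params()] set.
#' @return `filter_sites()`: the input with `knockout_ratio`, `pass` and
#'   `reason` columns appended. `filter_site()`: a list with `pass` and
#'   `reason`.
#' @export
filter_sites <- function(candidates, knockout = NULL,
                         params = filter_params()) {
  kr <- knockout_ratio_for(candidates, knockout, params)
  ok_cov <- candidates$coverage >= params$min_coverage
  ok_lo <- candidates$ratio >= params$ratio_min
  ok_hi <- candidates$ratio <= params$ratio_max
  ok_ed <- candidates$edited >= params$min_edited_reads
  ok_fold <- is.na(kr) | candidates$ratio >= params$fold_vs_knockout * kr
  reason <- rep("pass", nrow(candidates))
  reason[!ok_fold] <- "fold_vs_knockout"
  reason[!ok_ed] <- "min_edited_reads"
  reason[!ok_hi] <- "ratio_max"
  reason[!ok_lo] <- "ratio_min"
  reason[!ok_cov] <- "min_coverage"
  out <- candidates
  out$knockout_ratio <- kr
  out$pass <- ok_cov & ok_lo & ok_hi & ok_ed & ok_fold
  out$reason <- reason
  out
}

#' @rdname filter_sites
#' @param candidate a single-row candidate `data.frame`.
#' @export
filter_site <- function(candidate, knockout = NULL, params = filter_params()) {
  stopifnot(nrow(candidate) == 1L)
  res <- filter_sites(candidate, knockout, params)
  list(pass = res$pass, reason = res$reason)
}

#' Call editing sites replicated across samples
#'
#' Runs the per-site filter in every replicate and retains sites that pass in
#' at least `params$min_replicates` of them (singleton sites are removed).
#' Reported ratio, coverage and edited-read counts are means over the passing
#' replicates.
#'
#' @param replicates list of candidate `data.frame`s, one per replicate.
#' @param knockout matched knockout candidates (`keep_zero = TRUE`) or `NULL`.
#' @param params a [filter_params()] set.
#' @return a called-site `data.frame`: `chrom`, `pos`, `strand`,
#'   `conversion`, `gene_id`, `n_pass`, `ratio`, `coverage`, `edited`,
#'   `knockout_ratio`, `tier`.
#' @export
call_replicated_sites <- function(replicates, knockout = NULL,
                                  params = filter_params()) {
  stopifnot(is.list(replicates), length(replicates) >= 1L)
  passed <- lapply(replicates, function(cand) {
    res <- filter_sites(cand, knockout, params)
    res[res$pass, , drop = FALSE]
  })
  all <- do.call(rbind, passed)
  if (is.null(all) || nrow(all) == 0L) return(empty_called_sites())
  key <- site_key(all)
  n_pass <- tapply(rep(1L, nrow(all)), key, sum)
  keep_keys <- names(n_pass)[n_pass >= params$min_replicates]
  if (!length(keep_keys)) return(empty_called_sites())
  all <- all[key %in% keep_keys, , drop = FALSE]
  key <- site_key(all)
  first <- all[!duplicated(key), , drop = FALSE]
  fkey <- site_key(first)
  agg <- function(v) as.numeric(tapply(v, key, mean)[fkey])
  out <- data.frame(chrom = first$chrom, pos = first$pos,
                    strand = first$strand, conversion = first$conversion,
                    gene_id = first$gene_id,
                    n_pass = as.integer(n_pass[fkey]),
                    ratio = agg(all$ratio), coverage = agg(all$coverage),
                    edited = agg(all$edited),
                    knockout_ratio = first$knockout_ratio,
                    tier = "default", stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$pos, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_called_sites <- function() {
  data.frame(chrom = character(0), pos = integer(0), strand = character(0),
             conversion = character(0), gene_id = character(0),
             n_pass = integer(0), ratio = numeric(0), coverage = numeric(0),
             edited = numeric(0), knockout_ratio = numeric(0),
             tier = character(0), stringsAsFactors = FALSE)
}

#' Remove sites observed in deaminase-only controls
#'
#' Any called site whose (reference, position, conversion) also appears among
#' the deaminase-only candidates -- at any ratio -- is removed, eliminating
#' reader-independent off-target editing.
#'
#' @param sites called sites ([call_replicated_sites()]).
#' @param deaminase_only candidate `data.frame` from the deaminase-only
#'   condition (default extraction, i.e. edited positions only).
#' @return the surviving subset of `sites`.
#' @export
subtract_background <- function(sites, deaminase_only) {
  if (is.null(deaminase_only) || nrow(deaminase_only) == 0L) return(sites)
  drop <- candidate_key(sites) %in% candidate_key(deaminase_only)
  out <- sites[!drop, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Extract the high-confidence tier from default-tier sites
#'
#' Re-applies the stricter predicate set to the aggregated site statistics of
#' the default tier; the result is always a subset of its input.
#'
#' @param sites default-tier called sites.
#' @param hc_params a [high_confidence_params()] set.
#' @return the qualifying subset with `tier` relabelled
#'   `"high_confidence"`.
#' @export
high_confidence_tier <- function(sites, hc_params = high_confidence_params()) {
  if (nrow(sites) == 0L) return(sites)
  kr <- sites$knockout_ratio
  keep <- sites$coverage >= hc_params$min_coverage &
    sites$ratio >= hc_params$ratio_min &
    sites$ratio <= hc_params$ratio_max &
    sites$edited >= hc_params$min_edited_reads &
    (is.na(kr) | sites$ratio >= hc_params$fold_vs_knockout * kr)
  out <- sites[keep, , drop = FALSE]
  if (nrow(out)) out$tier <- "high_confidence"
  rownames(out) <- NULL
  out
}

#' Merge gene lists supported by the two editors
#'
#' Integrates genes carrying called sites from the ABE arm and the CBE arm
#' into one table recording which editor(s) support each gene and how many
#' sites each contributes.
#'
#' @param abe_sites,cbe_sites called-site `data.frame`s from the two arms.
#' @param genes gene model (used to order output; genes without sites are
#'   omitted).
#' @return a `data.frame` with `gene_id`, `n_sites_abe`, `n_sites_cbe`,
#'   `editors` (`"ABE"`, `"CBE"` or `"ABE+CBE"`).
#' @export
merge_editor_genes <- function(abe_sites, cbe_sites, genes = NULL) {
  tab <- function(s) {
    g <- s$gene_id[!is.na(s$gene_id)]
    if (!length(g)) return(integer(0))
    table(g)
  }
  ta <- tab(abe_sites); tc <- tab(cbe_sites)
  gene_ids <- union(names(ta), names(tc))
  if (!is.null(genes)) {
    gene_ids <- c(intersect(genes$name, gene_ids),
                  setdiff(gene_ids, genes$name))
  }
  na <- as.integer(ta[gene_ids]); na[is.na(na)] <- 0L
  nc <- as.integer(tc[gene_ids]); nc[is.na(nc)] <- 0L
  editors <- ifelse(na > 0L & nc > 0L, "ABE+CBE", ifelse(na > 0L, "ABE", "CBE"))
  data.frame(gene_id = gene_ids, n_sites_abe = na, n_sites_cbe = nc,
             editors = editors, stringsAsFactors = FALSE)
}

#' Export called sites as BED6
#'
#' Scores encode the mean edit ratio as `round(1000 * ratio)`.
#'
#' @param sites called sites.
#' @param path output BED path.
#' @return `path`, invisibly.
#' @export
write_sites_bed <- function(sites, path) {
  out <- data.frame(sites$chrom, sites$pos, sites$pos + 1L,
                    paste0(sites$conversion, "_", seq_len(nrow(sites))),
                    round(1000 * sites$ratio), sites$strand)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
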