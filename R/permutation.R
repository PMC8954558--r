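# Permutation null for the srRNA mapping: within-read shuffling destroys
# contiguous homology while conserving composition, then the entire
# isolation pipeline is rerun and the permuted mappings are compared with
# the observed ones.

spearman_z <- function(x, y) {
  if (length(x) < 3 || sd(x) == 0 || sd(y) == 0)
    return(list(z = 0, p = 1, rho = NA_real_))
  rho <- cor(x, y, method = "spearman")
  z <- rho * sqrt(length(x) - 1)
  list(z = z, p = min(1, 2 * pnorm(-abs(z))), rho = rho)
}

binned_counts <- function(records, chrom_lengths, bin) {
  unlist(lapply(names(chrom_lengths), function(chrom) {
    n_bins <- ceiling(chrom_lengths[[chrom]] / bin)
    out <- numeric(n_bins)
    r <- records[records$chrom == chrom, , drop = FALSE]
    if (nrow(r)) {
      mid <- floor((r$start + r$end) / 2)
      ix <- pmin(n_bins, mid %/% bin + 1L)
      for (j in seq_along(ix)) out[ix[j]] <- out[ix[j]] + r$read_count[j]
    }
    out
  }), use.names = FALSE)
}

#' Run one read-shuffling permutation trial
#'
#' Shuffles every read (bases together with their qualities), reruns the
#' whole isolation pipeline (trim, rDNA pass, genome pass, mapping table,
#' gene assignment) and compares the permuted mappings with the observed
#' ones: mapped read/region counts, region intersections (>= 1 bp), the
#' interval Jaccard statistic, the target-gene overlap with its
#' hypergeometric tail probability, and a Spearman rank correlation (z and
#' p from the large-sample normal approximation) between observed and
#' permuted binned coverage.
#'
#' @param reads the original (pre-QC) [small_read_set()].
#' @param rdna_index,genome_index [seq_index()] objects for the two passes.
#' @param genes gene annotation ([sim_gene_annotation()] list or gene
#'   data.frame).
#' @param observed_records the observed `mapping_table`.
#' @param seed integer seed for the shuffle.
#' @param trim trimming thresholds (list, see [trim_reads()]).
#' @param rdna_max_mismatch,genome_max_mismatch per-pass mismatch caps.
#' @param universe_size gene universe for the hypergeometric test (defaults
#'   to the number of annotated genes).
#' @param cor_bin bin width (bp) of the correlation coverage vectors.
#' @return one-row data.frame: trial_id, n_mapped_reads, n_mapped_regions,
#'   n_region_intersections_with_observed, jaccard, n_overlap_genes,
#'   hypergeom_p, correlation_z, correlation_p.
#' @export
permutation_trial <- function(reads, rdna_index, genome_index, genes,
                              observed_records, seed = 1,
                              trim = list(), rdna_max_mismatch = 2,
                              genome_max_mismatch = 1, universe_size = NULL,
                              cor_bin = 1000) {
  if (is.list(genes) && !is.data.frame(genes) && !is.null(genes$genes))
    genes_df <- genes$genes else genes_df <- genes
  if (is.null(universe_size)) universe_size <- nrow(genes_df)
  shuffled <- shuffle_reads(reads, seed = seed)
  qc <- do.call(trim_reads, c(list(reads = shuffled), trim))
  sel <- select_rdna_reads(qc$reads, rdna_index,
                           max_mismatch = rdna_max_mismatch)
  gal <- align_reads(sel$reads, genome_index,
                     max_mismatch = genome_max_mismatch)
  tab <- mapping_table(gal$alignments, shuffled)
  perm_regions <- merge_mapping_regions(tab)
  obs_regions <- merge_mapping_regions(observed_records)
  n_inter <- if (!nrow(perm_regions) || !nrow(obs_regions)) 0L else {
    pg <- GenomicRanges::GRanges(perm_regions$chrom,
      IRanges::IRanges(perm_regions$start + 1L, perm_regions$end))
    og <- GenomicRanges::GRanges(obs_regions$chrom,
      IRanges::IRanges(obs_regions$start + 1L, obs_regions$end))
    sum(GenomicRanges::countOverlaps(pg, og, minoverlap = 1L) > 0)
  }
  jac <- jaccard_intervals(perm_regions, obs_regions)
  tg_obs <- assign_target_genes(observed_records, genes_df)$targets$gene_id
  tg_perm <- assign_target_genes(tab, genes_df)$targets$gene_id
  n_overlap <- length(intersect(tg_obs, tg_perm))
  hp <- hypergeom_overlap_p(n_overlap - 1, length(tg_obs), universe_size,
                            max(length(tg_perm), 0))
  lens <- genome_index$lengths
  cz <- spearman_z(binned_counts(observed_records, lens, cor_bin),
                   binned_counts(tab, lens, cor_bin))
  data.frame(trial_id = NA_integer_,
             n_mapped_reads = unname(gal$stats["n_aligned"]),
             n_mapped_regions = nrow(perm_regions),
             n_region_intersections_with_observed = n_inter,
             jaccard = jac, n_overlap_genes = n_overlap,
             hypergeom_p = hp, correlation_z = cz$z, correlation_p = cz$p,
             stringsAsFactors = FALSE)
}

#' Run repeated permutation trials
#'
#' @inheritParams permutation_trial
#' @param n_trials number of trials (default 10).
#' @param seed master seed; each trial uses a derived seed.
#' @return data.frame with one row per trial.
#' @export
run_permutation_trials <- function(reads, rdna_index, genome_index, genes,
                                   observed_records, n_trials = 10, seed = 1,
                                   ...) {
  out <- lapply(seq_len(n_trials), function(t) {
    r <- permutation_trial(reads, rdna_index, genome_index, genes,
                           observed_records,
                           seed = derive_seed(seed, 1000 + t), ...)
    r$trial_id <- t
    r
  })
  do.call(rbind, out)
}
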