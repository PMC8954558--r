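# Epigenomic context of srRNA targets: z-scored signal metaprofiles,
# chromatin-state composition with per-state Welch tests, and TSS
# classification (bidirectional vs unidirectional promoters).

track_chrom_lengths <- function(track, chrom_lengths = NULL) {
  if (!is.null(chrom_lengths)) return(chrom_lengths)
  tapply(track$end, track$chrom, max)
}

# Weighted per-base Rle of a step-function track on one chromosome.
track_rle <- function(track, chrom, L) {
  t <- track[track$chrom == chrom, , drop = FALSE]
  if (!nrow(t)) return(S4Vectors::Rle(0, L))
  IRanges::coverage(IRanges::IRanges(t$start + 1L, pmin(t$end, L)),
                    weight = t$value, width = L)
}

#' Anchor midpoints of mapping records
#'
#' @param records a `mapping_table` (chrom/start/end).
#' @return data.frame `chrom`, `mid` with `mid = floor((start + end) / 2)`.
#' @export
anchor_midpoints <- function(records) {
  data.frame(chrom = records$chrom,
             mid = as.integer(floor((records$start + records$end) / 2)),
             stringsAsFactors = FALSE)
}

#' Signal metaprofile around anchor points
#'
#' For each anchor the signal is averaged within fixed-width bins across
#' `[mid - flank, mid + flank)`; bins are then averaged over anchors and
#' optionally z-scored across the bin vector (mean 0, sd 1; an all-constant
#' profile z-scores to all zeros).  Signal within a bin is length-weighted by
#' the overlap of track steps with the bin; positions not covered by the
#' track count as 0.  Anchors whose window runs off a chromosome end are
#' clipped, with per-bin denominators adjusted; bins entirely out of bounds
#' are excluded from the average.
#'
#' @param track a `signal_track` data.frame (chrom, start, end, value).
#' @param anchors data.frame `chrom`, `mid` (see [anchor_midpoints()]).
#' @param flank half-window in bp (default 1500); must be divisible by `bin`.
#' @param bin bin width in bp (default 10).
#' @param zscore z-score the profile across bins (default `TRUE`).
#' @param chrom_lengths optional named chromosome lengths (defaults to the
#'   track extent per chromosome).
#' @return a `metaprofile` list: `bin_size`, `flank`, `n_bins`, `values`,
#'   `raw_values`, `bin_centers` (offsets of bin centers from the anchor),
#'   `n_anchors`.
#' @export
metaprofile <- function(track, anchors, flank = 1500, bin = 10,
                        zscore = TRUE, chrom_lengths = NULL) {
  if (!nrow(anchors)) stop("no anchors")
  if (flank %% bin != 0) stop("flank must be divisible by bin")
  n_bins <- as.integer(2 * flank / bin)
  lens <- track_chrom_lengths(track, chrom_lengths)
  sums <- numeric(n_bins)
  denom <- numeric(n_bins)
  offs <- seq(-flank, flank - bin, by = bin)
  for (chrom in unique(anchors$chrom)) {
    if (!chrom %in% names(lens)) next
    L <- as.integer(lens[[chrom]])
    r <- track_rle(track, chrom, L)
    mids <- anchors$mid[anchors$chrom == chrom]
    # bin j of anchor a: [mid + offs[j], mid + offs[j] + bin), 0-based
    s0 <- rep(mids, each = n_bins) + rep(offs, length(mids))   # 0-based start
    e0 <- s0 + bin
    cs <- pmax(s0, 0L); ce <- pmin(e0, L)
    w <- ce - cs
    ok <- w > 0
    vsum <- numeric(length(s0))
    if (any(ok)) {
      v <- IRanges::Views(r, start = cs[ok] + 1L, end = ce[ok])
      vsum[ok] <- IRanges::viewSums(v)
    }
    bin_idx <- rep(seq_len(n_bins), length(mids))
    m <- vsum[ok] / w[ok]
    sums <- sums + as.numeric(tapply(c(m, numeric(0)),
                                     factor(bin_idx[ok], levels = seq_len(n_bins)),
                                     sum, default = 0))
    denom <- denom + as.numeric(table(factor(bin_idx[ok],
                                             levels = seq_len(n_bins))))
  }
  if (all(denom == 0)) stop("no anchor window overlaps any chromosome")
  raw <- ifelse(denom > 0, sums / pmax(denom, 1), NA_real_)
  values <- raw
  if (zscore) {
    s <- sd(raw[!is.na(raw)])
    values <- if (is.na(s) || s == 0) rep(0, n_bins) else
      (raw - mean(raw, na.rm = TRUE)) / s
  }
  structure(list(bin_size = bin, flank = flank, n_bins = n_bins,
                 values = values, raw_values = raw,
                 bin_centers = offs + bin / 2,
                 n_anchors = nrow(anchors)),
            class = "metaprofile")
}

#' Chromatin-state composition of target intervals vs the genome
#'
#' Base-pair-weighted composition: for each state, the fraction of target bp
#' falling in that state and the fraction of the genome it covers.  Targets
#' are internally merged so overlapping records are not double counted.
#' Untiled genome bp (and target bp outside any state) are reported as an
#' `unannotated` bucket, so both fraction columns sum to 1.
#'
#' @param targets data.frame chrom/start/end (mapping table or regions).
#' @param states a `state_segmentation` data.frame.
#' @param genome_lengths named chromosome lengths.
#' @return data.frame: state, genome_bp, target_bp, genome_fraction,
#'   target_fraction.
#' @export
state_composition <- function(targets, states, genome_lengths) {
  tg <- GenomicRanges::reduce(GenomicRanges::GRanges(targets$chrom,
    IRanges::IRanges(targets$start + 1L, targets$end)))
  target_total <- sum(GenomicRanges::width(tg))
  genome_total <- sum(as.numeric(genome_lengths))
  labs <- unique(states$state)
  rows <- lapply(labs, function(lab) {
    s <- states[states$state == lab, , drop = FALSE]
    sg <- GenomicRanges::reduce(GenomicRanges::GRanges(s$chrom,
      IRanges::IRanges(s$start + 1L, s$end)))
    inter <- GenomicRanges::intersect(tg, sg)
    data.frame(state = lab, genome_bp = sum(GenomicRanges::width(sg)),
               target_bp = sum(GenomicRanges::width(inter)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  un_g <- genome_total - sum(out$genome_bp)
  un_t <- target_total - sum(out$target_bp)
  if (un_g > 0 || un_t > 0)
    out <- rbind(out, data.frame(state = "unannotated", genome_bp = un_g,
                                 target_bp = un_t, stringsAsFactors = FALSE))
  out$genome_fraction <- out$genome_bp / genome_total
  out$target_fraction <- if (target_total > 0) out$target_bp / target_total
                         else 0
  out
}

#' Per-state Welch test of target vs genome state fractions
#'
#' The replication unit is the chromosome: for each state, the
#' per-chromosome fraction of target bp in that state is compared with the
#' per-chromosome genome fraction by the unequal-variances (Welch) two-sample
#' t-test, two-sided.  Chromosomes carrying no target bp are dropped.
#'
#' @param targets data.frame chrom/start/end.
#' @param states a `state_segmentation`.
#' @param genome_lengths named chromosome lengths (at least 2 chromosomes).
#' @return data.frame: state, t, df, p.
#' @export
state_welch_test <- function(targets, states, genome_lengths) {
  chroms <- names(genome_lengths)
  if (length(chroms) < 2) stop("need >= 2 chromosomes for the Welch test")
  labs <- unique(states$state)
  per_chrom <- lapply(chroms, function(chrom) {
    comp <- state_composition(targets[targets$chrom == chrom, , drop = FALSE],
                              states[states$chrom == chrom, , drop = FALSE],
                              genome_lengths[chrom])
    comp[match(labs, comp$state), c("genome_fraction", "target_fraction")]
  })
  t_bp <- vapply(chroms, function(chrom) {
    t <- targets[targets$chrom == chrom, , drop = FALSE]
    if (!nrow(t)) 0 else
      sum(GenomicRanges::width(GenomicRanges::reduce(GenomicRanges::GRanges(
        t$chrom, IRanges::IRanges(t$start + 1L, t$end)))))
  }, 0)
  use <- t_bp > 0
  if (sum(use) < 2) stop("need targets on >= 2 chromosomes")
  rows <- lapply(seq_along(labs), function(i) {
    x <- vapply(per_chrom[use], function(p) p$target_fraction[i], 0)
    y <- vapply(per_chrom[use], function(p) p$genome_fraction[i], 0)
    x[is.na(x)] <- 0; y[is.na(y)] <- 0
    if (var(x) == 0 && var(y) == 0) {
      if (isTRUE(all.equal(mean(x), mean(y))))
        return(data.frame(state = labs[i], t = 0, df = NA_real_, p = 1))
      return(data.frame(state = labs[i],
                        t = sign(mean(x) - mean(y)) * Inf,
                        df = NA_real_, p = 0))
    }
    tt <- t.test(x, y, var.equal = FALSE)
    data.frame(state = labs[i], t = unname(tt$statistic),
               df = unname(tt$parameter), p = tt$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Classify TSSs: minor filtering and bidirectional pairing
#'
#' Per gene, TSSs with CAGE expression strictly below `minor_fraction` of the
#' gene's strongest TSS are marked `filtered_minor`.  Among survivors, a TSS
#' is `bidirectional` when a surviving TSS on the opposite strand lies within
#' `bidir_max_dist` bp in divergent orientation (the `-` strand TSS at or
#' left of the `+` strand TSS, so the transcripts run apart and do not
#' intersect); all other survivors are `unidirectional`.
#'
#' @param tss data.frame: chrom, pos (0-based), strand, cage_tpm, gene_id.
#' @param minor_fraction minor-TSS threshold (default 0.01; strict `<`).
#' @param bidir_max_dist maximum TSS distance for a bidirectional pair
#'   (default 1000; strict `<`).
#' @return the input with a `class` column
#'   (`bidirectional`/`unidirectional`/`filtered_minor`).
#' @export
classify_tss <- function(tss, minor_fraction = 0.01, bidir_max_dist = 1000) {
  if (any(tss$cage_tpm < 0)) stop("negative CAGE expression")
  gene_max <- tapply(tss$cage_tpm, tss$gene_id, max)
  minor <- tss$cage_tpm < minor_fraction * gene_max[tss$gene_id]
  class <- rep("unidirectional", nrow(tss))
  class[minor] <- "filtered_minor"
  surv <- which(!minor)
  for (chrom in unique(tss$chrom[surv])) {
    here <- surv[tss$chrom[surv] == chrom]
    plus <- sort(tss$pos[here][tss$strand[here] == "+"])
    minus <- sort(tss$pos[here][tss$strand[here] == "-"])
    if (!length(plus) || !length(minus)) next
    for (i in here) {
      p <- tss$pos[i]
      hit <- if (tss$strand[i] == "+")
        any(minus <= p & minus > p - bidir_max_dist)
      else
        any(plus >= p & plus < p + bidir_max_dist)
      if (hit) class[i] <- "bidirectional"
    }
  }
  out <- tss
  out$class <- class
  out
}

#' srRNA coverage track from mapping records
#'
#' Per-base read-count-weighted coverage as a step-function track.
#'
#' @param records a `mapping_table`.
#' @param chrom_lengths named chromosome lengths.
#' @return a `signal_track` data.frame.
#' @export
mapping_coverage_track <- function(records, chrom_lengths) {
  out <- lapply(names(chrom_lengths), function(chrom) {
    L <- as.integer(chrom_lengths[[chrom]])
    r <- records[records$chrom == chrom, , drop = FALSE]
    if (!nrow(r))
      return(data.frame(chrom = chrom, start = 0L, end = L, value = 0,
                        stringsAsFactors = FALSE))
    cov <- IRanges::coverage(IRanges::IRanges(r$start + 1L, r$end),
                             weight = r$read_count, width = L)
    ends <- cumsum(S4Vectors::runLength(cov))
    data.frame(chrom = chrom, start = c(0L, ends[-length(ends)]),
               end = ends, value = as.numeric(S4Vectors::runValue(cov)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  class(out) <- c("signal_track", "data.frame")
  out
}

#' srRNA metaprofiles around classified TSSs
#'
#' Builds the srRNA mapping-coverage track and profiles it around the TSSs
#' of each promoter class (bidirectional, unidirectional).  Empty classes
#' are skipped with a warning.
#'
#' @param records a `mapping_table`.
#' @param classified_tss output of [classify_tss()].
#' @param flank,bin,zscore see [metaprofile()].
#' @param chrom_lengths named chromosome lengths.
#' @return named list of `metaprofile` objects.
#' @export
tss_metaprofile <- function(records, classified_tss, flank = 1500, bin = 10,
                            zscore = TRUE, chrom_lengths) {
  track <- mapping_coverage_track(records, chrom_lengths)
  out <- list()
  for (cls in c("bidirectional", "unidirectional")) {
    t <- classified_tss[classified_tss$class == cls, , drop = FALSE]
    if (!nrow(t)) {
      warning("no TSS in class ", cls, "; skipped")
      next
    }
    anchors <- data.frame(chrom = t$chrom, mid = t$pos,
                          stringsAsFactors = FALSE)
    out[[cls]] <- metaprofile(track, anchors, flank = flank, bin = bin,
                              zscore = zscore, chrom_lengths = chrom_lengths)
  }
  out
}
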