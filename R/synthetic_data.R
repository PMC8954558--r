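# Synthetic data generation.
#
# The generator emulates the study conditions at 1/10 scale: a 4.3-kb rDNA
# unit (5'ETS-18S-ITS1-5.8S-ITS2-28S-3'ETS followed by the intergenic
# spacer), a few-Mb genome with ~50 genes, diverged (~96% identity,
# optionally inverted) rDNA fragments planted inside introns and intergenic
# space, and ~50k srRNA-like reads (19-50 nt, mean 29, >99% sense strand)
# drawn from hotspot regions of the rDNA unit.

derive_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) * 131 + stage) %% 2147483647)
}

#' Default rDNA segment fractions
#'
#' Proportions of the rDNA unit taken by each segment, matching the layout of
#' the human ~43-kb unit (transcribed portion followed by the intergenic
#' spacer, which takes about 69% of the unit).
#'
#' @return named numeric vector summing to 1.
#' @export
default_rdna_fractions <- function() {
  c("5'ETS" = 0.085, "18S" = 0.044, "ITS1" = 0.026, "5.8S" = 0.004,
    "ITS2" = 0.026, "28S" = 0.119, "3'ETS" = 0.008, "IGS" = 0.688)
}

#' Generate a synthetic rDNA reference unit
#'
#' @param total_len total unit length in bp (default 4300, a 1/10-scale unit).
#' @param segment_fractions named fractions for the eight segments, in unit
#'   order; must sum to 1 (tolerance 1e-9).
#' @param seed integer seed.
#' @return an `rdna_reference` list: `name`, `sequence`, `segments`
#'   (data.frame label/start/end, 0-based half-open, tiling the unit) and
#'   `transcribed_end` (where IGS begins).
#' @export
make_rdna_reference <- function(total_len = 4300,
                                segment_fractions = default_rdna_fractions(),
                                seed = 1) {
  if (total_len < 1000) stop("total_len must be >= 1000")
  if (abs(sum(segment_fractions) - 1) > 1e-9)
    stop("segment_fractions must sum to 1")
  labels <- names(segment_fractions)
  lens <- round(segment_fractions * total_len)
  lens[length(lens)] <- total_len - sum(lens[-length(lens)])  # IGS absorbs rounding
  if (any(lens < 1)) stop("total_len too small for the given fractions")
  ends <- cumsum(lens)
  segments <- data.frame(label = labels, start = c(0, ends[-length(ends)]),
                         end = unname(ends), stringsAsFactors = FALSE)
  sequence <- withr::with_seed(seed,
    paste(sample(c("A", "C", "G", "T"), total_len, replace = TRUE),
          collapse = ""))
  structure(list(name = "rDNA_unit", sequence = sequence, segments = segments,
                 transcribed_end = segments$start[segments$label == "IGS"]),
            class = "rdna_reference")
}

#' Default srRNA hotspot regions of the rDNA unit
#'
#' Hotspots mirror the observed peak structure: a peak in 18S, a prominent
#' peak at 5.8S, several peaks in 28S with the strongest at the 5' region of
#' 28S, smaller peaks in the transcribed spacers.  Antisense hotspots sit in
#' the intergenic spacer.
#'
#' @param rdna an [make_rdna_reference()] object.
#' @param strand `"sense"` (default) or `"antisense"`.
#' @param width hotspot width in bp.
#' @param n_minor number of low-weight minor source regions spread across the
#'   transcribed portion in addition to the ten main peaks (the real unit
#'   sources srRNAs from many regions, not only the main peaks; minor
#'   regions overlapping a main peak are dropped).
#' @return data.frame with `start`, `end`, `weight`, `label`.
#' @export
default_srrna_hotspots <- function(rdna, strand = c("sense", "antisense"),
                                   width = 60, n_minor = 15) {
  strand <- match.arg(strand)
  seg <- rdna$segments
  at <- function(label, frac, weight) {
    s <- seg[seg$label == label, ]
    center <- s$start + floor(frac * (s$end - s$start))
    start <- max(0L, center - width %/% 2)
    end <- min(nchar(rdna$sequence) - 60L, start + width)
    data.frame(start = start, end = end, weight = weight,
               label = sprintf("%s_%.2f", label, frac),
               stringsAsFactors = FALSE)
  }
  if (strand == "sense") {
    out <- rbind(at("5'ETS", 0.5, 0.5), at("18S", 0.5, 1.0),
                 at("ITS1", 0.5, 0.4), at("5.8S", 0.5, 2.0),
                 at("ITS2", 0.5, 0.5), at("28S", 0.05, 4.0),
                 at("28S", 0.25, 1.2), at("28S", 0.45, 1.0),
                 at("28S", 0.65, 1.0), at("28S", 0.85, 1.2))
    if (n_minor > 0) {
      tlen <- rdna$transcribed_end
      centers <- floor(seq(0.04, 0.96, length.out = n_minor) * tlen)
      minor <- data.frame(start = pmax(0L, centers - width %/% 2L),
                          end = pmax(0L, centers - width %/% 2L) + width,
                          weight = 0.3,
                          label = sprintf("minor_%02d", seq_len(n_minor)),
                          stringsAsFactors = FALSE)
      keep <- vapply(seq_len(nrow(minor)), function(i)
        !any(minor$start[i] < out$end + 20 & minor$end[i] > out$start - 20),
        logical(1))
      out <- rbind(out, minor[keep, ])
    }
  } else {
    out <- rbind(at("IGS", 0.3, 1.0), at("IGS", 0.6, 1.0))
  }
  rownames(out) <- NULL
  out
}

#' Generate a random genome
#'
#' @param chrom_lengths named integer vector of chromosome lengths.
#' @param seed integer seed.
#' @return named character vector of chromosome sequences.
#' @export
sim_genome <- function(chrom_lengths = c(chr1 = 400000L, chr2 = 400000L,
                                         chr3 = 400000L),
                       seed = 1) {
  withr::with_seed(seed, {
    setNames(vapply(chrom_lengths, function(L)
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""),
      ""), names(chrom_lengths))
  })
}

#' Generate a synthetic gene annotation
#'
#' Genes are placed left to right along each chromosome with random strands
#' and multi-exon structure (introns are at least ~600 bp so planted
#' fragments fit inside them).  A configurable fraction of gene pairs is
#' placed head-to-head with a small gap, giving divergent (bidirectional)
#' promoter pairs for the TSS analysis.
#'
#' @param chrom_lengths named chromosome lengths.
#' @param n_genes total number of genes.
#' @param gene_length_range min/max gene length.
#' @param n_exons_range min/max number of exons per gene.
#' @param min_gap minimum intergenic gap in bp.
#' @param bidir_fraction fraction of genes started as a divergent pair.
#' @param seed integer seed.
#' @return list with `genes` (gene_id, name, chrom, start, end, strand) and
#'   `exons` / `introns` data.frames, all 0-based half-open.
#' @export
sim_gene_annotation <- function(chrom_lengths = c(chr1 = 400000L,
                                                  chr2 = 400000L,
                                                  chr3 = 400000L),
                                n_genes = 60,
                                gene_length_range = c(6000, 12000),
                                n_exons_range = c(3, 5),
                                min_gap = 2000,
                                bidir_fraction = 0.2,
                                seed = 1) {
  withr::with_seed(seed, {
    chroms <- rep(names(chrom_lengths), length.out = n_genes)
    chroms <- sort(chroms)
    genes <- list(); exons <- list()
    gi <- 0L
    for (chrom in names(chrom_lengths)) {
      n_here <- sum(chroms == chrom)
      pos <- round(runif(1, min_gap, 2 * min_gap))
      i <- 0L
      while (i < n_here) {
        pair <- (runif(1) < bidir_fraction) && (i + 2L <= n_here)
        for (k in seq_len(if (pair) 2L else 1L)) {
          gi <- gi + 1L; i <- i + 1L
          glen <- round(runif(1, gene_length_range[1], gene_length_range[2]))
          if (pos + glen > chrom_lengths[[chrom]] - min_gap) {
            gi <- gi - 1L; i <- n_here  # chromosome full
            break
          }
          strand <- if (pair) c("-", "+")[k] else sample(c("+", "-"), 1)
          gene_id <- sprintf("GENE%04d", gi)
          genes[[gi]] <- data.frame(
            gene_id = gene_id, name = sprintf("SYM%04d", gi), chrom = chrom,
            start = pos, end = pos + glen, strand = strand,
            stringsAsFactors = FALSE)
          n_ex <- sample(seq(n_exons_range[1], n_exons_range[2]), 1)
          ex_len <- round(runif(n_ex, 150, 400))
          intron_total <- glen - sum(ex_len)
          intron_len <- rep(intron_total %/% (n_ex - 1L), n_ex - 1L)
          intron_len[1] <- intron_len[1] + intron_total %% (n_ex - 1L)
          es <- pos + c(0, cumsum(ex_len[-n_ex] + intron_len))
          exons[[gi]] <- data.frame(gene_id = gene_id, chrom = chrom,
                                    start = es, end = es + ex_len,
                                    stringsAsFactors = FALSE)
          gap <- if (pair && k == 1L) round(runif(1, 100, 800))
                 else round(runif(1, min_gap, 2 * min_gap))
          pos <- pos + glen + gap
        }
      }
    }
    genes <- do.call(rbind, genes)
    exons <- do.call(rbind, exons)
    introns <- do.call(rbind, lapply(split(exons, exons$gene_id), function(e) {
      e <- e[order(e$start), ]
      if (nrow(e) < 2) return(NULL)
      data.frame(gene_id = e$gene_id[1], chrom = e$chrom[1],
                 start = e$end[-nrow(e)], end = e$start[-1],
                 stringsAsFactors = FALSE)
    }))
    rownames(genes) <- rownames(exons) <- rownames(introns) <- NULL
    list(genes = genes, exons = exons, introns = introns)
  })
}

#' Plant diverged rDNA fragments into a genome
#'
#' Copies subsequences of the rDNA unit (each overlapping an srRNA hotspot,
#' so reads drawn from hotspots can map to the planted copies), diverges them
#' by per-base substitution with probability `1 - identity` (no indels),
#' optionally reverse-complements them (antisense orientation), and writes
#' them into introns and intergenic space.
#'
#' @param genome named character vector of chromosome sequences.
#' @param genes a [sim_gene_annotation()] result.
#' @param rdna an [make_rdna_reference()] object.
#' @param n_fragments number of fragments to plant.
#' @param identity per-base identity of planted copies, in (0.5, 1].
#' @param antisense_prob probability a fragment is inserted in antisense
#'   orientation.
#' @param intergenic_fraction fraction of fragments placed outside genes.
#' @param length_range min/max fragment length.
#' @param hotspots hotspot data.frame (see [default_srrna_hotspots()]); each
#'   fragment's rDNA source interval contains a hotspot center.
#' @param seed integer seed.
#' @return list with the modified `genome` and `fragments`, a truth
#'   data.frame (chrom, start, end, source_label, source_start, source_end,
#'   orientation, identity, host_gene_id; `NA` host for intergenic).
#' @export
plant_fragments <- function(genome, genes, rdna, n_fragments = 45,
                            identity = 0.9632, antisense_prob = 0.3,
                            intergenic_fraction = 0.2,
                            length_range = c(110, 200),
                            hotspots = default_srrna_hotspots(rdna),
                            seed = 1) {
  if (identity <= 0.5 || identity > 1)
    stop("identity must be in (0.5, 1]")
  rdna_len <- nchar(rdna$sequence)
  withr::with_seed(seed, {
    n_intronic <- round(n_fragments * (1 - intergenic_fraction))
    n_intergenic <- n_fragments - n_intronic
    g <- genes$genes
    introns <- genes$introns
    host_pool <- unique(introns$gene_id)
    if (length(host_pool) < n_intronic)
      stop("genome too small: not enough genes with introns to host ",
           n_intronic, " fragments")
    hosts <- sample(host_pool, n_intronic)
    placed <- data.frame(chrom = character(), start = integer(),
                         end = integer(), stringsAsFactors = FALSE)
    frags <- list()
    # Substitutions are stratified: one per block of ~1/(1 - identity) bp at
    # a random in-block position (a partial trailing block is mutated with
    # matching probability).  The realized substitution rate is exact and
    # divergence cannot cluster locally, so every part of a planted copy
    # stays reachable by mismatch-capped read alignment.
    mutate_seq <- function(s) {
      if (identity >= 1) return(s)
      v <- strsplit(s, "")[[1]]
      Lb <- max(1L, round(1 / (1 - identity)))
      for (b in seq(1L, length(v), by = Lb)) {
        e <- min(b + Lb - 1L, length(v))
        w <- e - b + 1L
        if (w == Lb || runif(1) < w / Lb) {
          i <- b + sample.int(w, 1) - 1L
          v[i] <- sample(setdiff(c("A", "C", "G", "T"), v[i]), 1)
        }
      }
      paste(v, collapse = "")
    }
    # Hotspots are dealt round-robin (shuffled), and a hotspot dealt to
    # several fragments is partitioned among them, each fragment sourcing
    # one sub-interval plus the maximum read length of right margin.  Reads
    # map to their single best locus, so near-identical sibling copies of
    # the same region would otherwise compete: the partition guarantees
    # every fragment a private pool of read windows (a read starting inside
    # its sub-interval always lies fully inside its copy).  The left pad is
    # capped so one copy's source does not sprawl over a neighbour's
    # territory.
    max_read_len <- 50L
    pad_max <- 20L
    deal <- sample(rep(sample.int(nrow(hotspots)), length.out = n_fragments))
    sub_start <- integer(n_fragments); sub_end <- integer(n_fragments)
    for (h in unique(deal)) {
      ix <- which(deal == h)
      m <- length(ix)
      w <- hotspots$end[h] - hotspots$start[h]
      bounds <- hotspots$start[h] + round(seq(0, w, length.out = m + 1))
      ord <- sample.int(m)
      sub_start[ix] <- bounds[ord]
      sub_end[ix] <- bounds[ord + 1]
    }
    draw_source <- function(j, len) {
      span_end <- min(sub_end[j] + max_read_len, rdna_len)
      span <- span_end - sub_start[j]
      len <- max(span, min(len, span + pad_max))
      s <- max(0L, span_end - len)
      c(s, span_end)
    }
    for (j in seq_len(n_fragments)) {
      len <- round(runif(1, length_range[1], length_range[2]))
      src <- draw_source(j, len)
      len <- src[2] - src[1]  # source span caps the drawn length
      seq0 <- substring(rdna$sequence, src[1] + 1, src[2])
      seqm <- mutate_seq(seq0)
      orient <- if (runif(1) < antisense_prob) "antisense" else "sense"
      ins <- if (orient == "antisense") revcomp(seqm) else seqm
      if (j <= n_intronic) {
        gene_id <- hosts[j]
        intr <- introns[introns$gene_id == gene_id, ]
        intr <- intr[(intr$end - intr$start) >= len + 20, ]
        if (!nrow(intr)) stop("no intron large enough in ", gene_id,
                              " for a ", len, " bp fragment")
        it <- intr[sample.int(nrow(intr), 1), ]
        start <- it$start + sample.int(it$end - it$start - len, 1)
        chrom <- it$chrom
        host <- gene_id
      } else {
        ok <- FALSE
        for (try in seq_len(1000)) {
          chrom <- sample(names(genome), 1)
          start <- sample.int(nchar(genome[[chrom]]) - len, 1)
          near_gene <- any(g$chrom == chrom & start < g$end + 200 &
                             start + len > g$start - 200)
          near_frag <- any(placed$chrom == chrom & start < placed$end + 50 &
                             start + len > placed$start - 50)
          if (!near_gene && !near_frag) { ok <- TRUE; break }
        }
        if (!ok) stop("genome too small to place intergenic fragments ",
                      "without overlap")
        host <- NA_character_
      }
      substr(genome[[chrom]], start + 1, start + len) <- ins
      placed <- rbind(placed, data.frame(chrom = chrom, start = start,
                                         end = start + len,
                                         stringsAsFactors = FALSE))
      mid <- floor((src[1] + src[2]) / 2)
      seg <- rdna$segments
      lab <- seg$label[seg$start <= mid & mid < seg$end]
      frags[[j]] <- data.frame(
        chrom = chrom, start = start, end = start + len,
        source_label = lab, source_start = src[1], source_end = src[2],
        orientation = orient, identity = identity, host_gene_id = host,
        stringsAsFactors = FALSE)
    }
    list(genome = genome, fragments = do.call(rbind, frags))
  })
}

# Discretised two-component truncated-normal read-length model.  The narrow
# component sits at the observed 25/26-nt twin peak; the broad component
# supplies the right tail so the overall mean hits `mean_len`.
sim_read_lengths <- function(n, length_range = c(19L, 50L), mean_len = 29,
                             peak_mean = 25.5, peak_sd = 2, peak_weight = 0.62,
                             broad_sd = 8) {
  broad_mean <- (mean_len - peak_weight * peak_mean) / (1 - peak_weight)
  comp <- runif(n) < peak_weight
  len <- round(ifelse(comp, rnorm(n, peak_mean, peak_sd),
                      rnorm(n, broad_mean, broad_sd)))
  bad <- which(len < length_range[1] | len > length_range[2])
  while (length(bad)) {
    comp <- runif(length(bad)) < peak_weight
    len[bad] <- round(ifelse(comp, rnorm(length(bad), peak_mean, peak_sd),
                             rnorm(length(bad), broad_mean, broad_sd)))
    bad <- bad[len[bad] < length_range[1] | len[bad] > length_range[2]]
  }
  as.integer(len)
}

#' Simulate srRNA-like reads from rDNA hotspots
#'
#' Reads start inside a weighted hotspot and run 3' along the unit; antisense
#' reads are the reverse complement of the sampled window.  Read lengths
#' follow a discretised two-component truncated normal on
#' `[length_range[1], length_range[2]]` with mean `mean_len` and a narrow
#' peak at 25/26 nt.  Qualities are a Q38-40 plateau with optional
#' low-quality 5'/3' tails so that quality trimming is exercised.
#'
#' @param rdna an [make_rdna_reference()] object.
#' @param hotspots data.frame start/end/weight (see
#'   [default_srrna_hotspots()]); reads start inside these intervals.
#' @param n_reads number of reads.
#' @param length_range,mean_len read-length model (defaults 19-50, mean 29).
#' @param sense_fraction fraction of sense-strand reads (default 0.995).
#' @param error_rate per-base sequencing substitution rate (default 0.003).
#' @param antisense_hotspots optional hotspot table for antisense reads
#'   (defaults to `hotspots`).
#' @param quality_model list: `plateau` (range of high scores), `tail_prob`
#'   (probability of a low-quality tail at either end), `tail_max` (max tail
#'   length), `tail_q` (range of tail scores).
#' @param seed integer seed.
#' @return list with `reads` (a [small_read_set()]) and `truth` (read_id,
#'   origin_start, origin_end, strand, hotspot label).
#' @export
simulate_srrna_reads <- function(rdna, hotspots = default_srrna_hotspots(rdna),
                                 n_reads = 50000,
                                 length_range = c(19L, 50L), mean_len = 29,
                                 sense_fraction = 0.995,
                                 error_rate = 0.003,
                                 antisense_hotspots = NULL,
                                 quality_model = list(plateau = c(38L, 40L),
                                                      tail_prob = 0.2,
                                                      tail_max = 3L,
                                                      tail_q = c(8L, 17L)),
                                 seed = 1) {
  if (is.null(hotspots) || !nrow(hotspots)) stop("hotspot list is empty")
  rdna_len <- nchar(rdna$sequence)
  if (any(hotspots$start < 0) || any(hotspots$end > rdna_len))
    stop("hotspots must lie within [0, rdna length)")
  if (is.null(antisense_hotspots)) antisense_hotspots <- hotspots
  withr::with_seed(seed, {
    len <- sim_read_lengths(n_reads, length_range, mean_len)
    sense <- runif(n_reads) < sense_fraction
    hs <- function(tab, m) tab[sample.int(nrow(tab), m, replace = TRUE,
                                          prob = tab$weight), , drop = FALSE]
    pick <- data.frame(start = integer(n_reads), label = character(n_reads),
                       stringsAsFactors = FALSE)
    for (grp in list(which(sense), which(!sense))) {
      if (!length(grp)) next
      tab <- if (identical(grp, which(sense))) hotspots else antisense_hotspots
      h <- hs(tab, length(grp))
      pick$start[grp] <- h$start +
        floor(runif(length(grp)) * pmax(1, h$end - h$start))
      pick$label[grp] <- if (is.null(h$label)) "" else h$label
    }
    start <- pmin(pick$start, rdna_len - len)
    seqs <- substring(rdna$sequence, start + 1, start + len)
    if (any(!sense)) seqs[!sense] <- revcomp(seqs[!sense])
    if (error_rate > 0) {
      err <- which(runif(sum(len)) < error_rate)
      if (length(err)) {
        read_of <- rep.int(seq_len(n_reads), len)
        offset_of <- sequence(len)
        for (e in err) {
          i <- read_of[e]; o <- offset_of[e]
          old <- substr(seqs[i], o, o)
          substr(seqs[i], o, o) <- sample(setdiff(c("A", "C", "G", "T"), old), 1)
        }
      }
    }
    # qualities: plateau, then low-quality tails on a subset of reads
    qm <- quality_model
    total <- sum(len)
    f <- rep.int(seq_len(n_reads), len)
    q <- sample(seq(qm$plateau[1], qm$plateau[2]), total, replace = TRUE)
    qlist <- split(q, f)
    tail5 <- runif(n_reads) < qm$tail_prob
    tail3 <- runif(n_reads) < qm$tail_prob
    for (i in which(tail5 | tail3)) {
      v <- qlist[[i]]
      if (tail5[i]) {
        t5 <- sample.int(qm$tail_max, 1)
        v[seq_len(min(t5, length(v)))] <-
          sample(seq(qm$tail_q[1], qm$tail_q[2]), min(t5, length(v)),
                 replace = TRUE)
      }
      if (tail3[i]) {
        t3 <- sample.int(qm$tail_max, 1)
        idx <- seq(length(v) - min(t3, length(v)) + 1, length(v))
        v[idx] <- sample(seq(qm$tail_q[1], qm$tail_q[2]), length(idx),
                         replace = TRUE)
      }
      qlist[[i]] <- v
    }
    quality <- vapply(qlist, function(v) intToUtf8(v + 33L), "",
                      USE.NAMES = FALSE)
    read_id <- sprintf("read%06d", seq_len(n_reads))
    reads <- small_read_set(read_id, seqs, quality)
    truth <- data.frame(read_id = read_id, origin_start = start,
                        origin_end = start + len,
                        strand = ifelse(sense, "+", "-"),
                        hotspot = pick$label, stringsAsFactors = FALSE)
    list(reads = reads, truth = truth)
  })
}

#' Simulate a zero-inflated log-normal expression table
#'
#' Gene-level expression (TPM) is modelled as a point mass at zero plus a
#' log-normal for expressed genes, the standard shape of bulk expression
#' tables (which are far from normal, hence the rank-based testing
#' machinery).
#'
#' @param n_genes number of genes (default 60522, mirroring the annotated
#'   gene universe used for the overlap statistics).
#' @param zero_fraction exact fraction of zero values, in `[0, 1)`.
#' @param meanlog,sdlog log-normal parameters of the expressed genes.
#' @param gene_ids optional gene identifiers (generated if `NULL`).
#' @param seed integer seed.
#' @return data.frame with `gene_id` and `tpm`.
#' @export
simulate_expression_table <- function(n_genes = 60522, zero_fraction = 0.4,
                                      meanlog = 1, sdlog = 2,
                                      gene_ids = NULL, seed = 1) {
  if (n_genes < 2) stop("n_genes must be >= 2")
  if (zero_fraction < 0 || zero_fraction >= 1)
    stop("zero_fraction must be in [0, 1)")
  if (is.null(gene_ids)) gene_ids <- sprintf("BG%06d", seq_len(n_genes))
  if (length(gene_ids) != n_genes) stop("gene_ids length must equal n_genes")
  withr::with_seed(seed, {
    tpm <- rlnorm(n_genes, meanlog, sdlog)
    n_zero <- round(zero_fraction * n_genes)
    if (n_zero > 0) tpm[sample.int(n_genes, n_zero)] <- 0
    data.frame(gene_id = gene_ids, tpm = tpm, stringsAsFactors = FALSE)
  })
}

#' Chromatin-state labels of the core 15-state model
#' @return character vector of 15 state labels.
#' @export
roadmap15_states <- function() {
  c("1_TssA", "2_TssAFlnk", "3_TxFlnk", "4_Tx", "5_TxWk", "6_EnhG", "7_Enh",
    "8_ZNF/Rpts", "9_Het", "10_TssBiv", "11_BivFlnk", "12_EnhBiv",
    "13_ReprPC", "14_ReprPCWk", "15_Quies")
}

#' Simulate a chromatin-state segmentation
#'
#' Segments tile each chromosome exactly; labels are drawn independently per
#' segment with the given weights.
#'
#' @param chrom_lengths named chromosome lengths.
#' @param n_states number of states.
#' @param mean_segment_len mean segment length (exponential, discretised).
#' @param state_weights per-state sampling weights (uniform if `NULL`).
#' @param state_labels state names (defaults to [roadmap15_states()]).
#' @param seed integer seed.
#' @return `state_segmentation` data.frame: chrom, start, end, state.
#' @export
simulate_state_segmentation <- function(chrom_lengths, n_states = 15,
                                        mean_segment_len = 2000,
                                        state_weights = NULL,
                                        state_labels = roadmap15_states(),
                                        seed = 1) {
  if (is.null(state_weights)) state_weights <- rep(1 / n_states, n_states)
  if (length(state_weights) != n_states)
    stop("state_weights must have length n_states")
  if (length(state_labels) != n_states)
    stop("state_labels must have length n_states")
  withr::with_seed(seed, {
    out <- lapply(names(chrom_lengths), function(chrom) {
      L <- chrom_lengths[[chrom]]
      lens <- integer(0)
      while (sum(lens) < L)
        lens <- c(lens, pmax(1L, round(rexp(max(16, ceiling(L / mean_segment_len)),
                                            1 / mean_segment_len))))
      lens <- lens[cumsum(lens) - lens < L]
      ends <- pmin(cumsum(lens), L)
      starts <- c(0, ends[-length(ends)])
      keep <- ends > starts
      data.frame(chrom = chrom, start = starts[keep], end = ends[keep],
                 state = sample(state_labels, sum(keep), replace = TRUE,
                                prob = state_weights),
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, out)
    class(out) <- c("state_segmentation", "data.frame")
    out
  })
}

#' Simulate a step-function signal track
#'
#' A bedGraph-style step function with noisy baseline and an elevated mean
#' inside `enriched_regions` (`mean(inside)/mean(outside)` is approximately
#' `enrichment`).  `enrichment = 0` disables elevation (flat-mean track).
#'
#' @param chrom_lengths named chromosome lengths.
#' @param enriched_regions optional data.frame chrom/start/end; overlapping
#'   regions are merged with a warning.
#' @param enrichment fold elevation of the mean inside enriched regions.
#' @param step_len step length in bp.
#' @param base_mean,noise_sd baseline normal parameters (values floored at 0).
#' @param seed integer seed.
#' @return `signal_track` data.frame: chrom, start, end, value (sorted,
#'   non-overlapping, tiling each chromosome).
#' @export
simulate_signal_track <- function(chrom_lengths, enriched_regions = NULL,
                                  enrichment = 5, step_len = 200,
                                  base_mean = 1, noise_sd = 0.25, seed = 1) {
  if (enrichment < 0) stop("enrichment must be >= 0")
  if (!is.null(enriched_regions) && nrow(enriched_regions)) {
    gr <- GenomicRanges::GRanges(enriched_regions$chrom,
      IRanges::IRanges(enriched_regions$start + 1, enriched_regions$end))
    red <- GenomicRanges::reduce(gr)
    if (length(red) < length(gr))
      warning("overlapping enriched regions merged")
    enriched_regions <- data.frame(
      chrom = as.character(GenomicRanges::seqnames(red)),
      start = GenomicRanges::start(red) - 1L,
      end = GenomicRanges::end(red), stringsAsFactors = FALSE)
  }
  withr::with_seed(seed, {
    out <- lapply(names(chrom_lengths), function(chrom) {
      L <- chrom_lengths[[chrom]]
      brk <- seq(0L, L, by = step_len)
      if (brk[length(brk)] < L) brk <- c(brk, L)
      if (!is.null(enriched_regions)) {
        er <- enriched_regions[enriched_regions$chrom == chrom, ]
        brk <- sort(unique(c(brk, er$start, er$end)))
        brk <- brk[brk >= 0 & brk <= L]
      }
      start <- brk[-length(brk)]; end <- brk[-1]
      value <- pmax(0, rnorm(length(start), base_mean, noise_sd))
      if (!is.null(enriched_regions) && enrichment > 0) {
        er <- enriched_regions[enriched_regions$chrom == chrom, ]
        if (nrow(er)) {
          mid <- (start + end) / 2
          inside <- vapply(mid, function(m)
            any(er$start <= m & m < er$end), logical(1))
          value[inside] <- value[inside] * enrichment
        }
      }
      data.frame(chrom = chrom, start = start, end = end, value = value,
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, out)
    class(out) <- c("signal_track", "data.frame")
    out
  })
}
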