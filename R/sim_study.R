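# Full synthetic study bundle: every input the pipeline consumes plus the
# ground-truth records needed for recovery testing.

#' Simulate a TSS/CAGE table for a gene annotation
#'
#' Each gene gets a major TSS at its 5' end; a fraction of genes gets an
#' additional interior minor TSS with low relative expression (some below the
#' 1% minor-TSS threshold, so the filtering rule is exercised).
#'
#' @param genes a [sim_gene_annotation()] result.
#' @param minor_prob probability a gene carries a second, minor TSS.
#' @param seed integer seed.
#' @return data.frame: chrom, pos (0-based), strand, cage_tpm, gene_id.
#' @export
sim_tss_table <- function(genes, minor_prob = 0.4, seed = 1) {
  g <- genes$genes
  withr::with_seed(seed, {
    pos <- ifelse(g$strand == "+", g$start, g$end - 1L)
    major <- data.frame(chrom = g$chrom, pos = as.integer(pos),
                        strand = g$strand,
                        cage_tpm = rlnorm(nrow(g), 2, 1),
                        gene_id = g$gene_id, stringsAsFactors = FALSE)
    has_minor <- runif(nrow(g)) < minor_prob
    minor <- major[has_minor, ]
    if (nrow(minor)) {
      shift <- sample(200:2000, nrow(minor), replace = TRUE)
      minor$pos <- as.integer(ifelse(minor$strand == "+", minor$pos + shift,
                                     minor$pos - shift))
      minor$cage_tpm <- minor$cage_tpm * runif(nrow(minor), 0.001, 0.2)
    }
    out <- rbind(major, minor)
    out[order(out$chrom, out$pos), , drop = FALSE]
  })
}

#' Default configuration of the synthetic study
#'
#' The study conditions at 1/10 scale: a 4.3-kb rDNA unit, a 1.2-Mb genome
#' over three chromosomes with 60 genes, 45 planted rDNA fragments at 96.32%
#' identity (30% antisense), 50,000 reads of 19-50 nt (mean 29 nt, 99.5%
#' sense), and a 60,522-gene zero-inflated log-normal expression universe.
#'
#' @return named list of generator parameters.
#' @export
default_study_config <- function() {
  list(rdna_length = 4300L,
       chrom_lengths = c(chr1 = 400000L, chr2 = 400000L, chr3 = 400000L),
       n_genes = 60L,
       n_reads = 50000L,
       n_fragments = 45L,
       identity = 0.9632,
       antisense_prob = 0.3,
       intergenic_fraction = 0.2,
       sense_fraction = 0.995,
       mean_len = 29,
       length_range = c(19L, 50L),
       zero_fraction = 0.4,
       n_expression_genes = 60522L,
       n_contacting_genes = 25L,
       track_enrichment = 5)
}

#' Generate the complete synthetic study
#'
#' Runs every generator with seeds derived from one master seed and, if
#' `outdir` is given, writes all standard-format files (FASTA, FASTQ, GFF3,
#' BED, bedGraph, TSV, JSON truth).
#'
#' @param config named list overriding entries of [default_study_config()].
#' @param seed master integer seed.
#' @param outdir optional output directory.
#' @return list with all inputs plus `truth` (`planted_fragments`,
#'   `hotspot_regions`, `true_target_genes`, per-read origins in
#'   `read_truth`).
#' @export
sim_srrna_study <- function(config = list(), seed = 1, outdir = NULL) {
  cfg <- default_study_config()
  unknown <- setdiff(names(config), names(cfg))
  if (length(unknown)) stop("unknown config keys: ",
                            paste(unknown, collapse = ", "))
  cfg[names(config)] <- config
  rdna <- make_rdna_reference(cfg$rdna_length, seed = derive_seed(seed, 1))
  hotspots <- default_srrna_hotspots(rdna)
  genome0 <- sim_genome(cfg$chrom_lengths, seed = derive_seed(seed, 2))
  genes <- sim_gene_annotation(cfg$chrom_lengths, cfg$n_genes,
                               seed = derive_seed(seed, 3))
  planted <- plant_fragments(genome0, genes, rdna,
                             n_fragments = cfg$n_fragments,
                             identity = cfg$identity,
                             antisense_prob = cfg$antisense_prob,
                             intergenic_fraction = cfg$intergenic_fraction,
                             hotspots = hotspots,
                             seed = derive_seed(seed, 4))
  sim <- simulate_srrna_reads(rdna, hotspots, n_reads = cfg$n_reads,
                              length_range = cfg$length_range,
                              mean_len = cfg$mean_len,
                              sense_fraction = cfg$sense_fraction,
                              antisense_hotspots =
                                default_srrna_hotspots(rdna, "antisense"),
                              seed = derive_seed(seed, 5))
  gene_ids <- c(genes$genes$gene_id,
                sprintf("BG%06d",
                        seq_len(cfg$n_expression_genes - nrow(genes$genes))))
  expression <- simulate_expression_table(cfg$n_expression_genes,
                                          zero_fraction = cfg$zero_fraction,
                                          gene_ids = gene_ids,
                                          seed = derive_seed(seed, 6))
  states <- simulate_state_segmentation(cfg$chrom_lengths,
                                        seed = derive_seed(seed, 7))
  frag <- planted$fragments
  enr <- data.frame(chrom = frag$chrom,
                    start = pmax(0L, frag$start - 200L),
                    end = frag$end + 200L, stringsAsFactors = FALSE)
  track <- simulate_signal_track(cfg$chrom_lengths, enriched_regions = enr,
                                 enrichment = cfg$track_enrichment,
                                 seed = derive_seed(seed, 8))
  tss <- sim_tss_table(genes, seed = derive_seed(seed, 9))
  true_targets <- sort(unique(frag$host_gene_id[!is.na(frag$host_gene_id)]))
  contacting <- withr::with_seed(derive_seed(seed, 10), {
    n_shared <- min(length(true_targets),
                    round(0.4 * cfg$n_contacting_genes))
    shared <- sample(true_targets, n_shared)
    others <- sample(setdiff(genes$genes$gene_id, shared),
                     cfg$n_contacting_genes - n_shared)
    sort(c(shared, others))
  })
  study <- list(
    config = cfg, seed = seed,
    rdna = rdna, hotspots = hotspots, genome = planted$genome, genes = genes,
    fragments = frag, reads = sim$reads, read_truth = sim$truth,
    expression = expression, states = states, track = track, tss = tss,
    contacting_genes = contacting,
    truth = list(planted_fragments = frag,
                 hotspot_regions = hotspots,
                 true_target_genes = true_targets))
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    fp <- function(x) file.path(outdir, x)
    write_fasta(rdna, fp("rdna.fa"))
    write_fasta(planted$genome, fp("genome.fa"))
    write_fastq(sim$reads, fp("reads.fastq"))
    write_genes_gff3(genes, fp("genes.gff3"))
    frag_bed <- frag
    write_tsv(frag_bed, fp("planted_fragments.tsv"))
    write_states_bed(states, fp("states.bed"))
    write_bedgraph(track, fp("signal.bedGraph"))
    write_tsv(expression, fp("expression.tsv"))
    write_tsv(tss, fp("tss.tsv"))
    writeLines(contacting, fp("contacting_genes.txt"))
    write_tsv(sim$truth, fp("read_truth.tsv"))
    jsonlite::write_json(list(true_target_genes = true_targets,
                              planted_fragments = frag,
                              hotspots = hotspots,
                              seed = seed),
                         fp("truth.json"), auto_unbox = TRUE, digits = NA)
  }
  study
}
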