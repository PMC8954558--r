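# File-format boundaries.  Internally everything is 0-based half-open;
# rtracklayer/GenomicRanges (1-based closed) conversions happen here.

#' Write named sequences as FASTA
#' @param sequences named character vector (or an `rdna_reference`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path) {
  if (inherits(sequences, "rdna_reference"))
    sequences <- setNames(sequences$sequence, sequences$name)
  x <- Biostrings::DNAStringSet(sequences)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a FASTA file as a named character vector
#' @param path FASTA path.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

df_to_granges <- function(df, extra = NULL) {
  gr <- GenomicRanges::GRanges(df$chrom,
    IRanges::IRanges(df$start + 1, df$end),
    strand = if ("strand" %in% names(df)) df$strand else "*")
  for (nm in extra) S4Vectors::mcols(gr)[[nm]] <- df[[nm]]
  gr
}

granges_to_df <- function(gr) {
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}

#' Write a gene annotation as GFF3
#'
#' Emits `gene` and `exon` features (1-based inclusive coordinates, as GFF3
#' requires) with `ID`/`Name` attributes.
#'
#' @param genes a [sim_gene_annotation()] result.
#' @param path output path.
#' @export
write_genes_gff3 <- function(genes, path) {
  g <- genes$genes
  ggr <- GenomicRanges::GRanges(g$chrom, IRanges::IRanges(g$start + 1, g$end),
                                strand = g$strand)
  S4Vectors::mcols(ggr)$type <- "gene"
  S4Vectors::mcols(ggr)$ID <- g$gene_id
  S4Vectors::mcols(ggr)$Name <- g$name
  e <- genes$exons
  st <- g$strand[match(e$gene_id, g$gene_id)]
  egr <- GenomicRanges::GRanges(e$chrom, IRanges::IRanges(e$start + 1, e$end),
                                strand = st)
  S4Vectors::mcols(egr)$type <- "exon"
  S4Vectors::mcols(egr)$Parent <- e$gene_id
  rtracklayer::export(c(ggr, egr), path, format = "gff3")
  invisible(path)
}

#' Read a GFF3 gene annotation
#'
#' Returns the same list structure as [sim_gene_annotation()] (0-based
#' half-open), reconstructing introns from exons.
#'
#' @param path GFF3 path.
#' @export
read_genes_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  gg <- gr[gr$type == "gene"]
  genes <- data.frame(gene_id = as.character(gg$ID),
                      name = as.character(gg$Name),
                      chrom = as.character(GenomicRanges::seqnames(gg)),
                      start = GenomicRanges::start(gg) - 1L,
                      end = GenomicRanges::end(gg),
                      strand = as.character(GenomicRanges::strand(gg)),
                      stringsAsFactors = FALSE)
  ee <- gr[gr$type == "exon"]
  parent <- vapply(ee$Parent, function(p) as.character(p)[1], "")
  exons <- data.frame(gene_id = parent,
                      chrom = as.character(GenomicRanges::seqnames(ee)),
                      start = GenomicRanges::start(ee) - 1L,
                      end = GenomicRanges::end(ee),
                      stringsAsFactors = FALSE)
  introns <- do.call(rbind, lapply(split(exons, exons$gene_id), function(e) {
    e <- e[order(e$start), ]
    if (nrow(e) < 2) return(NULL)
    data.frame(gene_id = e$gene_id[1], chrom = e$chrom[1],
               start = e$end[-nrow(e)], end = e$start[-1],
               stringsAsFactors = FALSE)
  }))
  rownames(exons) <- rownames(introns) <- NULL
  list(genes = genes, exons = exons, introns = introns)
}

#' Write a chromatin-state segmentation as BED (col 4 = state label)
#' @param states a `state_segmentation` data.frame.
#' @param path output path.
#' @export
write_states_bed <- function(states, path) {
  gr <- df_to_granges(states)
  S4Vectors::mcols(gr)$name <- states$state
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' Read a chromatin-state segmentation from BED
#' @param path BED path (column 4 holds the state label).
#' @export
read_states_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  out <- granges_to_df(gr)
  out$state <- as.character(gr$name)
  class(out) <- c("state_segmentation", "data.frame")
  out
}

#' Write a signal track as bedGraph
#' @param track a `signal_track` data.frame (chrom, start, end, value).
#' @param path output path.
#' @export
write_bedgraph <- function(track, path) {
  gr <- df_to_granges(track)
  S4Vectors::mcols(gr)$score <- track$value
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Read a bedGraph signal track
#' @param path bedGraph path.
#' @export
read_bedgraph <- function(path) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  out <- granges_to_df(gr)
  out$value <- gr$score
  class(out) <- c("signal_track", "data.frame")
  out
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             check.names = FALSE)
}
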