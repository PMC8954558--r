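# Two-pass srRNA selection and target-gene assignment.
#
# Pass 1 selects reads that align to the rDNA unit (the srRNA class); pass 2
# maps exactly those reads to the genome.  Genome mappings are grouped into
# MappingRecords, merged into regions, and assigned to overlapping genes.

#' Select rDNA-aligned reads (pass 1)
#'
#' @param reads a (typically quality-trimmed) [small_read_set()].
#' @param rdna_index [seq_index()] over the rDNA reference.
#' @param max_mismatch mismatch cap for the rDNA pass (default 2, the
#'   high-sensitivity pass).
#' @return list: `reads` (the selected reads, as aligned), `alignments`
#'   (their rDNA alignments), `stats`.
#' @export
select_rdna_reads <- function(reads, rdna_index, max_mismatch = 2) {
  res <- align_reads(reads, rdna_index, max_mismatch = max_mismatch)
  sel <- reads[reads$read_id %in% res$alignments$read_id, , drop = FALSE]
  rownames(sel) <- NULL
  list(reads = sel, alignments = res$alignments, stats = res$stats)
}

#' Per-base srRNA coverage profile along the rDNA unit
#'
#' @param alignments rDNA alignments (from [select_rdna_reads()]).
#' @param rdna the [make_rdna_reference()] object.
#' @return list: `target_len`, `sense_depth`, `antisense_depth` (integer
#'   vectors; the sum of each equals the total aligned bases on that strand).
#' @export
rdna_coverage <- function(alignments, rdna) {
  L <- nchar(rdna$sequence)
  if (nrow(alignments) &&
      (min(alignments$start) < 0 || max(alignments$end) > L))
    stop("alignment outside [0, target length)")
  depth <- function(a) {
    if (!nrow(a)) return(integer(L))
    cov <- IRanges::coverage(IRanges::IRanges(a$start + 1L, a$end), width = L)
    as.integer(cov)
  }
  list(target_len = L,
       sense_depth = depth(alignments[alignments$strand == "+", , drop = FALSE]),
       antisense_depth = depth(alignments[alignments$strand == "-", , drop = FALSE]))
}

#' Fraction of sense-strand alignments
#'
#' @param alignments nonempty alignment data.frame.
#' @return fraction of `+` strand alignments.
#' @export
strand_fraction <- function(alignments) {
  if (!nrow(alignments)) stop("no alignments")
  mean(alignments$strand == "+")
}

#' Build the per-mapping table from genome alignments (pass 2 output)
#'
#' One record per distinct (chrom, start, end, strand, aligned sequence).
#' `read_count` is the number of reads collapsing onto the record,
#' `unique_count` the number of distinct original (pre-trimming) read
#' sequences among them, and `mean_depth` the per-locus depth of identical
#' placements (equal to `read_count` for end-to-end placements).
#'
#' @param alignments genome alignments (from [align_reads()]).
#' @param original_reads the pre-QC [small_read_set()], used to count
#'   distinct original sequences per record.
#' @return a `mapping_table` data.frame sorted by (chrom, start): chrom,
#'   start, end, strand, read_count, unique_count, mean_depth, sequence.
#' @export
mapping_table <- function(alignments, original_reads = NULL) {
  if (!nrow(alignments)) {
    out <- data.frame(chrom = character(), start = integer(),
                      end = integer(), strand = character(),
                      read_count = integer(), unique_count = integer(),
                      mean_depth = numeric(), sequence = character(),
                      stringsAsFactors = FALSE)
    class(out) <- c("mapping_table", "data.frame")
    return(out)
  }
  orig <- if (is.null(original_reads)) alignments$sequence else
    original_reads$sequence[match(alignments$read_id,
                                  original_reads$read_id)]
  orig[is.na(orig)] <- alignments$sequence[is.na(orig)]
  key <- paste(alignments$target, alignments$start, alignments$end,
               alignments$strand, alignments$sequence, sep = "\r")
  grp <- split(seq_len(nrow(alignments)), key)
  first <- vapply(grp, `[`, 0L, 1L)
  out <- data.frame(chrom = alignments$target[first],
                    start = alignments$start[first],
                    end = alignments$end[first],
                    strand = alignments$strand[first],
                    read_count = unname(lengths(grp)),
                    unique_count = vapply(grp, function(ix)
                      length(unique(orig[ix])), 0L, USE.NAMES = FALSE),
                    mean_depth = as.numeric(unname(lengths(grp))),
                    sequence = alignments$sequence[first],
                    stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$start, out$end, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("mapping_table", "data.frame")
  out
}

#' Merge mapping records into regions
#'
#' A region is a maximal run of overlapping or bookended (gap <= `gap`)
#' mappings, strand-agnostic.
#'
#' @param records a `mapping_table` (or any chrom/start/end data.frame).
#' @param gap maximum distance merged across (default 0 = bookended).
#' @return data.frame of merged regions (chrom, start, end), sorted.
#' @export
merge_mapping_regions <- function(records, gap = 0) {
  if (!nrow(records))
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  gr <- GenomicRanges::GRanges(records$chrom,
    IRanges::IRanges(records$start + 1L, records$end))
  red <- GenomicRanges::reduce(gr, min.gapwidth = gap + 1L,
                               ignore.strand = TRUE)
  out <- granges_to_df(red)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assign mapping records to overlapping genes
#'
#' A record is assigned to every gene it overlaps by at least 1 bp
#' (strand-agnostic: a sense srRNA can target an antisense-embedded
#' fragment); genes with at least one record become target genes.
#'
#' @param records a `mapping_table`.
#' @param genes gene data.frame (gene_id, name, chrom, start, end, strand;
#'   a [sim_gene_annotation()] list is accepted).
#' @return list: `targets` (one row per target gene with `n_mappings` and
#'   `n_srrnas` = summed read counts) and `assignments` (record_row,
#'   gene_id pairs).
#' @export
assign_target_genes <- function(records, genes) {
  if (is.list(genes) && !is.data.frame(genes) && !is.null(genes$genes))
    genes <- genes$genes
  empty <- list(targets = data.frame(gene_id = character(),
                                     name = character(), chrom = character(),
                                     start = integer(), end = integer(),
                                     strand = character(),
                                     n_mappings = integer(),
                                     n_srrnas = integer(),
                                     stringsAsFactors = FALSE),
                assignments = data.frame(record_row = integer(),
                                         gene_id = character(),
                                         stringsAsFactors = FALSE))
  if (!nrow(records) || !nrow(genes)) return(empty)
  rgr <- GenomicRanges::GRanges(records$chrom,
    IRanges::IRanges(records$start + 1L, records$end))
  ggr <- GenomicRanges::GRanges(genes$chrom,
    IRanges::IRanges(genes$start + 1L, genes$end))
  ov <- GenomicRanges::findOverlaps(rgr, ggr, minoverlap = 1L,
                                    ignore.strand = TRUE)
  if (!length(ov)) return(empty)
  assignments <- data.frame(record_row = S4Vectors::queryHits(ov),
                            gene_id = genes$gene_id[S4Vectors::subjectHits(ov)],
                            stringsAsFactors = FALSE)
  by_gene <- split(assignments$record_row, assignments$gene_id)
  targets <- do.call(rbind, lapply(names(by_gene), function(gid) {
    g <- genes[genes$gene_id == gid, ][1, ]
    ix <- by_gene[[gid]]
    data.frame(gene_id = gid, name = g$name, chrom = g$chrom,
               start = g$start, end = g$end, strand = g$strand,
               n_mappings = length(ix),
               n_srrnas = sum(records$read_count[ix]),
               stringsAsFactors = FALSE)
  }))
  targets <- targets[order(targets$gene_id), , drop = FALSE]
  rownames(targets) <- NULL
  list(targets = targets, assignments = assignments)
}

#' Intersect two gene lists
#'
#' Case-sensitive exact-match set algebra.
#'
#' @param list_a,list_b character vectors of gene ids.
#' @return list: `intersection`, `a_only`, `b_only`, and `counts`.
#' @export
overlap_gene_lists <- function(list_a, list_b) {
  a <- unique(list_a); b <- unique(list_b)
  inter <- intersect(a, b)
  list(intersection = inter, a_only = setdiff(a, b), b_only = setdiff(b, a),
       counts = c(intersection = length(inter),
                  a_only = length(a) - length(inter),
                  b_only = length(b) - length(inter)))
}

#' The 13 rDNA-family gene identifiers excluded from expression analysis
#' @return character vector of 13 gene names.
#' @export
rdna_family_genes <- function() {
  c("RNA5-8SN1", "RNA5-8SN3", "RNA5-8SN2", "FP671120.4", "FP671120.2",
    "FP236383.3", "FP236383.1", "FP236383.2", "RNA5-8SP6", "FP671120.1",
    "RF00002", "RNA5-8SP2", "AC010970.1")
}

#' Remove the rDNA gene family from a gene list
#'
#' Exact-name removal of the 13 rDNA-family identifiers; all other entries
#' are untouched and order is preserved.
#'
#' @param gene_list character vector of gene ids/names.
#' @export
exclude_rdna_family <- function(gene_list) {
  gene_list[!gene_list %in% rdna_family_genes()]
}
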