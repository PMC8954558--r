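# R surface of the gapless seed-and-extend aligner (compiled in
# src/aligner.cpp).

#' Build a k-mer seed index over reference sequences
#'
#' Exact k-mer positions over the sequences as given (+ strand); reverse
#' strand hits are found at query time by reverse-complementing the read.
#'
#' @param sequences named character vector (or `DNAStringSet`) of reference
#'   sequences; an `rdna_reference` is accepted directly.
#' @param k seed length, >= 8 and no longer than the shortest reference.
#' @return a `seq_index` object.
#' @export
seq_index <- function(sequences, k = 12) {
  if (inherits(sequences, "rdna_reference"))
    sequences <- setNames(sequences$sequence, sequences$name)
  if (methods::is(sequences, "DNAStringSet"))
    sequences <- setNames(as.character(sequences), names(sequences))
  if (!length(sequences)) stop("sequences must be nonempty")
  if (is.null(names(sequences)) || any(!nzchar(names(sequences))))
    stop("sequences must be named")
  if (k < 8) stop("k must be >= 8")
  if (k > min(nchar(sequences)))
    stop("k longer than the shortest reference sequence")
  ord <- order(names(sequences))  # name order fixes the tie-break
  sequences <- sequences[ord]
  ptr <- cpp_build_index(names(sequences), unname(sequences), as.integer(k))
  structure(list(ptr = ptr, names = names(sequences), k = as.integer(k),
                 lengths = setNames(nchar(sequences), names(sequences))),
            class = "seq_index")
}

#' Look up the reference positions of one k-mer
#'
#' @param index a [seq_index()].
#' @param kmer a string of length `k` (ACGT).
#' @return data.frame `target`, `pos` (0-based); zero rows when absent.
#' @export
index_lookup <- function(index, kmer) {
  cpp_index_lookup(index$ptr, kmer)
}

#' Align one read end-to-end against an index
#'
#' Gapless alignment over the full read length: candidate loci come from
#' exact matches of every overlapping read k-mer on both strands; the
#' Hamming distance is computed per candidate, N mismatching everything.
#' The best alignment (minimum mismatches, at most `max_mismatch`) is
#' returned with its `multiplicity` (number of equally-best loci); ties break
#' to the lowest (target name, start), `+` strand before `-`.  Sensitivity is
#' complete for alignments with at most `m = max_mismatch` mismatches when
#' the read length is at least `(m + 1)(k - 1) + m + 1` (36 for the defaults
#' `k = 12, m = 2`): `m` mismatches split a read into `m + 1` clean runs, and
#' only then must one run contain a full k-mer.  Shorter reads carrying the
#' full mismatch budget can be missed.
#'
#' @param sequence read sequence (length >= `k`).
#' @param index a [seq_index()].
#' @param max_mismatch maximum Hamming distance (default 2).
#' @param read_id identifier carried into the result.
#' @return one-row data.frame (`read_id`, `target`, `start`, `end` 0-based
#'   half-open, `strand`, `mismatches`, `multiplicity`, `sequence`) or a
#'   zero-row data.frame when unaligned.
#' @export
align_read <- function(sequence, index, max_mismatch = 2, read_id = "read") {
  cpp_align_reads(index$ptr, read_id, sequence, as.integer(max_mismatch),
                  FALSE)
}

#' Align a read set against an index
#'
#' @param reads a [small_read_set()] (or data.frame with `read_id` and
#'   `sequence`).
#' @param index a [seq_index()].
#' @param max_mismatch maximum Hamming distance.
#' @param keep_unaligned if `TRUE`, unaligned reads appear with `NA` fields.
#' @return list: `alignments` (coordinate-sorted by target then start) and
#'   `stats` (`n_input`, `n_aligned`, `n_unaligned`).
#' @export
align_reads <- function(reads, index, max_mismatch = 2,
                        keep_unaligned = FALSE) {
  aln <- cpp_align_reads(index$ptr, reads$read_id, reads$sequence,
                         as.integer(max_mismatch), keep_unaligned)
  if (keep_unaligned) aln$target[!nzchar(aln$target)] <- NA_character_
  aligned <- aln[!is.na(aln$target) & nzchar(aln$target), , drop = FALSE]
  n_aligned <- length(unique(aligned$read_id))
  ord <- order(aln$target, aln$start)
  aln <- aln[ord, , drop = FALSE]
  rownames(aln) <- NULL
  list(alignments = aln,
       stats = c(n_input = nrow(reads), n_aligned = n_aligned,
                 n_unaligned = nrow(reads) - n_aligned))
}

#' Export alignments as SAM
#'
#' Minimal SAM for interoperability: gapless reads become `<len>M` records;
#' reverse-strand alignments carry flag 16 and the reverse-complemented
#' sequence, as SAM requires.
#'
#' @param alignments alignment data.frame from [align_reads()].
#' @param index the [seq_index()] used (provides header lengths).
#' @param path output path.
#' @export
write_sam <- function(alignments, index, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:coordinate", con)
  for (nm in index$names)
    writeLines(sprintf("@SQ\tSN:%s\tLN:%d", nm, index$lengths[[nm]]), con)
  a <- alignments[!is.na(alignments$target), , drop = FALSE]
  if (nrow(a)) {
    seq_out <- ifelse(a$strand == "-", revcomp(a$sequence), a$sequence)
    flag <- ifelse(a$strand == "-", 16L, 0L)
    writeLines(sprintf("%s\t%d\t%s\t%d\t255\t%dM\t*\t0\t0\t%s\t*\tNM:i:%d",
                       a$read_id, flag, a$target, a$start + 1L,
                       nchar(a$sequence), seq_out, a$mismatches), con)
  }
  invisible(path)
}
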