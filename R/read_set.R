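#' Construct a set of small-RNA reads
#'
#' A small-read set is the unit of all read processing: a data.frame with one
#' row per read and columns `read_id`, `sequence` (ACGTN) and `quality`
#' (Phred+33 string, same length as the sequence, scores 0-60).
#'
#' @param read_id character vector of read identifiers.
#' @param sequence character vector of nucleotide strings (ACGTN).
#' @param quality character vector of Phred+33-encoded quality strings.
#' @return a `small_read_set` data.frame.
#' @export
small_read_set <- function(read_id, sequence, quality) {
  read_id <- as.character(read_id)
  sequence <- as.character(sequence)
  quality <- as.character(quality)
  if (length(read_id) != length(sequence) || length(sequence) != length(quality))
    stop("read_id, sequence and quality must have equal length")
  if (any(nchar(sequence) != nchar(quality)))
    stop("sequence and quality lengths differ for some reads")
  # Phred 0..60 <=> chars '!'(33) .. ']'(93)
  if (length(quality)) {
    all_q <- utf8ToInt(paste(quality, collapse = ""))
    if (length(all_q) && (min(all_q) < 33L || max(all_q) > 93L))
      stop("quality scores must be Phred+33 in [0, 60]")
  }
  out <- data.frame(read_id = read_id, sequence = sequence, quality = quality,
                    stringsAsFactors = FALSE)
  class(out) <- c("small_read_set", "data.frame")
  out
}

#' Read a FASTQ file into a small-read set
#'
#' @param path path to an (uncompressed or gzipped) FASTQ file, Phred+33.
#' @return a [small_read_set()].
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  small_read_set(names(x), as.character(x),
                 as.character(S4Vectors::mcols(x)$qualities))
}

#' Write a small-read set as FASTQ (Phred+33)
#'
#' @param reads a [small_read_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(reads$sequence)
  names(x) <- reads$read_id
  Biostrings::writeXStringSet(x, path, format = "fastq",
                              qualities = Biostrings::BStringSet(reads$quality))
  invisible(path)
}

# Decode Phred+33 strings to a list of integer vectors.
phred_decode <- function(quality) {
  lapply(quality, function(s) utf8ToInt(s) - 33L)
}

# Encode integer Phred scores as a +33 string.
phred_encode <- function(scores) {
  if (!length(scores)) return("")
  intToUtf8(scores + 33L)
}

# Vectorised reverse complement via Biostrings.
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Reverse a character string (used for antisense qualities).
str_reverse <- function(x) {
  vapply(x, function(s) intToUtf8(rev(utf8ToInt(s))), "", USE.NAMES = FALSE)
}
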