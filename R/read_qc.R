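# Read QC: quality trimming, exact deduplication and length statistics.
#
# Trimming reimplements the semantics of the published option string
# LEADING:18 TRAILING:18 SLIDINGWINDOW:4:22 MINLEN:20, applied in that order.

trim_one <- function(q, leading_q, trailing_q, window, window_q, min_len) {
  n <- length(q)
  i <- 1L
  while (i <= n && q[i] < leading_q) i <- i + 1L
  j <- n
  while (j >= i && q[j] < trailing_q) j <- j - 1L
  if (j < i) return(NULL)
  q <- q[i:j]
  L <- length(q)
  if (L >= window) {
    wm <- (cumsum(q)[window:L] -
             c(0, cumsum(q))[1:(L - window + 1L)]) / window
    bad <- which(wm < window_q)
    if (length(bad)) {
      keep <- bad[1] - 1L
      if (keep == 0L) return(NULL)
      q <- q[seq_len(keep)]
      j <- i + keep - 1L
    }
  } else {
    if (mean(q) < window_q) return(NULL)
  }
  if (length(q) < min_len) return(NULL)
  c(i, j)
}

#' Quality-trim a single read
#'
#' Steps are applied in order LEADING (drop 5' bases with quality below
#' `leading_q`), TRAILING (same from the 3' end), SLIDINGWINDOW (scan 5'->3';
#' at the first `window`-base window whose mean quality falls below
#' `window_q` the read is truncated at the window start; a remainder shorter
#' than `window` is kept only if its mean quality reaches `window_q`), and
#' MINLEN (reject below `min_len`).
#'
#' @param sequence nucleotide string.
#' @param quality Phred+33 quality string of the same length.
#' @param leading_q,trailing_q,window,window_q,min_len trimming thresholds
#'   (defaults 18/18/4:22/20).
#' @return list with trimmed `sequence` and `quality`, or `NULL` if the read
#'   is rejected.
#' @export
trim_read <- function(sequence, quality, leading_q = 18, trailing_q = 18,
                      window = 4, window_q = 22, min_len = 20) {
  if (nchar(sequence) != nchar(quality))
    stop("sequence and quality lengths differ")
  if (min(leading_q, trailing_q, window_q) < 0 || window < 1)
    stop("invalid trimming thresholds")
  q <- utf8ToInt(quality) - 33L
  span <- trim_one(q, leading_q, trailing_q, window, window_q, min_len)
  if (is.null(span)) return(NULL)
  list(sequence = substring(sequence, span[1], span[2]),
       quality = substring(quality, span[1], span[2]))
}

#' Quality-trim a read set
#'
#' Applies [trim_read()] to every read, preserving the order of survivors.
#'
#' @param reads a [small_read_set()].
#' @param ... thresholds passed to [trim_read()].
#' @return list with `reads` (trimmed survivors) and `counts`
#'   (`input`, `kept`, `rejected`).
#' @export
trim_reads <- function(reads, leading_q = 18, trailing_q = 18, window = 4,
                       window_q = 22, min_len = 20) {
  n <- nrow(reads)
  if (!n)
    return(list(reads = small_read_set(character(), character(), character()),
                counts = c(input = 0L, kept = 0L, rejected = 0L)))
  qs <- phred_decode(reads$quality)
  spans <- lapply(qs, trim_one, leading_q, trailing_q, window, window_q,
                  min_len)
  keep <- !vapply(spans, is.null, logical(1))
  from <- vapply(spans[keep], `[`, 0L, 1)
  to <- vapply(spans[keep], `[`, 0L, 2)
  out <- small_read_set(reads$read_id[keep],
                        substring(reads$sequence[keep], from, to),
                        substring(reads$quality[keep], from, to))
  list(reads = out,
       counts = c(input = n, kept = sum(keep), rejected = n - sum(keep)))
}

#' Deduplicate reads by exact sequence identity
#'
#' Each read is first end-trimmed (bases with quality below `end_trim_q`
#' stripped from both ends); reads whose trimmed sequences are byte-identical
#' collapse to one record whose representative is the first occurrence.
#' Reads trimmed to length zero do not survive.
#'
#' @param reads a [small_read_set()].
#' @param end_trim_q end-trim quality threshold (default 18).
#' @return data.frame: `read_id` (representative), `sequence`, `quality`
#'   (representative's trimmed values) and `copy_count`; copy counts sum to
#'   the number of reads surviving the end trim.
#' @export
dedup_reads <- function(reads, end_trim_q = 18) {
  if (!nrow(reads))
    return(data.frame(read_id = character(), sequence = character(),
                      quality = character(), copy_count = integer(),
                      stringsAsFactors = FALSE))
  qs <- phred_decode(reads$quality)
  spans <- lapply(qs, function(q) {
    n <- length(q)
    i <- 1L
    while (i <= n && q[i] < end_trim_q) i <- i + 1L
    j <- n
    while (j >= i && q[j] < end_trim_q) j <- j - 1L
    if (j < i) NULL else c(i, j)
  })
  keep <- !vapply(spans, is.null, logical(1))
  from <- vapply(spans[keep], `[`, 0L, 1)
  to <- vapply(spans[keep], `[`, 0L, 2)
  seqs <- substring(reads$sequence[keep], from, to)
  quals <- substring(reads$quality[keep], from, to)
  ids <- reads$read_id[keep]
  first <- !duplicated(seqs)
  counts <- table(factor(seqs, levels = seqs[first]))
  data.frame(read_id = ids[first], sequence = seqs[first],
             quality = quals[first],
             copy_count = as.integer(counts),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Summarise read lengths
#'
#' @param reads a [small_read_set()] (nonempty).
#' @return list: `n`, `min_len`, `max_len`, `mean_len`, `histogram`
#'   (named integer vector, length -> count).
#' @export
read_length_summary <- function(reads) {
  if (!nrow(reads)) stop("empty read set")
  len <- nchar(reads$sequence)
  h <- table(len)
  list(n = length(len), min_len = min(len), max_len = max(len),
       mean_len = mean(len),
       histogram = setNames(as.integer(h), names(h)))
}
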